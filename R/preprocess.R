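#' Configuration for the standardization pipeline
#'
#' @param target_spacing_mm numeric(3); the standardized resolution
#'   (default 2 x 2 x 3 mm).
#' @param roi_mm 2 x 3 matrix (rows min, max) giving the crop box in mm in
#'   standardized RAS space. The box is half-open `[min, max)` so boundary
#'   voxels are never counted twice across subjects. Must be set per
#'   dataset; the shipped phantom configs carry matching boxes.
#' @param blend_steepness logistic steepness for station blending; `NULL`
#'   picks the steepness at which the blend weights reach 0.05 / 0.95 at the
#'   overlap edges.
#' @param per_station_bias_correction optional bias correction of each
#'   station before stitching (off by default; post-stitch correction is the
#'   primary one).
#' @param bias_correction post-stitch bias-field correction flag.
#' @param bias_degree polynomial degree of the log-domain bias-field model.
#' @param normalization one of "none", "histogram_matching", "linear".
#' @param reference_scan reference volume (array) or NIfTI path, required
#'   for histogram matching.
#' @param normalize_range target range for the linear intensity transform.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_mm = c(2, 2, 3),
                              roi_mm = NULL,
                              blend_steepness = NULL,
                              per_station_bias_correction = FALSE,
                              bias_correction = TRUE,
                              bias_degree = 4L,
                              normalization = c("none", "histogram_matching",
                                                "linear"),
                              reference_scan = NULL,
                              normalize_range = c(0, 1)) {
  normalization <- match.arg(normalization)
  if (any(target_spacing_mm <= 0)) stopf("target spacing must be positive")
  if (!is.null(roi_mm)) {
    roi_mm <- matrix(as.numeric(roi_mm), 2, 3)
    if (any(roi_mm[1, ] >= roi_mm[2, ])) stopf("roi min must be < max per axis")
  }
  if (!is.null(blend_steepness) && blend_steepness <= 0)
    stopf("blend_steepness must be > 0")
  if (normalization == "histogram_matching" && is.null(reference_scan))
    stopf("histogram matching requires a reference scan")
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 roi_mm = roi_mm,
                 blend_steepness = blend_steepness,
                 per_station_bias_correction = per_station_bias_correction,
                 bias_correction = bias_correction,
                 bias_degree = as.integer(bias_degree),
                 normalization = normalization,
                 reference_scan = reference_scan,
                 normalize_range = normalize_range),
            class = "preprocess_config")
}

#' Read a preprocessing configuration from YAML
#' @param path YAML file with `preprocess_config` fields; `roi_mm` given as
#'   `min` and `max` triplets.
#' @param ... overrides.
#' @return a `preprocess_config`.
#' @export
read_preprocess_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$roi_mm))
    y$roi_mm <- rbind(as.numeric(y$roi_mm$min), as.numeric(y$roi_mm$max))
  y <- utils::modifyList(y, list(...))
  do.call(preprocess_config, y)
}

#' Reorient a volume to RAS voxel order
#'
#' Works on axis-aligned affines (up to permutation and flips); the physical
#' point each voxel maps to is preserved exactly.
#'
#' @param volume 3D array.
#' @param affine 4 x 4 voxel-to-mm matrix (0-based voxel indices).
#' @param tol relative tolerance for off-axis affine components.
#' @return list with reoriented `volume` and updated `affine`.
#' @export
reorient_to_ras <- function(volume, affine, tol = 1e-6) {
  stopifnot(is_affine(affine))
  R <- affine[1:3, 1:3]
  dominant <- apply(abs(R), 2, which.max)
  if (length(unique(dominant)) != 3L)
    stopf("affine is not a permutation of the coordinate axes")
  for (j in 1:3) {
    off <- abs(R[-dominant[j], j])
    if (any(off > tol * abs(R[dominant[j], j])))
      stopf("oblique affine: pipeline assumes axis-aligned acquisitions")
  }
  perm <- order(dominant)              # voxel axis feeding world axis 1, 2, 3
  vol <- aperm(volume, perm)
  Rp <- R[, perm]
  origin <- affine[1:3, 4]
  d <- dim(vol)
  for (a in 1:3) {
    if (Rp[a, a] < 0) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[a]] <- d[a]:1
      vol <- do.call(`[`, c(list(vol), idx, list(drop = FALSE)))
      origin <- origin + Rp[, a] * (d[a] - 1)
      Rp[, a] <- -Rp[, a]
    }
  }
  out <- diag(4)
  out[1:3, 1:3] <- Rp
  out[1:3, 4] <- origin
  list(volume = vol, affine = out)
}

#' Sigmoid blending profile for a station overlap
#'
#' Logistic weights centred at the overlap midpoint: positions near the
#' incoming station's boundary get small weight (boundary slices are the
#' most artifact-prone). The profile is symmetric, so the two stations'
#' weights sum to one at every overlap position.
#'
#' @param n_overlap_slices number of overlapping slices (>= 1).
#' @param steepness logistic steepness per slice (> 0); `NULL` picks the
#'   value at which the profile reaches 0.05 / 0.95 at the overlap edges.
#' @return numeric vector of length `n_overlap_slices`, increasing in (0,1).
#' @export
sigmoid_blend_weights <- function(n_overlap_slices, steepness = NULL) {
  n <- as.integer(n_overlap_slices)
  if (n < 1L) stopf("n_overlap_slices must be >= 1")
  if (is.null(steepness)) {
    steepness <- if (n > 1L) 2 * log(19) / (n - 1) else 1
  }
  if (steepness <= 0) stopf("steepness must be > 0")
  plogis(steepness * ((seq_len(n) - 1) - (n - 1) / 2))
}

#' Stitch overlapping stations into one volume set
#'
#' Stations are sorted by table-axis offset and folded left to right. In
#' each overlap, intensities are blended with [sigmoid_blend_weights()];
#' outside overlaps voxels are copied verbatim. The same geometry and
#' weights are applied to every contrast.
#'
#' @param stations list of stations; each a list holding one or more
#'   contrast arrays (all sharing one grid) plus `affine` (RAS-oriented).
#' @param contrasts names of the arrays to stitch.
#' @param blend_steepness see [sigmoid_blend_weights()].
#' @return list with the stitched arrays (one per contrast) and `affine`.
#' @export
stitch_stations <- function(stations, contrasts = DIXON_CONTRASTS,
                            blend_steepness = NULL) {
  if (length(stations) < 2L) stopf("need at least 2 stations")
  affs <- lapply(stations, `[[`, "affine")
  sp <- affine_spacing(affs[[1]])
  for (a in affs) {
    if (max(abs(a[1:3, 1:3] - affs[[1]][1:3, 1:3])) > 1e-6)
      stopf("stations must share orientation and spacing")
    if (max(abs(a[1:2, 4] - affs[[1]][1:2, 4])) > 1e-6)
      stopf("stations must share the in-plane grid")
  }
  d1 <- dim(stations[[1]][[contrasts[1]]])[1:2]
  for (s in stations)
    if (!all(dim(s[[contrasts[1]]])[1:2] == d1))
      stopf("in-plane grid mismatch between stations")

  z0 <- vapply(affs, function(a) a[3, 4], 0)
  ord <- order(z0)
  stations <- stations[ord]; z0 <- z0[ord]
  zmin <- z0[1]
  starts <- (z0 - zmin) / sp[3]
  if (max(abs(starts - round(starts))) > 1e-6)
    stopf("stations do not lie on a common voxel grid along the table axis")
  starts <- as.integer(round(starts))
  lens <- vapply(stations, function(s) dim(s[[contrasts[1]]])[3], 0L)
  nz <- max(starts + lens)

  out <- lapply(contrasts, function(k) array(0, c(d1, nz)))
  names(out) <- contrasts
  prev_end <- 0L                       # 0-based exclusive end of coverage
  for (t in seq_along(stations)) {
    s0 <- starts[t]; s1 <- s0 + lens[t]
    if (t > 1L) {
      ov <- prev_end - s0
      if (ov < 1L) stopf("stations %d and %d do not overlap", t - 1L, t)
      w <- sigmoid_blend_weights(ov, blend_steepness)
      for (k in contrasts) {
        st <- stations[[t]][[k]]
        for (i in seq_len(ov)) {
          z <- s0 + i                   # 1-based canvas slice
          out[[k]][, , z] <- (1 - w[i]) * out[[k]][, , z] + w[i] * st[, , i]
        }
        if (s1 > prev_end)
          out[[k]][, , (prev_end + 1L):s1] <- st[, , (ov + 1L):lens[t]]
      }
    } else {
      for (k in contrasts) out[[k]][, , (s0 + 1L):s1] <- stations[[t]][[k]]
    }
    prev_end <- max(prev_end, s1)
  }
  out$affine <- make_affine(sp, c(affs[[1]][1:2, 4], zmin))
  out
}

# polynomial basis of total degree <= deg on normalized [-1, 1]^3 coordinates
poly_basis3 <- function(x, y, z, deg) {
  terms <- list()
  for (i in 0:deg) for (j in 0:(deg - i)) for (k in 0:(deg - i - j))
    terms[[length(terms) + 1L]] <- x^i * y^j * z^k
  do.call(cbind, terms)
}

#' Bias-field correction from the in-phase contrast
#'
#' Estimates the smooth multiplicative intensity inhomogeneity by a masked
#' robust fit of a low-order 3D polynomial to the log in-phase intensities.
#' Voxels that deviate strongly from the smooth model (organ tissue whose
#' intrinsic intensity differs from the dominant tissue class) are trimmed
#' over a few reweighting iterations, so the field tracks the slowly varying
#' gain rather than anatomy. The field is normalized to unit geometric mean
#' over the mask and divided out of every supplied contrast voxelwise.
#'
#' @param in_phase 3D array; the field is estimated from this contrast only.
#' @param other_contrasts named list of additional arrays to correct with
#'   the shared field.
#' @param degree total polynomial degree of the log-field model.
#' @param mask_frac voxels with in-phase intensity above `mask_frac` times
#'   the robust (99th percentile) maximum enter the fit.
#' @param max_fit_voxels deterministic subsampling cap for the fit.
#' @param n_trim_iters robust reweighting iterations.
#' @param trim_k residual cut in units of the median absolute deviation.
#' @return list with `corrected` (named list: `in_phase` plus the others),
#'   `field` (the estimated multiplicative field) and `params`.
#' @export
bias_correct <- function(in_phase, other_contrasts = list(), degree = 4L,
                         mask_frac = 0.05, max_fit_voxels = 20000L,
                         n_trim_iters = 4L, trim_k = 2.0) {
  if (all(in_phase == 0)) stopf("in_phase is all zero; cannot estimate field")
  d <- dim(in_phase)
  top <- quantile(in_phase[in_phase > 0], 0.99, names = FALSE)
  mask <- in_phase > mask_frac * top
  idx <- which(mask)
  if (length(idx) > max_fit_voxels) {
    step <- ceiling(length(idx) / max_fit_voxels)
    idx <- idx[seq(1L, length(idx), by = step)]
  }
  ijk <- arrayInd(idx, d)
  nrm <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else 0 * i
  B <- poly_basis3(nrm(ijk[, 1], d[1]), nrm(ijk[, 2], d[2]),
                   nrm(ijk[, 3], d[3]), degree)
  yv <- log(in_phase[idx])
  wv <- rep(1, length(yv))
  for (it in seq_len(max(1L, n_trim_iters))) {
    fit <- stats::lm.wfit(B, yv, wv)
    res <- yv - as.numeric(B %*% ifelse(is.na(fit$coefficients), 0,
                                        fit$coefficients))
    s <- stats::mad(res)
    if (s <= 0) break
    wv <- as.numeric(abs(res - median(res)) < trim_k * s)
    if (sum(wv) < ncol(B) * 3) break   # keep the fit well-posed
  }
  co <- fit$coefficients
  co[is.na(co)] <- 0
  gx <- nrm(seq_len(d[1]), d[1]); gy <- nrm(seq_len(d[2]), d[2])
  gz <- nrm(seq_len(d[3]), d[3])
  # evaluate the full-grid log field without materializing a huge basis
  logf <- array(0, d)
  t_ind <- 0L
  for (i in 0:degree) for (j in 0:(degree - i)) for (k in 0:(degree - i - j)) {
    t_ind <- t_ind + 1L
    if (co[t_ind] != 0)
      logf <- logf + co[t_ind] * outer(outer(gx^i, gy^j), gz^k)
  }
  logf <- logf - mean(logf[mask])
  field <- exp(logf)
  corrected <- c(list(in_phase = in_phase / field),
                 lapply(other_contrasts, function(v) v / field))
  list(corrected = corrected, field = field,
       params = list(degree = degree, mask_frac = mask_frac,
                     n_fit_voxels = length(idx),
                     n_trim_iters = n_trim_iters, trim_k = trim_k))
}

#' Resample a volume to a target spacing
#'
#' @param volume 3D array with an axis-aligned RAS affine.
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @param target_spacing_mm numeric(3).
#' @param method "linear" for image contrasts, "nearest" for label maps.
#' @return list with resampled `volume` and updated `affine`.
#' @export
resample_volume <- function(volume, affine, target_spacing_mm,
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (any(target_spacing_mm <= 0)) stopf("target spacing must be positive")
  sp_in <- affine_spacing(affine)
  d_in <- dim(volume)
  d_out <- pmax(1L, as.integer(ceiling(d_in * sp_in / target_spacing_mm)))
  out_aff <- affine
  out_aff[1:3, 1:3] <- diag(target_spacing_mm, 3, 3)
  M <- solve(affine) %*% out_aff       # output voxel index -> input index
  vol <- sample_volume(volume, M, d_out, method)
  list(volume = vol, affine = out_aff)
}

#' Crop a volume to a region of interest in mm
#'
#' Keeps exactly the voxels whose centre coordinates fall inside the
#' half-open box `[min, max)` per axis.
#'
#' @param volume 3D array (RAS, axis-aligned affine).
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @param roi_mm 2 x 3 matrix, rows min and max.
#' @return list with cropped `volume` and updated `affine`.
#' @export
crop_roi <- function(volume, affine, roi_mm) {
  stopifnot(is_affine(affine))
  roi_mm <- matrix(as.numeric(roi_mm), 2, 3)
  d <- dim(volume)
  keep <- vector("list", 3)
  for (a in 1:3) {
    centers <- affine[a, 4] + (seq_len(d[a]) - 1) * affine[a, a]
    keep[[a]] <- which(centers >= roi_mm[1, a] & centers < roi_mm[2, a])
    if (length(keep[[a]]) == 0L)
      stopf("ROI does not intersect the volume along axis %d", a)
  }
  vol <- volume[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  out <- affine
  out[1:3, 4] <- affine[1:3, 4] +
    affine[1:3, 1:3] %*% (vapply(keep, `[`, 0L, 1L) - 1)
  list(volume = vol, affine = out)
}

#' Intensity normalization
#'
#' @param volume 3D array.
#' @param method "none", "linear" (min/max to `range`) or
#'   "histogram_matching" (quantile-landmark mapping onto a reference).
#' @param reference reference array, required for histogram matching.
#' @param range target range for the linear transform.
#' @param n_landmarks number of quantile landmarks for matching.
#' @return normalized array.
#' @export
normalize_intensity <- function(volume,
                                method = c("none", "linear",
                                           "histogram_matching"),
                                reference = NULL, range = c(0, 1),
                                n_landmarks = 101L) {
  method <- match.arg(method)
  if (method == "none") return(volume)
  if (method == "linear") {
    lo <- min(volume); hi <- max(volume)
    if (hi == lo) return(array(range[1], dim(volume)))
    out <- (volume - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
    return(out)
  }
  if (is.null(reference)) stopf("histogram matching requires a reference")
  p <- seq(0, 1, length.out = n_landmarks)
  qin <- quantile(volume, p, names = FALSE)
  qref <- quantile(reference, p, names = FALSE)
  out <- approx(qin, qref, xout = as.vector(volume), rule = 2,
                ties = "ordered")$y
  array(out, dim(volume))
}

#' Standardize a multi-station Dixon study
#'
#' Composes the full pipeline: reorientation to RAS, optional per-station
#' bias correction, sigmoid-blended stitching, bias correction on the
#' stitched in-phase (the field is shared by all contrasts), resampling to
#' the target resolution, ROI cropping, and optional intensity
#' normalization. A provenance record lists every step with its parameters.
#'
#' @param study a `dixon_study` (see [generate_phantom()] /
#'   [read_dixon_study()]).
#' @param config a [preprocess_config()]; `roi_mm` is required.
#' @return a `standardized_study`: the four contrast arrays on one grid,
#'   `affine`, `spacing` and `provenance`.
#' @export
preprocess_study <- function(study, config) {
  stopifnot(inherits(config, "preprocess_config"))
  if (is.null(config$roi_mm)) stopf("config$roi_mm is required")
  prov <- list()
  stations <- lapply(study$stations, function(st) {
    r <- reorient_to_ras(st[[DIXON_CONTRASTS[1]]], st$affine)
    out <- list(affine = r$affine)
    out[[DIXON_CONTRASTS[1]]] <- r$volume
    for (k in DIXON_CONTRASTS[-1])
      out[[k]] <- reorient_to_ras(st[[k]], st$affine)$volume
    out
  })
  prov$reorient <- list(orientation = "RAS")

  if (isTRUE(config$per_station_bias_correction)) {
    stations <- lapply(stations, function(st) {
      bc <- bias_correct(st$in_phase,
                         st[setdiff(DIXON_CONTRASTS, "in_phase")],
                         degree = config$bias_degree)
      st[names(bc$corrected)] <- bc$corrected
      st
    })
    prov$per_station_bias <- list(degree = config$bias_degree)
  }

  st <- stitch_stations(stations, DIXON_CONTRASTS, config$blend_steepness)
  prov$stitch <- list(n_stations = length(stations),
                      blend_steepness = config$blend_steepness)
  affine <- st$affine

  if (isTRUE(config$bias_correction)) {
    bc <- bias_correct(st$in_phase,
                       st[setdiff(DIXON_CONTRASTS, "in_phase")],
                       degree = config$bias_degree)
    st[names(bc$corrected)] <- bc$corrected
    prov$bias_correction <- bc$params
  }

  vols <- lapply(st[DIXON_CONTRASTS], function(v) {
    resample_volume(v, affine, config$target_spacing_mm, "linear")
  })
  affine <- vols[[1]]$affine
  vols <- lapply(vols, `[[`, "volume")
  prov$resample <- list(target_spacing_mm = config$target_spacing_mm)

  vols <- lapply(vols, function(v) crop_roi(v, affine, config$roi_mm))
  affine <- vols[[1]]$affine
  vols <- lapply(vols, `[[`, "volume")
  prov$crop <- list(roi_mm = config$roi_mm)

  if (config$normalization != "none") {
    ref <- config$reference_scan
    if (is.character(ref)) ref <- read_volume(ref)$volume
    meth <- if (config$normalization == "linear") "linear"
            else "histogram_matching"
    vols <- lapply(vols, normalize_intensity, method = meth, reference = ref,
                   range = config$normalize_range)
    prov$normalize <- list(method = config$normalization)
  }

  structure(c(vols, list(affine = affine,
                         spacing = config$target_spacing_mm,
                         provenance = prov)),
            class = "standardized_study")
}

#' Standardize a label map onto the pipeline's output grid
#'
#' Applies the geometric steps of [preprocess_study()] (reorientation,
#' nearest-neighbour resampling, ROI crop) to an integer label volume so it
#' stays aligned with the standardized contrasts. No intensity steps touch
#' the labels.
#'
#' @param labels integer 3D array (0..8).
#' @param affine its voxel-to-mm matrix.
#' @param config the same [preprocess_config()] used for the study.
#' @return list with `volume` (integer array) and `affine`.
#' @export
preprocess_labelmap <- function(labels, affine, config) {
  stopifnot(inherits(config, "preprocess_config"))
  r <- reorient_to_ras(labels, affine)
  rs <- resample_volume(r$volume, r$affine, config$target_spacing_mm,
                        "nearest")
  cr <- crop_roi(rs$volume, rs$affine, config$roi_mm)
  cr$volume <- array(as.integer(round(cr$volume)), dim(cr$volume))
  cr
}
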