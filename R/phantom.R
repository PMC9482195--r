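#' Configuration for the synthetic multi-station Dixon phantom
#'
#' The phantom emulates the geometry and contrast relations of a two-point
#' Dixon abdominal acquisition: a body-shaped background plus eight
#' ellipsoidal "organs" with per-organ water fractions, imaged as four
#' contrasts (water, fat, in-phase = water + fat, opposed-phase =
#' |water - fat|), modulated by a smooth multiplicative bias field, corrupted
#' by additive Gaussian noise, and split into overlapping table stations.
#'
#' @param grid_shape integer(3), voxels per axis of the whole volume.
#' @param voxel_spacing_mm numeric(3), mm per voxel.
#' @param n_stations integer >= 2, number of overlapping table stations the
#'   volume is split into along the third (table) axis.
#' @param overlap_mm overlap between consecutive stations in mm (> 0).
#' @param bias_amplitude amplitude of the multiplicative bias field in
#'   `[0, 1)`; the field lies in `[1 - a, 1 + a]`.
#' @param noise_sigma standard deviation of i.i.d. Gaussian noise added to
#'   each contrast after the bias field (measurement noise is post-gain).
#' @param organ_specs data.frame with columns `label` (1..8), `cx`, `cy`,
#'   `cz` (centre as fraction of the grid extent), `ax`, `ay`, `az`
#'   (ellipsoid semi-axes in mm) and `water_fraction` in `[0, 1]`.
#' @param seed integer seed; the phantom is a pure function of the config.
#' @param center_jitter_mm per-subject random displacement (sd, mm) of organ
#'   centres; models inter-subject anatomy.
#' @param axes_jitter_frac per-subject relative jitter (sd) of semi-axes.
#' @param intensity_jitter per-subject relative jitter (sd) of organ signal.
#' @param station_orientation orientation code the stations are stored in
#'   ("RAS" or "LPS"); acquisitions are often LPS on disk.
#' @return A `phantom_config` list, validated.
#' @export
phantom_config <- function(grid_shape = c(96L, 96L, 64L),
                           voxel_spacing_mm = c(2.5, 2.5, 3.6),
                           n_stations = 3L,
                           overlap_mm = 36,
                           bias_amplitude = 0.2,
                           noise_sigma = 0.02,
                           organ_specs = default_organ_specs(),
                           seed = 1L,
                           center_jitter_mm = 3,
                           axes_jitter_frac = 0.08,
                           intensity_jitter = 0.05,
                           station_orientation = c("RAS", "LPS")) {
  station_orientation <- match.arg(station_orientation)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stopf("grid_shape must be 3 integers >= 8")
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stopf("voxel_spacing_mm must be 3 positive values")
  if (n_stations < 2L) stopf("n_stations must be >= 2")
  if (overlap_mm <= 0) stopf("overlap_mm must be > 0")
  extent_z <- grid_shape[3] * voxel_spacing_mm[3]
  if (overlap_mm >= extent_z / n_stations)
    stopf("overlap_mm (%g) must be smaller than the station extent", overlap_mm)
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stopf("bias_amplitude must be in [0, 1)")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  os <- as.data.frame(organ_specs)
  need <- c("label", "cx", "cy", "cz", "ax", "ay", "az", "water_fraction")
  if (!all(need %in% names(os))) stopf("organ_specs needs columns: %s",
                                       paste(need, collapse = ", "))
  if (!identical(sort(as.integer(os$label)), 1:8))
    stopf("organ labels must be exactly 1..8, each once")
  if (any(os$ax <= 0 | os$ay <= 0 | os$az <= 0))
    stopf("organ semi-axes must be positive")
  if (any(os$water_fraction < 0 | os$water_fraction > 1))
    stopf("water_fraction must be in [0, 1]")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 n_stations = as.integer(n_stations),
                 overlap_mm = overlap_mm,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 organ_specs = os[order(os$label), , drop = FALSE],
                 seed = as.integer(seed),
                 center_jitter_mm = center_jitter_mm,
                 axes_jitter_frac = axes_jitter_frac,
                 intensity_jitter = intensity_jitter,
                 station_orientation = station_orientation),
            class = "phantom_config")
}

#' Default phantom organ layout
#'
#' One large organ (liver-like), one medium (spleen-like), two lateral
#' medium pairs (kidney-like), two tiny pairs (adrenal-like), one elongated
#' (pancreas-like) and one small (gallbladder-like) ellipsoid, so metric and
#' training behaviour on organs of very different sizes is exercised.
#' Scaled for the default 240 x 240 x 230 mm grid.
#' @return data.frame of organ specifications.
#' @export
default_organ_specs <- function() {
  data.frame(
    label = 1:8,
    name = ORGAN_NAMES[2:9],
    cx = c(0.33, 0.76, 0.30, 0.70, 0.30, 0.70, 0.52, 0.42),
    cy = c(0.42, 0.44, 0.66, 0.66, 0.70, 0.70, 0.62, 0.20),
    cz = c(0.62, 0.64, 0.36, 0.36, 0.55, 0.55, 0.47, 0.47),
    ax = c(58, 26, 19, 19, 9, 9, 38, 13),
    ay = c(41, 22, 17, 17, 7, 7, 13, 10),
    az = c(43, 25, 26, 26, 8.5, 8.5, 12, 14.5),
    water_fraction = c(0.70, 0.80, 0.75, 0.75, 0.55, 0.55, 0.62, 0.92))
}

#' Read a phantom configuration from YAML
#'
#' @param path YAML file; see `system.file("extdata", "phantom_small.yaml",
#'   package = "abdomenseg")` for the shipped layouts.
#' @param ... overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
read_phantom_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$organ_specs)) {
    y$organ_specs <- do.call(rbind, lapply(y$organ_specs, as.data.frame))
  }
  y <- utils::modifyList(y, list(...))
  do.call(phantom_config, y)
}

# RAS affine: diag(spacing) with an origin offset
make_affine <- function(spacing, origin = c(0, 0, 0)) {
  a <- diag(4)
  a[1:3, 1:3] <- diag(spacing, 3, 3)
  a[1:3, 4] <- origin
  a
}

# voxel-centre coordinate vectors in mm, 0-based indexing
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

ellipsoid_mask <- function(coords, center_mm, semi_mm) {
  u <- (coords[[1]] - center_mm[1]) / semi_mm[1]
  v <- (coords[[2]] - center_mm[2]) / semi_mm[2]
  w <- (coords[[3]] - center_mm[3]) / semi_mm[3]
  q <- outer(outer(u^2, v^2, `+`), w^2, `+`)
  q <= 1
}

#' Generate a synthetic multi-station Dixon study
#'
#' Builds water and fat maps from ellipsoids on a body-shaped background,
#' derives in-phase (water + fat) and opposed-phase (|water - fat|), applies
#' one smooth multiplicative bias field identically to all four contrasts,
#' adds Gaussian noise, and crops the result into overlapping stations whose
#' affines encode the table position. Fully deterministic given the config
#' seed. Overlapping organ voxels go to the earlier-listed label.
#'
#' @param config a [phantom_config()].
#' @return list with `study` (a `dixon_study`: stations, each holding the
#'   four contrast arrays, an affine and an orientation code), `labels`
#'   (integer array 0..8 on the whole grid) and `truth` (the clean,
#'   bias-free, noise-free whole-grid contrast volumes plus affine).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    shp <- config$grid_shape
    sp <- config$voxel_spacing_mm
    extent <- shp * sp
    coords <- grid_coords(shp, sp)
    labels <- array(0L, shp)

    body <- ellipsoid_mask(coords, extent * c(0.5, 0.5, 0.5),
                           extent * c(0.46, 0.43, 0.54))
    water <- array(0, shp); fat <- array(0, shp)
    water[body] <- 0.35
    fat[body] <- 0.35

    os <- config$organ_specs
    clamp2 <- function(x, s) pmax(pmin(x, 2 * s), -2 * s)  # truncated jitter
    for (r in seq_len(nrow(os))) {
      ctr <- c(os$cx[r], os$cy[r], os$cz[r]) * extent +
        clamp2(rnorm(3, 0, config$center_jitter_mm), config$center_jitter_mm)
      semi <- c(os$ax[r], os$ay[r], os$az[r]) *
        (1 + clamp2(rnorm(3, 0, config$axes_jitter_frac),
                    config$axes_jitter_frac))
      if (any(ctr - semi < 0) || any(ctr + semi > extent))
        stopf("organ with label %d extends outside the grid", os$label[r])
      m <- ellipsoid_mask(coords, ctr, semi) & labels == 0L
      if (!any(m)) stopf("organ with label %d occupies no voxel", os$label[r])
      labels[m] <- as.integer(os$label[r])
      sig <- 1 * (1 + rnorm(1, 0, config$intensity_jitter))
      water[m] <- sig * os$water_fraction[r]
      fat[m] <- sig * (1 - os$water_fraction[r])
    }

    truth <- list(water = water, fat = fat,
                  in_phase = water + fat,
                  opposed_phase = abs(water - fat),
                  affine = make_affine(sp))

    # smooth multiplicative bias: separable low-frequency cosine product,
    # exactly bounded in [1 - a, 1 + a]
    freq <- runif(3, 0.4, 0.8)
    phase <- runif(3, 0, 2 * pi)
    cs <- lapply(1:3, function(a)
      cos(2 * pi * freq[a] * coords[[a]] / extent[a] + phase[a]))
    bias <- 1 + config$bias_amplitude *
      outer(outer(cs[[1]], cs[[2]]), cs[[3]])

    observed <- lapply(truth[DIXON_CONTRASTS], function(v) {
      v <- v * bias
      if (config$noise_sigma > 0)
        v <- v + array(rnorm(length(v), 0, config$noise_sigma), dim(v))
      v
    })

    spans <- station_spans(shp[3], sp[3], config$n_stations, config$overlap_mm)
    stations <- lapply(seq_len(nrow(spans)), function(t) {
      zr <- spans$start[t]:spans$end[t]
      st <- lapply(observed, function(v) v[, , zr, drop = FALSE])
      st$affine <- make_affine(sp, c(0, 0, (spans$start[t] - 1) * sp[3]))
      st$orientation <- "RAS"
      if (config$station_orientation == "LPS") st <- station_to_lps(st)
      st
    })
    list(study = structure(list(stations = stations), class = "dixon_study"),
         labels = labels,
         labels_affine = make_affine(sp),
         truth = truth,
         bias_field = bias)
  })
}

# 1-based inclusive voxel spans of n stations with an exact voxel overlap
station_spans <- function(nz, sp_z, n_stations, overlap_mm) {
  ov <- as.integer(round(overlap_mm / sp_z))
  if (abs(ov * sp_z - overlap_mm) > 1e-6)
    stopf("overlap_mm must be a multiple of the z spacing (%g mm)", sp_z)
  if (ov < 1L) stopf("overlap_mm is below one voxel")
  total <- nz + (n_stations - 1L) * ov
  len <- rep(total %/% n_stations, n_stations)
  extra <- total %% n_stations
  if (extra > 0) len[seq_len(extra)] <- len[seq_len(extra)] + 1L
  if (any(len <= ov))
    stopf("n_stations = %d is too large for overlap %g mm", n_stations,
          overlap_mm)
  start <- integer(n_stations); start[1] <- 1L
  for (t in seq_len(n_stations - 1L))
    start[t + 1L] <- start[t] + len[t] - ov
  data.frame(start = start, end = start + len - 1L)
}

# store a station in LPS voxel order (first two axes flipped)
station_to_lps <- function(st) {
  d <- dim(st$water)
  aff <- st$affine
  for (a in 1:2) {
    aff[, 4] <- aff[, 4] + aff[, a] * (d[a] - 1)
    aff[, a] <- -aff[, a]
  }
  for (k in DIXON_CONTRASTS)
    st[[k]] <- st[[k]][d[1]:1, d[2]:1, , drop = FALSE]
  st$affine <- aff
  st$orientation <- "LPS"
  st
}

#' Generate a cohort of phantom subjects
#'
#' @param config base [phantom_config()]; each subject uses a distinct seed
#'   derived from `seed + subject index`.
#' @param n_subjects number of subjects.
#' @param seed cohort seed.
#' @return named list of phantoms (`subject_01`, ...).
#' @export
make_cohort <- function(config, n_subjects, seed = config$seed) {
  stopifnot(n_subjects >= 1)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- as.integer((seed + 977L * i) %% .Machine$integer.max)
    out[[i]] <- generate_phantom(cfg)
  }
  names(out) <- sprintf("subject_%02d", seq_len(n_subjects))
  out
}

#' Split study identifiers into k cross-validation folds
#'
#' Each fold is a disjoint, exhaustive (train, val, test) partition of the
#' ids; the test sets across folds partition the full id set. The validation
#' set of fold i is the test chunk of the cyclically next fold.
#'
#' @param study_ids character or integer vector of ids.
#' @param k number of folds (>= 2, <= number of ids).
#' @param seed shuffling seed.
#' @return list of `k` lists with elements `train`, `val`, `test`.
#' @export
split_into_folds <- function(study_ids, k, seed = 1L) {
  n <- length(study_ids)
  if (k < 2L) stopf("k must be >= 2")
  if (k > n) stopf("k = %d exceeds the %d available ids", k, n)
  shuffled <- with_seed(seed, sample(study_ids))
  # contiguous blocks of near-equal size over the shuffled ids
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ends <- cumsum(sizes); starts <- c(1L, utils::head(ends, -1L) + 1L)
  chunk <- lapply(seq_len(k), function(i) shuffled[starts[i]:ends[i]])
  lapply(seq_len(k), function(i) {
    test <- chunk[[i]]
    val <- chunk[[i %% k + 1L]]
    train <- setdiff(shuffled, c(test, val))
    list(train = train, val = val, test = test)
  })
}
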