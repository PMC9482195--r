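# Per-organ Dice similarity and average symmetric surface distance (mm).

#' Dice similarity coefficient for one class
#'
#' `2|P intersect G| / (|P| + |G|)` on the binary masks. When the class is
#' absent from both volumes the score is undefined (`NA`); when it is
#' absent from exactly one, the score is 0.
#'
#' @param pred,gt aligned integer label arrays.
#' @param class_id class to score.
#' @return Dice in `[0, 1]`, or `NA` when undefined.
#' @export
dice_score <- function(pred, gt, class_id) {
  if (!identical(dim(pred), dim(gt))) stopf("label maps differ in shape")
  p <- pred == class_id
  g <- gt == class_id
  np <- sum(p); ng <- sum(g)
  if (np == 0 && ng == 0) return(NA_real_)
  2 * sum(p & g) / (np + ng)
}

# mask voxels with at least one face-adjacent (6-connectivity) non-mask
# neighbour; voxels on the array boundary count as surface
surface_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  shift_and <- function(m, axis, by) {
    out <- array(FALSE, d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (by > 0) { idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1) }
    else { idx_dst[[axis]] <- 1:(d[axis] - 1); idx_src[[axis]] <- 2:d[axis] }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(m), idx_src)))))
    out
  }
  for (axis in 1:3) {
    for (by in c(1, -1)) {
      nb <- shift_and(mask, axis, by)   # neighbour present in direction
      interior <- interior & nb
    }
  }
  mask & !interior
}

#' Average symmetric surface distance in millimetres
#'
#' Surfaces are the mask voxels with a face-adjacent background neighbour;
#' distances between surface voxel centres respect the anisotropic voxel
#' spacing. The two directed mean distances are averaged weighted by
#' surface size (the standard ASSD).
#'
#' @param pred,gt aligned integer label arrays.
#' @param class_id class to score.
#' @param spacing_mm numeric(3) voxel spacing.
#' @return ASSD in mm (0 for identical masks), or `NA` with a warning when
#'   a mask is empty.
#' @export
assd <- function(pred, gt, class_id, spacing_mm = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(gt))) stopf("label maps differ in shape")
  if (any(spacing_mm <= 0)) stopf("spacing must be positive")
  p <- pred == class_id
  g <- gt == class_id
  if (!any(p) || !any(g)) {
    warning(sprintf("class %s absent from %s; ASSD undefined", class_id,
                    if (!any(p) && !any(g)) "both volumes"
                    else if (!any(p)) "the prediction" else "the ground truth"))
    return(NA_real_)
  }
  sp <- surface_points(p, spacing_mm)
  sg <- surface_points(g, spacing_mm)
  dpg <- nearest_distances(sp, sg)
  dgp <- nearest_distances(sg, sp)
  (sum(dpg) + sum(dgp)) / (nrow(sp) + nrow(sg))
}

surface_points <- function(mask, spacing_mm) {
  idx <- which(surface_mask(mask))
  ijk <- arrayInd(idx, dim(mask)) - 1L
  sweep(ijk, 2, spacing_mm, `*`)
}

#' Per-organ metrics table
#'
#' Dice and ASSD for all foreground classes, plus a mean row over the
#' classes where each metric is defined.
#'
#' @param pred,gt aligned integer label arrays (0..8).
#' @param spacing_mm numeric(3) voxel spacing.
#' @param class_names names for classes 1..8.
#' @return data.frame with columns `class_id`, `class_name`, `dice`,
#'   `assd_mm`; the final row holds the means.
#' @export
evaluate <- function(pred, gt, spacing_mm = c(2, 2, 3),
                     class_names = ORGAN_NAMES[2:9]) {
  n <- length(class_names)
  rows <- lapply(seq_len(n), function(l) {
    a <- withCallingHandlers(
      assd(pred, gt, l, spacing_mm),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(class_id = l, class_name = class_names[l],
               dice = dice_score(pred, gt, l), assd_mm = a)
  })
  tab <- do.call(rbind, rows)
  mean_row <- data.frame(class_id = NA_integer_, class_name = "mean",
                         dice = mean(tab$dice, na.rm = TRUE),
                         assd_mm = mean(tab$assd_mm, na.rm = TRUE))
  rbind(tab, mean_row)
}

#' Write a metrics table as CSV
#' @param metrics data.frame from [evaluate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
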