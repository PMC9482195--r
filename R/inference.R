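# Volume-level prediction per anatomical view and multi-view probability
# aggregation. Probability volumes are (X, Y, Z, n_classes) arrays whose
# class dimension sums to one per voxel.

#' Predict class probabilities for a whole study from one view
#'
#' Every slice along the view axis is passed through the network in eval
#' mode; the softmax slices are restacked into a probability volume aligned
#' with the study grid.
#'
#' @param net trained network for this view/contrast set.
#' @param study a `standardized_study`.
#' @param view anatomical view the network was trained on.
#' @param contrasts input contrasts (must match the network's in_channels).
#' @param batch slices per forward pass.
#' @return list with `probs` (X, Y, Z, n_classes) and `affine`.
#' @export
predict_view <- function(net, study,
                         view = c("axial", "coronal", "sagittal"),
                         contrasts = c("opposed_phase", "water"),
                         batch = 8L) {
  view <- match.arg(view)
  if (length(contrasts) != net$config$in_channels)
    stopf("%d contrasts requested but network takes %d channels",
          length(contrasts), net$config$in_channels)
  sl <- extract_slices(study, NULL, view, contrasts)
  p <- predict_slices(net, sl$x, batch)           # H x W x L x n
  L <- dim(p)[3]
  d <- sl$grid
  out <- array(0, c(d, L))
  for (l in seq_len(L))
    out[, , , l] <- restack_slices(p[, , l, ], view)
  list(probs = out, affine = study$affine)
}

#' Average probability volumes from several views
#'
#' Equal-weight voxelwise arithmetic mean; the mean of probability
#' simplices is a simplex.
#'
#' @param ... two or more probability volumes (arrays or `predict_view()`
#'   results), all on one grid. A single list argument is also accepted.
#' @return aggregated probability array (X, Y, Z, n_classes).
#' @export
aggregate_views <- function(...) {
  vols <- list(...)
  if (length(vols) == 1L && is.list(vols[[1]]) && !is.array(vols[[1]]))
    vols <- vols[[1]]
  vols <- lapply(vols, function(v) if (is.list(v)) v$probs else v)
  if (length(vols) < 1L) stopf("no probability volumes given")
  d <- dim(vols[[1]])
  for (v in vols)
    if (!identical(dim(v), d)) stopf("probability volumes are on different grids")
  Reduce(`+`, vols) / length(vols)
}

#' Convert a probability volume to a label map
#'
#' Per-voxel argmax over classes; ties break to the lowest class index
#' (background first), deterministically.
#'
#' @param p probability array (X, Y, Z, n_classes).
#' @return integer label array (X, Y, Z) with values `0 .. n_classes - 1`.
#' @export
to_labelmap <- function(p) {
  if (is.list(p)) p <- p$probs
  d <- dim(p)
  m <- matrix(p, ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), d[1:3])
}

#' Segment a study with one or more view networks
#'
#' Runs [predict_view()] for every provided network, averages the
#' probability volumes over the provided views (a single view degrades
#' gracefully to single-view segmentation) and takes the argmax.
#'
#' @param networks named list of networks; names are views
#'   ("axial", "coronal", "sagittal").
#' @param study a `standardized_study`.
#' @param contrasts input contrasts.
#' @return list with `labels` (integer array), `probs` and `affine`.
#' @export
segment <- function(networks, study, contrasts = c("opposed_phase", "water")) {
  if (length(networks) == 0L) stopf("at least one view network is required")
  if (is.null(names(networks)) || !all(names(networks) %in% names(VIEW_AXES)))
    stopf("networks must be named by view (axial/coronal/sagittal)")
  pv <- lapply(names(networks), function(v)
    predict_view(networks[[v]], study, v, contrasts))
  probs <- aggregate_views(lapply(pv, `[[`, "probs"))
  list(labels = to_labelmap(probs), probs = probs, affine = study$affine)
}
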