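# NIfTI and sidecar I/O. All volumes travel as plain arrays plus a 4x4
# voxel-to-mm affine (0-based voxel indices); RNifti handles the format.

#' Write a volume as NIfTI
#' @param volume 3D array.
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, affine, path) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- affine_spacing(affine)
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#' @param path NIfTI file.
#' @return list with `volume` (array) and `affine`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(volume = array(as.numeric(img), dim(img)), affine = aff)
}

#' Write a multi-station Dixon study to a directory
#'
#' One NIfTI per station and contrast, named
#' `<subject>_<station>_<contrast>.nii.gz`, plus `<subject>_labels.nii.gz`
#' when labels are given. Station affines carry the table offsets.
#'
#' @param study a `dixon_study`.
#' @param dir output directory (created if missing).
#' @param subject subject identifier used in filenames.
#' @param labels optional label array on the whole grid.
#' @param labels_affine affine of `labels`.
#' @return `dir`, invisibly.
#' @export
write_dixon_study <- function(study, dir, subject, labels = NULL,
                              labels_affine = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(study$stations)) {
    st <- study$stations[[t]]
    for (k in DIXON_CONTRASTS)
      write_volume(st[[k]], st$affine,
                   file.path(dir, sprintf("%s_%02d_%s.nii.gz", subject, t, k)))
  }
  if (!is.null(labels))
    write_volume(labels, labels_affine,
                 file.path(dir, sprintf("%s_labels.nii.gz", subject)))
  invisible(dir)
}

#' Read a multi-station Dixon study from a directory
#' @param dir directory written by [write_dixon_study()].
#' @param subject subject identifier.
#' @return list with `study` (a `dixon_study`) and, if present, `labels`
#'   and `labels_affine`.
#' @export
read_dixon_study <- function(dir, subject) {
  files <- list.files(dir, sprintf("^%s_\\d+_%s\\.nii(\\.gz)?$", subject,
                                   DIXON_CONTRASTS[1]))
  if (length(files) == 0L) stopf("no stations found for subject %s", subject)
  ids <- sort(sub(sprintf("^%s_(\\d+)_.*$", subject), "\\1", files))
  stations <- lapply(ids, function(t) {
    st <- list()
    for (k in DIXON_CONTRASTS) {
      v <- read_volume(file.path(dir, sprintf("%s_%s_%s.nii.gz", subject, t, k)))
      st[[k]] <- v$volume
      st$affine <- v$affine
    }
    st$orientation <- tryCatch(
      paste(RNifti::orientation(RNifti::readNifti(file.path(
        dir, sprintf("%s_%s_%s.nii.gz", subject, t, DIXON_CONTRASTS[1])))),
        collapse = ""),
      error = function(e) NA_character_)
    st
  })
  out <- list(study = structure(list(stations = stations),
                                class = "dixon_study"))
  lp <- file.path(dir, sprintf("%s_labels.nii.gz", subject))
  if (file.exists(lp)) {
    lv <- read_volume(lp)
    out$labels <- array(as.integer(round(lv$volume)), dim(lv$volume))
    out$labels_affine <- lv$affine
  }
  out
}

#' Write a provenance record as a JSON sidecar
#' @param provenance list of pipeline steps and parameters.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(provenance, path) {
  jsonlite::write_json(provenance, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}
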