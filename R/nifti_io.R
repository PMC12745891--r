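# NIfTI persistence for binned image sets: one volume per respiratory bin
# plus a JSON sidecar with acquisition provenance.

#' Write a binned image set to a directory of NIfTI volumes
#'
#' One `bin_###.nii.gz` file per respiratory bin (float64, lossless) plus a
#' `provenance.json` sidecar recording modality, binning mode, grid
#' geometry and acquisition provenance.
#'
#' @param set A [binned_image_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_nifti_set <- function(set, dir) {
  stopifnot(inherits(set, "binned_image_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (b in seq_len(set$n_bins)) {
    img <- RNifti::asNifti(set$volumes[[b]],
                           pixdim = set$grid$voxel_mm, datatype = "double")
    RNifti::writeNifti(img, file.path(dir, sprintf("bin_%03d.nii.gz", b - 1L)))
  }
  side <- list(modality = set$modality, bin_mode = set$bin_mode,
               n_bins = set$n_bins,
               grid = list(matrix = set$grid$matrix,
                           fov_mm = set$grid$fov_mm,
                           n_slices = set$grid$n_slices,
                           slice_thickness_mm = set$grid$slice_thickness_mm,
                           orientation = set$grid$orientation),
               provenance = set$provenance)
  jsonlite::write_json(side, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a binned image set from a directory of NIfTI volumes
#'
#' Loads every `bin_*.nii*` file (sorted) and the `provenance.json`
#' sidecar.  A missing sidecar is tolerated: volumes load with provenance
#' marked unknown and grid geometry inferred from the NIfTI header.  A
#' sidecar whose bin count disagrees with the files present, or volumes on
#' mismatched grids, raise a format error.
#'
#' @param dir Directory written by [write_nifti_set()].
#' @return A [binned_image_set()].
#' @export
read_nifti_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "^bin_[0-9]+\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no bin volumes found in ", dir, call. = FALSE)
  imgs <- lapply(files, RNifti::readNifti)
  dims <- vapply(imgs, function(x) paste(dim(x), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1L) {
    stop("format error: bin volumes have mismatched grids", call. = FALSE)
  }
  volumes <- lapply(imgs, function(x) array(as.numeric(x), dim(x)))
  sidecar <- file.path(dir, "provenance.json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$n_bins) && side$n_bins != length(files)) {
      stop(sprintf(
        "format error: sidecar declares %d bins but %d volumes present",
        side$n_bins, length(files)), call. = FALSE)
    }
    g <- side$grid
    grid <- image_grid(g$matrix, g$fov_mm, g$n_slices,
                       g$slice_thickness_mm, g$orientation)
    prov <- side$provenance
    modality <- side$modality
    bin_mode <- side$bin_mode
  } else {
    pd <- RNifti::pixdim(imgs[[1L]])
    d <- dim(imgs[[1L]])
    grid <- image_grid(d[1L], d[1L] * pd[1L], d[3L], pd[3L], "axial")
    prov <- list(unknown = TRUE)
    modality <- "MR"
    bin_mode <- "amplitude"
  }
  binned_image_set(volumes, grid, modality = modality, bin_mode = bin_mode,
                   provenance = prov)
}
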