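# Readers/writers for the standard formats: NIfTI-1 volumes (via RNifti),
# tab-separated tables, GMT gene sets and JSON summaries.

#' Write a tissue segmentation as NIfTI masks
#'
#' One unsigned 8-bit volume per mask, voxel spacing in the header.
#'
#' @param seg a [tissue_segmentation()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_segmentation <- function(seg, dir) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- c("ventricle_mask", "wm_mask", "wmh_mask", "gm_mask", "brain_mask")
  paths <- character(0)
  for (nm in masks) {
    if (is.null(seg[[nm]])) next
    img <- RNifti::asNifti(array(as.integer(seg[[nm]]), dim(seg[[nm]])))
    RNifti::pixdim(img) <- seg$spacing_mm
    f <- file.path(dir, paste0(sub("_mask$", "", nm), ".nii.gz"))
    RNifti::writeNifti(img, f, datatype = "uint8")
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Read a tissue segmentation from NIfTI masks
#'
#' Expects `ventricle.nii.gz`, `wm.nii.gz`, `brain.nii.gz` and optionally
#' `wmh.nii.gz`, `gm.nii.gz` in `dir`.
#'
#' @param dir directory holding the mask volumes.
#' @return a [tissue_segmentation()].
#' @export
read_segmentation <- function(dir) {
  rd <- function(nm, required = TRUE) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    if (!file.exists(f)) f <- file.path(dir, paste0(nm, ".nii"))
    if (!file.exists(f)) {
      if (required) stop_pv("missing mask volume: ", nm,
                            class = "pvgrad_validation_error")
      return(NULL)
    }
    RNifti::readNifti(f)
  }
  vent <- rd("ventricle")
  tissue_segmentation(ventricle = array(vent > 0, dim(vent)),
                      wm = array(rd("wm") > 0, dim(vent)),
                      wmh = { w <- rd("wmh", FALSE)
                              if (is.null(w)) NULL else array(w > 0, dim(vent)) },
                      gm = { g <- rd("gm", FALSE)
                             if (is.null(g)) NULL else array(g > 0, dim(vent)) },
                      brain = array(rd("brain") > 0, dim(vent)),
                      spacing_mm = RNifti::pixdim(vent)[1:3])
}

#' Write a metric volume as 32-bit float NIfTI
#'
#' @param metric numeric 3D array (`NA` allowed outside tissue).
#' @param file output path.
#' @param spacing_mm voxel spacing.
#' @export
write_metric <- function(metric, file, spacing_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(metric)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, file, datatype = "float")
  invisible(file)
}

#' Write/read tab-separated tables with a header row
#' @param x data.frame.
#' @param file path.
#' @rdname tsv
#' @export
write_tsv <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname tsv
#' @export
read_tsv <- function(file) {
  read.delim(file, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read/write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated: name, description, gene ids.
#'
#' @param file path.
#' @rdname gmt
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  sets
}

#' @param sets named list of character vectors.
#' @rdname gmt
#' @export
write_gmt <- function(sets, file) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, file)
  invisible(file)
}

write_json_summary <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Write a ring atlas as a labelled NIfTI plus a JSON sidecar of bounds
#'
#' @param atlas a [build_rings()] atlas.
#' @param file output NIfTI path; the sidecar replaces the extension by
#'   `.json`.
#' @param spacing_mm voxel spacing.
#' @export
write_ring_atlas <- function(atlas, file, spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(atlas, "ring_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, file, datatype = "int16")
  side <- sub("\\.nii(\\.gz)?$", ".json", file)
  write_json_summary(list(thickness_mm = atlas$thickness_mm,
                          n_rings = atlas$n_rings,
                          start_mm = atlas$start_mm,
                          bounds = atlas$bounds_mm), side)
  invisible(c(file, side))
}
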