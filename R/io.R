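#' Read a diffusion-weighted NIfTI stack
#'
#' Thin wrapper over [RNifti::readNifti()]; the returned image keeps its
#' affine/orientation metadata and behaves as a plain array for computation.
#'
#' @param path Path to a NIfTI file (`.nii` or `.nii.gz`); 2-D images are
#'   accepted because the format drops trailing singleton dimensions.
#' @return An `RNifti` `niftiImage`.
#' @export
load_dwi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (!length(dim(img)) %in% 2:4)
    stop("expected a 2-D to 4-D image, got ", length(dim(img)), " dimensions")
  img
}

#' Read an FSL-style b-value file
#'
#' Whitespace-separated b-values (s/mm^2) on one line.
#'
#' @param path Path to the text file.
#' @return Numeric vector of b-values.
#' @export
load_bvals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
  if (length(vals) == 0 || any(is.na(vals)))
    stop("malformed b-value file: ", path)
  if (any(vals < 0)) stop("negative b-values in ", path)
  vals
}

#' Read and write decay-curve CSV files
#'
#' CSV with header `b,signal` (b in s/mm^2); `save_curve()` writes the same
#' format, so the pair round-trips losslessly to printed precision.
#'
#' @param path CSV file path.
#' @param curve A [decay_curve()].
#' @return `load_curve()` returns a [decay_curve()]; `save_curve()` returns
#'   `path` invisibly.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
load_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("b", "signal") %in% names(df)))
    stop("decay-curve CSV needs columns 'b' and 'signal': ", path)
  decay_curve(df$b, df$signal)
}

#' @rdname curve_io
#' @export
save_curve <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  utils::write.csv(data.frame(b = curve$b, signal = curve$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write parameter maps to a directory of NIfTI files
#'
#' One 3-D NIfTI per map (`alpha.nii.gz`, `D.nii.gz`, `Kmlf.nii.gz`,
#' `Kapp.nii.gz`, `adc.nii.gz`, `mask.nii.gz`; all-`NA` maps are skipped),
#' 32-bit float, plus a JSON sidecar `fit.json` recording the fit provenance
#' (model, bounds, sigma, seed, b-values, convergence counts). When
#' `reference` is given (the input DWI image), its spatial metadata is
#' copied onto every output map.
#'
#' @param maps A `"parameter_maps"` object.
#' @param dir Output directory (created if needed).
#' @param reference Optional `niftiImage` (or path) supplying the affine.
#' @return The directory path, invisibly.
#' @export
save_maps <- function(maps, dir, reference = NULL) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(reference)) reference <- load_dwi(reference)
  files <- c(alpha = "alpha.nii.gz", D = "D.nii.gz", K_mlf = "Kmlf.nii.gz",
             K_app = "Kapp.nii.gz", adc = "adc.nii.gz")
  for (nm in names(files)) {
    if (all(is.na(maps[[nm]]))) next
    img <- maps[[nm]]
    if (!is.null(reference))
      img <- RNifti::asNifti(img, reference = reference)
    RNifti::writeNifti(img, file.path(dir, files[[nm]]), datatype = "float")
  }
  msk <- maps$mask + 0
  if (!is.null(reference)) msk <- RNifti::asNifti(msk, reference = reference)
  RNifti::writeNifti(msk, file.path(dir, "mask.nii.gz"), datatype = "float")

  meta <- attr(maps, "meta")
  conv <- maps$converged[maps$mask]
  sidecar <- list(model = meta$model, sigma = meta$sigma, seed = meta$seed,
                  bvals = meta$bvals, fit_s0 = meta$fit_s0,
                  bounds = list(names = meta$bounds$names,
                                lower = meta$bounds$lower,
                                upper = meta$bounds$upper),
                  n_voxels = meta$n_voxels, n_failed = meta$n_failed,
                  n_converged = sum(conv == 1, na.rm = TRUE))
  jsonlite::write_json(sidecar, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a phantom to disk as DWI + bvals + truth maps
#'
#' Companion to [make_phantom()] for command-line use: writes `dwi.nii.gz`
#' (4-D float stack), `bvals.txt`, a full-grid `mask.nii.gz`, and the
#' ground-truth maps (`truth_alpha.nii.gz`, `truth_D.nii.gz`,
#' `truth_K.nii.gz`, `truth_label.nii.gz`).
#'
#' @param phantom The list returned by [make_phantom()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
save_phantom <- function(phantom, dir) {
  stopifnot(is.list(phantom), !is.null(phantom$stack))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(phantom$stack, file.path(dir, "dwi.nii.gz"),
                     datatype = "float")
  writeLines(paste(phantom$spec$b_values, collapse = " "),
             file.path(dir, "bvals.txt"))
  RNifti::writeNifti(array(1, dim(phantom$truth$label_map)),
                     file.path(dir, "mask.nii.gz"), datatype = "float")
  tr <- phantom$truth
  RNifti::writeNifti(tr$alpha_true, file.path(dir, "truth_alpha.nii.gz"),
                     datatype = "float")
  RNifti::writeNifti(tr$D_true, file.path(dir, "truth_D.nii.gz"),
                     datatype = "double")
  RNifti::writeNifti(tr$K_true, file.path(dir, "truth_K.nii.gz"),
                     datatype = "float")
  RNifti::writeNifti(tr$label_map + 0, file.path(dir, "truth_label.nii.gz"),
                     datatype = "float")
  invisible(dir)
}
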