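#' Write a DWI volume as NIfTI-1 with FSL-style gradient files
#'
#' The 4-D signal array is written to `<path>.nii` (RAS-positive affine
#' built from the voxel size), the b-values to a sibling `<path>.bval`
#' (one space-separated row) and the gradient directions to `<path>.bvec`
#' (three rows of space-separated components, FSL convention).
#'
#' @param dwi a [dwi_volume()].
#' @param path output stem (or a `.nii` path; the extension is handled).
#' @param compress write `.nii.gz` instead of `.nii`.
#'
#' @return The NIfTI path, invisibly.
#' @export
write_dwi <- function(dwi, path, compress = FALSE) {
  stopifnot(inherits(dwi, "dwi_volume"))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  nii_path <- paste0(stem, if (compress) ".nii.gz" else ".nii")
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, nii_path)
  writeLines(paste(format(dwi$gtab$bvals, trim = TRUE), collapse = " "),
             paste0(stem, ".bval"))
  bv <- apply(dwi$gtab$bvecs, 1, function(row)
    paste(format(row, trim = TRUE, digits = 15), collapse = " "))
  writeLines(bv, paste0(stem, ".bvec"))
  invisible(nii_path)
}

#' Read a DWI volume and its gradient table
#'
#' Reads `<stem>.nii[.gz]` plus sibling `<stem>.bval` / `<stem>.bvec` files.
#' Errors if the gradient entries do not match the number of volumes;
#' non-unit weighted b-vectors trigger a warning and are renormalized (via
#' [gradient_table()]).
#'
#' @param path the NIfTI path or its stem.
#'
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(path) {
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  nii_path <- if (file.exists(paste0(stem, ".nii"))) paste0(stem, ".nii")
              else paste0(stem, ".nii.gz")
  if (!file.exists(nii_path)) stop("no NIfTI file at stem '", stem, "'")
  img <- RNifti::readNifti(nii_path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4L) stop("expected a 4-D DWI volume")
  gtab <- read_gradient_table(paste0(stem, ".bval"), paste0(stem, ".bvec"))
  if (length(gtab$bvals) != dim(data)[4]) {
    stop(sprintf("format error: %d gradient entries vs %d volumes",
                 length(gtab$bvals), dim(data)[4]))
  }
  dwi_volume(data, RNifti::pixdim(img)[1:3], gtab)
}

#' Read FSL-style bval/bvec files
#'
#' @param bval_path one row of space-separated b-values.
#' @param bvec_path three rows of space-separated direction components.
#'
#' @return A [gradient_table()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L) stop("bvec file must have exactly 3 rows")
  bvecs <- do.call(rbind, lapply(rows, function(r)
    scan(text = r, quiet = TRUE)))
  gradient_table(bvals, bvecs)
}

#' Write a ground-truth tensor field as a 6-volume NIfTI
#'
#' Component order (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) along the 4th dimension.
#'
#' @param field a [tensor_field()].
#' @param path output `.nii` path.
#' @return The path, invisibly.
#' @export
write_tensor_field <- function(field, path) {
  stopifnot(inherits(field, "tensor_field"))
  img <- RNifti::asNifti(field$D)
  RNifti::pixdim(img) <- c(field$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 6-volume tensor-field NIfTI
#'
#' @param path `.nii` path written by [write_tensor_field()].
#' @return A [tensor_field()].
#' @export
read_tensor_field <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4L || dim(data)[4] != 6L) {
    stop("expected a 4-D NIfTI with 6 tensor-component volumes")
  }
  tensor_field(data, RNifti::pixdim(img)[1:3])
}

#' Write / read a cohort table as CSV
#'
#' Header: `id,group,age_years,duration_months,frequency_per_day,alps_true`
#' plus `alps_measured` once the pipeline has filled it.
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @return The path (write) or the validated data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age_years", "duration_months",
            "frequency_per_day", "alps_true")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (!all(cohort$group %in% c("CAE", "HC"))) {
    stop("cohort schema error: group must be 'CAE' or 'HC'")
  }
  cohort
}

#' Load and validate a run configuration
#'
#' A single YAML (or JSON-compatible) file with optional sections `phantom`
#' (arguments to [phantom_spec()] except `regions`), `cohort` (arguments to
#' [cohort_config()]), `acquisition` (`n_directions`, `b`, `n_b0`, `s0`,
#' `snr`), and `roi` (`diameter`). Unknown keys raise an error naming them;
#' omitted sections fall back to package defaults.
#'
#' @param path YAML file path.
#'
#' @return A list with validated `phantom` ([phantom_spec()]), `cohort`
#'   ([cohort_config()]), `acquisition`, and `roi` entries.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("phantom", "cohort", "acquisition", "roi", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("run config: unknown section(s) ", paste(extra, collapse = ", "),
         "; expected ", paste(known, collapse = ", "))
  }
  check_args <- function(given, fn, what) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("run config (%s): unknown key(s) %s", what,
                   paste(bad, collapse = ", ")))
    }
    given
  }
  phantom <- do.call(phantom_spec,
                     check_args(raw$phantom %||% list(), phantom_spec, "phantom"))
  cohort_args <- raw$cohort %||% list()
  if (!is.null(raw$seed) && is.null(cohort_args$seed)) {
    cohort_args$seed <- raw$seed
  }
  cohort <- do.call(cohort_config,
                    check_args(cohort_args, cohort_config, "cohort"))
  acq <- utils::modifyList(list(n_directions = 30L, b = 1000, n_b0 = 1L,
                                s0 = 1000, snr = 30),
                           raw$acquisition %||% list())
  if (acq$n_directions < 6) stop("run config (acquisition): n_directions < 6")
  if (!is.null(acq$snr) && acq$snr <= 0) stop("run config (acquisition): snr must be > 0 or null")
  roi <- utils::modifyList(list(diameter = 5), raw$roi %||% list())
  if (roi$diameter <= 0) stop("run config (roi): diameter must be positive")
  list(phantom = phantom, cohort = cohort, acquisition = acq, roi = roi)
}

#' Write the resolved run configuration into an output directory
#'
#' Serializes the configuration next to the results it produced, so every
#' output directory records the exact conditions (including seeds) that
#' generated it.
#'
#' @param config list as returned by [read_run_config()] (or the raw list).
#' @param dir output directory.
#' @return The file path, invisibly.
#' @export
write_run_config <- function(config, dir) {
  ser <- list(
    phantom = config$phantom[c("grid_shape", "voxel_size", "d_parallel",
                               "d_perp", "d_background")],
    cohort = unclass(config$cohort),
    acquisition = config$acquisition,
    roi = config$roi)
  path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(ser, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
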