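#' The DTI-ALPS index
#'
#' index = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc): x-axis
#' diffusivity (along the perivascular space, perpendicular to both the
#' projection and association fibers) normalized by the diffusivity
#' perpendicular to both the fibers and the perivascular axis. The ratio is
#' scale-invariant and equals 1 for an isotropic field.
#'
#' @param dxx_proj,dyy_proj x- and y-axis diffusivities in the projection
#'   ROI, mm^2/s.
#' @param dxx_assoc,dzz_assoc x- and z-axis diffusivities in the association
#'   ROI, mm^2/s.
#'
#' @return The ALPS index (dimensionless).
#' @export
#' @examples
#' compute_alps(0.58e-3, 0.4e-3, 0.58e-3, 0.4e-3)  # 1.45
compute_alps <- function(dxx_proj, dyy_proj, dxx_assoc, dzz_assoc) {
  if (dyy_proj <= 0 || dzz_assoc <= 0) {
    stop("compute_alps: denominator diffusivities must be positive")
  }
  mean(c(dxx_proj, dxx_assoc)) / mean(c(dyy_proj, dzz_assoc))
}

#' Per-subject ALPS measurement from a DWI volume
#'
#' End-to-end single-subject procedure: tensor fit (log-linear least
#' squares), ROI placement (automatic from the phantom geometry or explicit
#' `roi_spec`s), per-axis diffusivity extraction, and the ALPS index.
#'
#' @param dwi a [dwi_volume()].
#' @param gtab gradient table; defaults to the one carried by `dwi`.
#' @param phantom_spec a [phantom_spec()] for automatic ROI placement, or
#'   `NULL` when `rois` is given.
#' @param rois optional named list with `projection` and `association`
#'   [roi_spec()]s (manual mode for non-phantom data).
#' @param diameter ROI diameter in mm for automatic placement.
#' @param fit_slice_only if `TRUE` (default) restrict the tensor fit to the
#'   ROI slice; the ALPS result is identical and the fit is faster.
#'
#' @return An object of class `alps_measurement`: list with the four ROI
#'   diffusivities (`dxx_proj`, `dyy_proj`, `dxx_assoc`, `dzz_assoc`,
#'   mm^2/s), voxel counts `n_voxels` per ROI, and `alps`.
#' @export
run_subject_pipeline <- function(dwi, gtab = dwi$gtab, phantom_spec = NULL,
                                 rois = NULL, diameter = 5,
                                 fit_slice_only = TRUE) {
  if (is.null(rois)) {
    if (is.null(phantom_spec)) {
      stop("subject pipeline: provide either a phantom_spec or explicit rois")
    }
    rois <- tryCatch(place_rois_auto(phantom_spec, diameter = diameter),
                     error = function(e) stop("ROI placement stage: ",
                                              conditionMessage(e)))
  }
  if (!all(c("projection", "association") %in% names(rois))) {
    stop("rois must name 'projection' and 'association'")
  }
  grid_shape <- dim(dwi$data)[1:3]
  masks <- lapply(rois, roi_mask, grid_shape = grid_shape,
                  voxel_size = dwi$voxel_size)
  fit_mask <- NULL
  if (fit_slice_only) {
    fit_mask <- array(FALSE, dim = grid_shape)
    slices <- unique(vapply(rois, `[[`, integer(1), "slice_index"))
    fit_mask[, , slices] <- TRUE
  }
  field <- tryCatch(fit_tensor(dwi, gtab, mask = fit_mask),
                    error = function(e) stop("tensor fit stage: ",
                                             conditionMessage(e)))
  dp <- tryCatch(extract_axis_diffusivities(field, masks$projection),
                 error = function(e) stop("extraction stage (projection): ",
                                          conditionMessage(e)))
  da <- tryCatch(extract_axis_diffusivities(field, masks$association),
                 error = function(e) stop("extraction stage (association): ",
                                          conditionMessage(e)))
  structure(list(
    dxx_proj = unname(dp["dxx"]), dyy_proj = unname(dp["dyy"]),
    dxx_assoc = unname(da["dxx"]), dzz_assoc = unname(da["dzz"]),
    n_voxels = c(projection = attr(dp, "n_voxels"),
                 association = attr(da, "n_voxels")),
    alps = compute_alps(dp["dxx"], dp["dyy"], da["dxx"], da["dzz"])),
    class = "alps_measurement")
}

#' @export
print.alps_measurement <- function(x, ...) {
  cat(sprintf(paste0(
    "ALPS measurement\n",
    "  projection ROI  (%2d vox): Dxx = %.4g, Dyy = %.4g mm^2/s\n",
    "  association ROI (%2d vox): Dxx = %.4g, Dzz = %.4g mm^2/s\n",
    "  ALPS index = %.4f\n"),
    x$n_voxels["projection"], x$dxx_proj, x$dyy_proj,
    x$n_voxels["association"], x$dxx_assoc, x$dzz_assoc, x$alps))
  invisible(x)
}

#' Simulate and measure one subject
#'
#' Convenience wrapper: embed a known ALPS value in a phantom, simulate the
#' DWI acquisition, and run the measurement pipeline.
#'
#' @param spec a [phantom_spec()].
#' @param alps_true ground-truth ALPS index for the phantom.
#' @param gtab gradient table (default the 30-direction b = 1000 scheme).
#' @param s0 b0 signal amplitude.
#' @param snr Rician SNR on the b0 signal, or `NULL` for noiseless data.
#' @param seed noise seed.
#'
#' @return An `alps_measurement` with attribute `alps_true`.
#' @export
simulate_and_measure <- function(spec, alps_true,
                                 gtab = build_gradient_table(30, 1000, 1),
                                 s0 = 1000, snr = 30, seed = 0L) {
  field <- make_phantom(spec, alps_true)
  dwi <- simulate_dwi(field, gtab, s0 = s0, snr = snr, seed = seed)
  m <- run_subject_pipeline(dwi, gtab, phantom_spec = spec)
  attr(m, "alps_true") <- alps_true
  m
}

#' Measure a whole cohort of simulated subjects
#'
#' Builds one phantom per subject from its true ALPS value, simulates the
#' acquisition at the given SNR with a per-subject noise seed derived from
#' `seed`, runs the measurement pipeline, and fills `alps_measured`.
#'
#' @param cohort data frame from [sample_cohort()] (needs columns `id`,
#'   `alps_true`).
#' @param spec a [phantom_spec()].
#' @param gtab gradient table.
#' @param s0 b0 amplitude.
#' @param snr Rician SNR, or `NULL` for noiseless.
#' @param seed base seed; subject k uses `seed + k`.
#'
#' @return The cohort data frame with an `alps_measured` column.
#' @export
measure_cohort <- function(cohort, spec = phantom_spec(),
                           gtab = build_gradient_table(30, 1000, 1),
                           s0 = 1000, snr = 30, seed = 0L) {
  stopifnot(is.data.frame(cohort), "alps_true" %in% names(cohort))
  cohort$alps_measured <- vapply(seq_len(nrow(cohort)), function(k) {
    simulate_and_measure(spec, cohort$alps_true[k], gtab, s0 = s0, snr = snr,
                         seed = as.integer(seed) + k)$alps
  }, numeric(1))
  cohort
}
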