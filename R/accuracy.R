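#' Cross-method correlation of paired morphometric values
#'
#' Pearson r per metric between a reference chain (micro-CT, on x) and a
#' test chain (MRI, on y), with the least-squares slope and intercept and
#' identity-line residual summaries reported alongside: r alone is blind
#' to a constant bias (a pairing with `b = a + 100` still has r = 1), so
#' the fit and residuals make such offsets visible while r stays the
#' headline number for comparability.
#'
#' @param pairs data.frame with columns `specimen`, `metric`,
#'   `value_ref`, `value_test`
#' @return data.frame, one row per metric: `pearson_r`, `slope`,
#'   `intercept`, `n`, `mean_abs_residual`, `max_abs_residual` (residuals
#'   against the identity line)
#' @export
crossMethodCorrelation <- function(pairs) {
  stopifnot(all(c("specimen", "metric", "value_ref", "value_test") %in%
                  names(pairs)))
  out <- lapply(split(pairs, pairs$metric), function(d) {
    if (nrow(d) < 3L)
      stop("need >= 3 specimens for a correlation (metric ", d$metric[1],
           ")")
    if (sd(d$value_ref) == 0 || sd(d$value_test) == 0)
      stop("r undefined: constant series for metric ", d$metric[1])
    fit <- lm(value_test ~ value_ref, data = d)
    res <- d$value_test - d$value_ref
    data.frame(metric = d$metric[1],
               pearson_r = cor(d$value_ref, d$value_test),
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               n = nrow(d),
               mean_abs_residual = mean(abs(res)),
               max_abs_residual = max(abs(res)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' One-voxel thickness error band
#'
#' Per-specimen absolute thickness differences between the two chains and
#' the fraction falling within `voxel_ref` mm — the one-voxel error band
#' of the MRI acquisition (0.45 mm in-plane by default). The bound is
#' closed: a difference of exactly `voxel_ref` counts as inside.
#'
#' @param th_ref,th_test numeric vectors of Cg.Th per specimen (mm)
#' @param specimen optional labels
#' @param voxel_ref band half-width in mm (default 0.45)
#' @return list with `differences` (data.frame) and `fraction_within`
#' @export
oneVoxelBand <- function(th_ref, th_test, specimen = NULL,
                         voxel_ref = 0.45) {
  stopifnot(length(th_ref) == length(th_test))
  if (is.null(specimen)) specimen <- paste0("P", seq_along(th_ref))
  d <- th_test - th_ref
  within <- abs(d) <= voxel_ref + 1e-12
  list(differences = data.frame(specimen = specimen, th_ref = th_ref,
                                th_test = th_test, difference = d,
                                within_band = within,
                                stringsAsFactors = FALSE),
       fraction_within = mean(within))
}

#' Two-chain accuracy study
#'
#' For every specimen, runs morphometry on the MRI-chain mask and on the
#' micro-CT chain (a grayscale volume pushed through [segmentCT()], or a
#' ready CT mask), then reports per-metric cross-method correlations and
#' the one-voxel thickness band.
#'
#' @param specimens named list; each element needs `mri_mask` (a
#'   [VoxelGrid-class]) and either `ct` (a [GrayscaleVolume-class]) or
#'   `ct_mask` (a [VoxelGrid-class])
#' @param ct_params [CtSegmentationParams-class] for the CT chain
#' @param voxel_ref thickness band half-width in mm
#' @param isotropic_target analysis spacing passed to [morphometryAll()]
#' @return list with `pairs` (long data.frame), `correlations`,
#'   `thickness_band`, `morphometry`
#' @export
accuracyStudy <- function(specimens, ct_params = ctParams(),
                          voxel_ref = 0.45, isotropic_target = NULL) {
  ids <- names(specimens)
  if (is.null(ids)) ids <- paste0("P", seq_along(specimens))
  if (length(specimens) < 3L)
    stop(">= 3 specimens required for correlation")
  rows <- list()
  for (i in seq_along(specimens)) {
    sp <- specimens[[i]]
    if (is.null(sp$mri_mask))
      stop("specimen ", ids[i], " is missing the MRI chain")
    if (is.null(sp$ct) && is.null(sp$ct_mask))
      stop("specimen ", ids[i], " is missing the CT chain")
    ct_mask <- if (!is.null(sp$ct_mask)) sp$ct_mask else
      segmentCT(sp$ct, ct_params)
    m_mri <- morphometryAll(sp$mri_mask, paste0(ids[i], "/mri"),
                            isotropic_target)
    m_ct <- morphometryAll(ct_mask, paste0(ids[i], "/ct"),
                           isotropic_target)
    rows[[i]] <- data.frame(
      specimen = ids[i],
      metric = c("cg_v", "cg_s", "cg_th"),
      value_ref = c(m_ct@cg_v, m_ct@cg_s, m_ct@cg_th),
      value_test = c(m_mri@cg_v, m_mri@cg_s, m_mri@cg_th),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  th <- pairs[pairs$metric == "cg_th", ]
  list(pairs = pairs,
       correlations = crossMethodCorrelation(pairs),
       thickness_band = oneVoxelBand(th$value_ref, th$value_test,
                                     th$specimen, voxel_ref),
       morphometry = pairs)
}
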