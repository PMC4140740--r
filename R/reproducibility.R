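#' Glüer precision errors of repeated measurements
#'
#' Per-subject standard deviations (with the m - 1 denominator) are pooled
#' as root mean squares: `PE_SD = sqrt(mean(SD_j^2))` in metric units, and
#' `PE_%CV = 100 * sqrt(mean((SD_j / mean_j)^2))` as a percentage of the
#' coefficient of variation. Degrees of freedom are n (m - 1); the report
#' flags whether they reach the recommended minimum of 27.
#'
#' @param table a [RepeatedMeasuresTable-class]
#' @return a [PrecisionReport-class] (ICC slot left NA; see
#'   [iccAbsoluteSingle()])
#' @export
precisionError <- function(table) {
  stopifnot(is(table, "RepeatedMeasuresTable"))
  v <- table@values
  means_j <- rowMeans(v)
  if (any(means_j <= 0))
    stop("non-positive subject mean: %CV undefined for subject(s) ",
         paste(table@subject_ids[means_j <= 0], collapse = ", "))
  sd_j <- apply(v, 1, sd)
  n <- nrow(v); m <- ncol(v)
  new("PrecisionReport", metric_name = table@metric_name,
      mean = mean(v),
      pe_sd = sqrt(mean(sd_j^2)),
      pe_pct_cv = 100 * sqrt(mean((sd_j / means_j)^2)),
      dof = as.integer(n * (m - 1)),
      dof_ok = n * (m - 1) >= 27,
      icc = NA_real_)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way random-effects model, absolute agreement, single measurement
#' (McGraw-Wong ICC(A,1)): with mean squares for rows/subjects (MSR),
#' columns/raters (MSC) and residual (MSE), k raters and n subjects,
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`.
#' Negative values are reported as computed (not clamped): they flag the
#' degenerate situation where between-subject variance is small relative
#' to measurement variance.
#'
#' @param table a [RepeatedMeasuresTable-class]
#' @return the ICC (dimensionless, <= 1)
#' @export
iccAbsoluteSingle <- function(table) {
  stopifnot(is(table, "RepeatedMeasuresTable"))
  v <- table@values
  n <- nrow(v); k <- ncol(v)
  g <- mean(v)
  msr <- k * sum((rowMeans(v) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(v) - g)^2) / (k - 1)
  sse <- sum((v - g)^2) - k * sum((rowMeans(v) - g)^2) -
    n * sum((colMeans(v) - g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300) stop("ICC undefined: zero denominator")
  (msr - mse) / denom
}

.union_bbox <- function(a, b, pad = 2L) {
  u <- a | b
  idx <- which(u, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(a))
  list(lo = lo, hi = hi)
}

#' Voxel-wise Pearson correlation of two masks
#'
#' Correlation of the two binary indicator fields over the bounding box of
#' the union of foregrounds padded by 2 voxels (clamped to the array).
#' Restricting the domain to the union neighbourhood keeps the coefficient
#' from being inflated arbitrarily by empty background.
#'
#' @param a,b two [VoxelGrid-class] masks of the same scan (same shape and
#'   spacing)
#' @return Pearson r in `[-1, 1]`
#' @export
pairwisePearson <- function(a, b) {
  stopifnot(is(a, "VoxelGrid"), is(b, "VoxelGrid"))
  if (!identical(dim(a), dim(b)))
    stop("masks must share array shape")
  if (max(abs(voxelSpacing(a) - voxelSpacing(b))) > 1e-9)
    stop("masks must share spacing")
  da <- voxelData(a); db <- voxelData(b)
  if (!any(da) || !any(db)) stop("r undefined: empty mask")
  bb <- .union_bbox(da, db)
  ia <- da[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
  ib <- db[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
  va <- as.numeric(ia); vb <- as.numeric(ib)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("r undefined: constant field over the comparison domain")
  cor(va, vb)
}

#' Overlap map of two masks
#'
#' Labels every voxel as background (0), common (1), A-only (2) or B-only
#' (3) and reports the class fractions over the union, alongside the
#' pairwise Pearson correlation (NA when undefined).
#'
#' @param a,b two [VoxelGrid-class] masks (same shape and spacing)
#' @return list with `comparison` (a [PairwiseMaskComparison-class]) and
#'   `labels` (a [GrayscaleVolume-class] of class codes)
#' @export
overlapMap <- function(a, b) {
  stopifnot(is(a, "VoxelGrid"), is(b, "VoxelGrid"))
  if (!identical(dim(a), dim(b))) stop("masks must share array shape")
  da <- voxelData(a); db <- voxelData(b)
  if (!any(da) && !any(db)) stop("both masks empty")
  common <- da & db
  a_only <- da & !db
  b_only <- db & !da
  n_union <- sum(common) + sum(a_only) + sum(b_only)
  labels <- array(0, dim(da))
  labels[common] <- 1; labels[a_only] <- 2; labels[b_only] <- 3
  r <- tryCatch(pairwisePearson(a, b), error = function(e) NA_real_)
  cmp <- new("PairwiseMaskComparison", pearson_r = r,
             common_fraction = sum(common) / n_union,
             a_only_fraction = sum(a_only) / n_union,
             b_only_fraction = sum(b_only) / n_union)
  list(comparison = cmp,
       labels = GrayscaleVolume(labels, voxelSpacing(a), voxelOrigin(a)))
}

#' Full precision study over a subjects x raters mask collection
#'
#' Runs [morphometryAll()] on every mask, assembles
#' [RepeatedMeasuresTable-class]s for Cg.V, Cg.S and Cg.Th, and emits a
#' [PrecisionReport-class] (including ICC(A,1)) per metric plus, per
#' subject, all rater-pair mask comparisons and the mean and SD of the
#' pairwise Pearson r.
#'
#' @param masks nested list: `masks[[subject]][[rater]]` of
#'   [VoxelGrid-class]; every subject must have every rater (complete
#'   design)
#' @param isotropic_target analysis spacing passed to [morphometryAll()]
#' @param compare_masks compute pairwise voxel-wise comparisons (default
#'   TRUE; the morphometry tables alone are cheaper)
#' @return list with `morphometry` (data.frame), `reports` (named list of
#'   [PrecisionReport-class]), `pairwise` (data.frame),
#'   `pairwise_r_mean`, `pairwise_r_sd`
#' @export
precisionStudy <- function(masks, isotropic_target = NULL,
                           compare_masks = TRUE) {
  subjects <- names(masks)
  if (is.null(subjects) || !length(subjects))
    stop("masks must be a named list by subject")
  raters <- names(masks[[1]])
  if (is.null(raters) || length(raters) < 2L)
    stop("m_repeats < 2: need at least two raters/repeats per subject")
  missing <- unlist(lapply(subjects, function(s) {
    miss <- setdiff(raters, names(masks[[s]]))
    if (length(miss)) paste0(s, ":", miss) else character()
  }))
  if (length(missing))
    stop("incomplete design, missing cells: ",
         paste(missing, collapse = ", "))

  rows <- list()
  for (s in subjects)
    for (r in raters) {
      m <- morphometryAll(masks[[s]][[r]],
                          specimen_id = paste(s, r, sep = "/"),
                          isotropic_target = isotropic_target)
      rows[[paste(s, r)]] <- cbind(subject_id = s, rater_id = r,
                                   as.data.frame(m))
    }
  morpho <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  metrics <- c(cg_v = "cg_v_mm3", cg_s = "cg_s_mm2", cg_th = "cg_th_mm")
  reports <- lapply(names(metrics), function(mn) {
    col <- metrics[[mn]]
    tab <- matrix(morpho[[col]], nrow = length(subjects),
                  ncol = length(raters), byrow = TRUE,
                  dimnames = list(subjects, raters))
    rmt <- repeatedMeasures(tab, metric_name = mn)
    rep <- precisionError(rmt)
    rep@icc <- iccAbsoluteSingle(rmt)
    validObject(rep)
    rep
  })
  names(reports) <- names(metrics)

  pairwise <- NULL
  r_mean <- r_sd <- NA_real_
  if (compare_masks) {
    prs <- utils::combn(raters, 2, simplify = FALSE)
    pw <- list()
    for (s in subjects)
      for (p in prs) {
        om <- overlapMap(masks[[s]][[p[1]]], masks[[s]][[p[2]]])
        cmp <- om$comparison
        pw[[paste(s, p[1], p[2])]] <- data.frame(
          subject_id = s, rater_a = p[1], rater_b = p[2],
          pearson_r = cmp@pearson_r,
          common_fraction = cmp@common_fraction,
          a_only_fraction = cmp@a_only_fraction,
          b_only_fraction = cmp@b_only_fraction,
          stringsAsFactors = FALSE)
      }
    pairwise <- do.call(rbind, c(pw, list(make.row.names = FALSE)))
    r_mean <- mean(pairwise$pearson_r)
    r_sd <- sd(pairwise$pearson_r)
  }

  list(morphometry = morpho, reports = reports, pairwise = pairwise,
       pairwise_r_mean = r_mean, pairwise_r_sd = r_sd)
}
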