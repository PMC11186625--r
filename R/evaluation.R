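# Evaluation statistics for ex vivo volumetry: 2D Dice against manual
# slices, label volumes, GLM covariate correction, AUROC + Wilcoxon
# rank-sum group comparison, correlations against reference volumetry and
# Steiger tests for dependent correlations.

#' Per-label 2D Dice between two label images
#'
#' Dice overlap `2|A_l & B_l| / (|A_l| + |B_l|)` per label. A label absent
#' from both rasters is undefined and reported as `NA` (not 0 or 1), so it
#' can be excluded from aggregates.
#'
#' @param a,b integer label matrices of identical shape (0 = background).
#' @param labels integer vector of label ids to evaluate; defaults to all
#'   nonzero labels present in either image.
#' @return tibble with columns `label`, `dice`, `size_a`, `size_b`.
#' @export
#' @examples
#' a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
#' dice2d(a, a)
dice2d <- function(a, b, labels = NULL) {
  if (!identical(dim(a), dim(b)))
    stop("ShapeMismatch: label images differ in shape")
  if (is.null(labels))
    labels <- sort(unique(c(a[a != 0], b[b != 0])))
  out <- lapply(labels, function(l) {
    na <- sum(a == l); nb <- sum(b == l)
    d <- if (na + nb == 0) NA_real_ else 2 * sum(a == l & b == l) / (na + nb)
    tibble::tibble(label = l, dice = d, size_a = na, size_b = nb)
  })
  do.call(rbind, out)
}

#' Per-label volumes of a 3D segmentation
#'
#' @param labels integer 3D label array (0 = background).
#' @param voxel_size voxel dimensions in mm; scalar or length 3.
#' @return tibble with columns `label`, `n_voxels`, `volume_mm3`.
#' @export
label_volumes <- function(labels, voxel_size = 1) {
  stopifnot(all(voxel_size > 0))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  vv <- prod(voxel_size)
  tab <- table(labels[labels != 0])
  tibble::tibble(label = as.integer(names(tab)),
                 n_voxels = as.integer(tab),
                 volume_mm3 = as.numeric(tab) * vv)
}

#' Residualize volume columns against age and sex
#'
#' Replaces each region-volume column of a volume table by the residuals of
#' an ordinary least squares fit on `[1, age, sex]` (pooled over groups),
#' the general-linear-model correction applied before group comparison.
#'
#' @param table data frame with columns `age`, `sex` and the volume columns.
#' @param columns character vector of columns to residualize; defaults to
#'   all numeric columns other than `age`, `sex`, `group`, `case_id`.
#' @return the table with the named columns replaced by residuals.
#' @export
residualize <- function(table, columns = NULL) {
  stopifnot(all(c("age", "sex") %in% names(table)), nrow(table) >= 3)
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       c("age", "sex", "group", "case_id"))
  X <- cbind(1, table$age, as.numeric(table$sex))
  if (qr(X)$rank < 3)
    stop("RankDeficientDesign: age/sex design matrix is rank deficient")
  for (cl in columns) {
    fit <- stats::lm.fit(X, table[[cl]])
    table[[cl]] <- fit$residuals
  }
  table
}

#' Area under the ROC curve for a two-group comparison
#'
#' The normalized Mann-Whitney U statistic: the probability that a case
#' value exceeds a control value, counting ties as 1/2. 0.5 is chance,
#' 1.0 perfect separation; the non-parametric analogue of effect size.
#'
#' @param x control values.
#' @param y case values.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(1, 2, 3), c(2, 3, 4))  # 0.7778
auroc <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("EmptyGroup: both groups must be nonempty")
  r <- rank(c(x, y))
  ny <- length(y)
  U <- sum(r[seq_along(y) + length(x)]) - ny * (ny + 1) / 2
  U / (length(x) * ny)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact permutation p-value (mid-ranks for ties) when the smaller group
#' has at most `exact_max` observations and the combined sample at most
#' `exact_total`; otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y the two samples.
#' @param exact_max,exact_total limits for exact enumeration.
#' @return two-sided p-value in `(0, 1]`.
#' @export
ranksum_p <- function(x, y, exact_max = 8L, exact_total = 16L) {
  if (length(x) == 0 || length(y) == 0)
    stop("EmptyGroup: both groups must be nonempty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[nx + seq_len(ny)])     # rank sum of y
  EW <- ny * (N + 1) / 2
  if (min(nx, ny) <= exact_max && N <= exact_total) {
    # full enumeration of rank assignments (handles ties via mid-ranks)
    sets <- utils::combn(N, ny)
    sums <- colSums(matrix(r[sets], nrow = ny))
    obs <- abs(W - EW)
    return(mean(abs(sums - EW) >= obs - 1e-12))
  }
  ties <- table(r)
  sig2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(W - EW) - 0.5) / sqrt(sig2)   # continuity corrected
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Pearson correlation with degeneracy checks
#'
#' @param u,v numeric vectors of equal length (>= 3).
#' @return sample correlation in `[-1, 1]`.
#' @export
pearson_r <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 3)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("ZeroVariance: correlation undefined for constant input")
  stats::cor(u, v)
}

#' Steiger test for two dependent correlations sharing one variable
#'
#' Compares `r_jk` and `r_jh` (both involving the common variable `j`)
#' measured on the same sample of size `n`, accounting for the dependency
#' through `r_kh`. Uses Fisher z-transforms with the pooled-correlation
#' covariance term; the statistic is standard normal under the null of
#' equal population correlations.
#'
#' @param r_jk,r_jh the two correlations being compared.
#' @param r_kh correlation between the two non-shared variables.
#' @param n sample size (>= 4).
#' @return list with `z` and two-sided `p`.
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n) {
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1))
    stop("InvalidCorrelation: correlations must lie strictly inside (-1, 1)")
  # the three correlations must form a positive semi-definite matrix
  R3 <- rbind(c(1, r_jk, r_jh), c(r_jk, 1, r_kh), c(r_jh, r_kh, 1))
  if (min(eigen(R3, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("InvalidCorrelation: the three correlations are jointly infeasible")
  stopifnot(n >= 4)
  z1 <- atanh(r_jk); z2 <- atanh(r_jh)
  rb <- (r_jk + r_jh) / 2
  # covariance of the dependent correlations (pooled-r form)
  cov_term <- (r_kh * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r_kh^2)) /
    (1 - rb^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  list(z = z, p = min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE)))
}

#' Group statistics over a volume table
#'
#' The group-comparison pipeline for region volumes: optional averaging of
#' left/right hemispheres, optional exclusion of unreliable regions,
#' age/sex residualization by a pooled general linear model, then per
#' region the AUROC and the two-sided Wilcoxon rank-sum p-value comparing
#' cases against controls. Raw p-values are reported by default; a
#' Bonferroni-adjusted column can be requested.
#'
#' @param table data frame with columns `case_id`, `group` (0 = control,
#'   1 = case, or a factor whose second level is the case group), `age`,
#'   `sex`, and one numeric column per region. Hemisphere pairs may be
#'   given as `<region>_left` / `<region>_right`.
#' @param exclude regions dropped before testing; by default the accumbens
#'   area and ventral diencephalon, whose segmentations have poor contrast.
#' @param correct_covariates residualize on age and sex first (default TRUE).
#' @param bonferroni add a Bonferroni-adjusted p-value column (default
#'   FALSE; raw p-values mirror standard reporting).
#' @return tibble of class `group_stats` with columns `region`, `auroc`,
#'   `p_value` (and `p_bonferroni` if requested).
#' @export
group_stats <- function(table,
                        exclude = c("accumbens", "ventral_dc"),
                        correct_covariates = TRUE,
                        bonferroni = FALSE) {
  stopifnot(all(c("group", "age", "sex") %in% names(table)))
  table <- average_hemispheres(table)
  regions <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                     c("age", "sex", "group", "case_id"))
  regions <- setdiff(regions, exclude)
  grp <- table$group
  if (is.factor(grp) || is.character(grp)) {
    lev <- unique(as.character(grp))
    grp <- as.integer(as.character(grp) == lev[2])
  }
  if (any(is.na(grp))) stop("group labels must not be missing")
  if (correct_covariates) table <- residualize(table, regions)
  res <- lapply(regions, function(rg) {
    x <- table[[rg]][grp == 0]; y <- table[[rg]][grp == 1]
    tibble::tibble(region = rg, auroc = auroc(x, y), p_value = ranksum_p(x, y))
  })
  out <- do.call(rbind, res)
  if (bonferroni)
    out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  class(out) <- c("group_stats", class(out))
  out
}

# Average <region>_left / <region>_right pairs into a single column; keeps
# unpaired columns as they are (hemisphere-only cases).
average_hemispheres <- function(table) {
  nms <- names(table)
  lefts <- grep("_left$", nms, value = TRUE)
  for (l in lefts) {
    base <- sub("_left$", "", l)
    r <- paste0(base, "_right")
    if (r %in% nms) {
      table[[base]] <- (table[[l]] + table[[r]]) / 2
      table[[l]] <- NULL; table[[r]] <- NULL
    }
  }
  table
}

#' Correlate two volumetry methods against a reference, with Steiger tests
#'
#' For every region, correlates each method's volumes with the reference
#' values and compares the two dependent correlations with a Steiger test.
#'
#' @param reference,method_a,method_b data frames of per-case region
#'   volumes with identical `case_id` ordering and region columns.
#' @param regions columns to analyze; defaults to shared numeric columns.
#' @return tibble with `region`, `r_a`, `r_b`, `steiger_z`, `steiger_p`.
#' @export
method_correlations <- function(reference, method_a, method_b,
                                regions = NULL) {
  if (is.null(regions))
    regions <- intersect(names(reference)[vapply(reference, is.numeric,
                                                 logical(1))],
                         intersect(names(method_a), names(method_b)))
  regions <- setdiff(regions, c("age", "sex", "group", "case_id"))
  n <- nrow(reference)
  out <- lapply(regions, function(rg) {
    ra <- pearson_r(method_a[[rg]], reference[[rg]])
    rb <- pearson_r(method_b[[rg]], reference[[rg]])
    rab <- pearson_r(method_a[[rg]], method_b[[rg]])
    st <- steiger_test(ra, rb, rab, n)
    tibble::tibble(region = rg, r_a = ra, r_b = rb,
                   steiger_z = st$z, steiger_p = st$p)
  })
  do.call(rbind, out)
}
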