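#' Median-of-ratios size factors
#'
#' Library-depth normalization for the negative-binomial screen. A pseudo
#' reference sample is built as the per-feature geometric mean over samples
#' (restricted to features with all-positive counts); each sample's factor is
#' the median ratio of its counts to the reference, rescaled so the factors
#' have geometric mean 1. If no feature is positive in every sample, the
#' function falls back to total-count ratios with a warning.
#'
#' @param counts expression matrix on the count scale.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_expr_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    sub <- counts[pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    f <- apply(sub / ref, 2, median)
  } else {
    warning("no feature with all-positive counts; ",
            "falling back to total-count size factors", call. = FALSE)
    f <- colSums(counts)
    if (any(f == 0)) stop("sample(s) with zero total counts", call. = FALSE)
  }
  f / exp(mean(log(f)))
}

#' Negative-binomial two-group Wald test (non-DE screen backend)
#'
#' A deliberately simple stand-in for a full DE engine: counts are normalized
#' by median-of-ratios size factors, a per-feature dispersion is estimated by
#' the method of moments pooled across the two groups (floored at 1e-8), and a
#' Wald statistic is formed as the log2 fold change (pseudocount 1/2) divided
#' by its delta-method standard error, with a two-sided p-value from the
#' normal reference. The model-based variance of each group mean,
#' (mu + alpha mu^2)/n, is floored at the group's empirical variance of the
#' mean so that dispersion underestimation at small n cannot deflate the
#' standard error; this keeps the null type-I error calibrated (~0.05 at
#' alpha = 0.05 for 10 vs 10 samples).
#'
#' Features that are all-zero in both groups get p = 1 by convention (no
#' evidence of differential expression). No shrinkage, no covariates: the
#' screen only needs a calibrated non-DE call at p > 0.1.
#'
#' @param counts expression matrix on the count scale.
#' @param design sample design data frame (`sample`, `group`, `condition`).
#' @param subtype group label of the case samples to compare against all
#'   control-condition samples.
#' @param sf optional precomputed size factors for `colnames(counts)`.
#' @return named numeric vector of two-sided p-values in `[0, 1]`.
#' @export
nb_two_group_test <- function(counts, design, subtype, sf = NULL) {
  validate_design(design, colnames(counts))
  design <- design[match(colnames(counts), design$sample), ]
  case <- design$sample[design$group == subtype & design$condition == "case"]
  ctrl <- design$sample[design$condition == "control"]
  if (length(case) < 2 || length(ctrl) < 2)
    stop("need >= 2 case and >= 2 control samples (subtype '", subtype, "')",
         call. = FALSE)
  sub <- counts[, c(case, ctrl), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(sub) else sf <- sf[colnames(sub)]
  q <- sweep(sub, 2, sf, "/")
  i1 <- seq_along(case); i0 <- length(case) + seq_along(ctrl)
  n1 <- length(i1); n0 <- length(i0)
  m1 <- rowMeans(q[, i1, drop = FALSE]); m0 <- rowMeans(q[, i0, drop = FALSE])
  v1 <- matrixStats::rowVars(q[, i1, drop = FALSE])
  v0 <- matrixStats::rowVars(q[, i0, drop = FALSE])
  # method-of-moments dispersion, df-weighted across groups
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, 0)
  a0 <- ifelse(m0 > 0, (v0 - m0) / m0^2, 0)
  alpha <- pmax(((n1 - 1) * a1 + (n0 - 1) * a0) / (n1 + n0 - 2), 1e-8)
  var1 <- pmax((m1 + alpha * m1^2) / n1, v1 / n1)
  var0 <- pmax((m0 + alpha * m0^2) / n0, v0 / n0)
  lfc <- log2((m1 + 0.5) / (m0 + 0.5))
  se2 <- var1 / ((m1 + 0.5)^2 * log(2)^2) + var0 / ((m0 + 0.5)^2 * log(2)^2)
  z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  p <- 2 * pnorm(-abs(z))
  p[m1 == 0 & m0 == 0] <- 1
  setNames(pmin(pmax(p, 0), 1), rownames(counts))
}

#' Retain features with no evidence of differential expression
#'
#' @param pvalues named numeric p-values in `[0, 1]`.
#' @param threshold retention threshold; a feature is kept iff p is strictly
#'   greater than it (default 0.1).
#' @return character vector of retained feature identifiers.
#' @export
nonde_filter <- function(pvalues, threshold = 0.1) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  names(pvalues)[!is.na(pvalues) & pvalues > threshold]
}

#' Intersect per-subtype feature sets
#'
#' @param sets list of character vectors, one per subtype.
#' @return features present in every set (order of the first set).
#' @export
intersect_subtypes <- function(sets) {
  if (length(sets) == 0) stop("need at least one subtype set", call. = FALSE)
  Reduce(intersect, sets)
}

#' High-expression filter against the pooled transcriptome
#'
#' A candidate is retained iff its mean log2(x + 1) across case samples
#' strictly exceeds the grand mean of log2(x + 1) over *all* features and case
#' samples, and likewise within control samples. The log scale matches the
#' pooled-transcriptome scatterplots the criterion mimics.
#'
#' @param expr expression matrix on the TPM or CPM scale.
#' @param design sample design data frame.
#' @param candidates feature identifiers to filter.
#' @return retained feature identifiers (possibly empty).
#' @export
high_expression_filter <- function(expr, design, candidates) {
  if (length(candidates) == 0) return(character(0))
  if (!expr_scale(expr) %in% c("TPM", "CPM", "abundance"))
    stop("high-expression filter expects normalized (TPM/CPM) values",
         call. = FALSE)
  validate_design(design, colnames(expr))
  lx <- log2p1(expr)
  keep <- candidates
  for (cond in c("case", "control")) {
    smp <- design$sample[design$condition == cond]
    pooled <- mean(lx[, smp, drop = FALSE])
    featmean <- rowMeans(lx[keep, smp, drop = FALSE])
    keep <- keep[featmean > pooled]
  }
  keep
}

#' Top-n features by mean expression
#'
#' @param expr expression matrix (normalized scale).
#' @param survivors features to rank.
#' @param n how many to keep (default 10); ties in the mean are broken by
#'   feature identifier.
#' @return up to `n` feature identifiers, most expressed first.
#' @export
select_top <- function(expr, survivors, n = 10) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(survivors) < n)
    message("only ", length(survivors), " survivors for top-", n, " selection")
  mu <- rowMeans(log2p1(expr[survivors, , drop = FALSE]))
  ord <- order(-mu, survivors)
  survivors[ord][seq_len(min(n, length(survivors)))]
}

#' Full candidate-identification cascade
#'
#' Runs, in order: median-of-ratios size factors, the per-subtype NB non-DE
#' test of each case group against all controls, retention at p > threshold,
#' intersection across subtypes, the pooled high-expression filter on the
#' normalized matrix, and top-n selection by mean expression.
#'
#' @param counts expression matrix on the count scale.
#' @param design sample design data frame.
#' @param norm normalized matrix (TPM or CPM) on the same features/samples.
#' @param p_threshold non-DE retention threshold (default 0.1, raw p-values).
#' @param top_n number of final candidates (default 10).
#' @return a list with per-subtype p-value matrix `pvalues`, a `result` data
#'   frame of per-feature flags (the screen result table), per-stage counts
#'   `stage_counts`, and the ordered `candidates`.
#' @export
screen_candidates <- function(counts, design, norm, p_threshold = 0.1,
                              top_n = 10) {
  validate_design(design, colnames(counts))
  subtypes <- sort(unique(design$group[design$condition == "case"]))
  if (length(subtypes) == 0) stop("no case groups in design", call. = FALSE)
  pmat <- sapply(subtypes, function(g) nb_two_group_test(counts, design, g))
  if (is.null(dim(pmat))) pmat <- matrix(pmat, ncol = length(subtypes),
                                         dimnames = list(rownames(counts), subtypes))
  sets <- lapply(subtypes, function(g) nonde_filter(pmat[, g], p_threshold))
  names(sets) <- subtypes
  universal <- intersect_subtypes(sets)
  high <- high_expression_filter(norm, design, universal)
  cands <- if (length(high) > 0) select_top(norm, high, top_n) else character(0)

  lx <- log2p1(norm)
  case_s <- design$sample[design$condition == "case"]
  ctrl_s <- design$sample[design$condition == "control"]
  res <- data.frame(
    feature = rownames(counts),
    mean_log_case = rowMeans(lx[, case_s, drop = FALSE]),
    mean_log_control = rowMeans(lx[, ctrl_s, drop = FALSE]),
    non_de_all_subtypes = rownames(counts) %in% universal,
    above_average_both = rownames(counts) %in% high,
    selected = rownames(counts) %in% cands,
    row.names = NULL, stringsAsFactors = FALSE
  )
  for (g in subtypes) res[[paste0("p_", g)]] <- pmat[, g]

  counts_per_stage <- c(
    input = nrow(counts),
    setNames(vapply(sets, length, 0L), paste0("non_de_", subtypes)),
    universal = length(universal),
    high_expression = length(high),
    candidates = length(cands)
  )
  list(pvalues = pmat, sets = sets, result = res,
       stage_counts = counts_per_stage, candidates = cands)
}
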