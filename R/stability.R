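#' Coefficient-of-variation stability
#'
#' CV_j = sd(A_j) / mean(A_j), with the sample (n-1) standard deviation,
#' computed on the *linear* normalized scale (TPM, CPM or 2^-Ct abundance).
#' Missing cells are excluded per feature; the number of exclusions is
#' messaged so silent degradation is visible.
#'
#' @param expr expression matrix on a normalized linear scale.
#' @return named numeric vector of CVs, one per feature.
#' @export
cv_stability <- function(expr) {
  n_ok <- rowSums(!is.na(expr))
  if (any(n_ok < 2))
    stop("feature(s) with < 2 non-missing values: ",
         paste(rownames(expr)[n_ok < 2], collapse = ", "), call. = FALSE)
  nmiss <- sum(is.na(expr))
  if (nmiss > 0) message("cv_stability: excluding ", nmiss, " missing cell(s)")
  mu <- rowMeans(expr, na.rm = TRUE)
  if (any(mu <= 0))
    stop("feature(s) with nonpositive mean: ",
         paste(rownames(expr)[mu <= 0], collapse = ", "), call. = FALSE)
  setNames(matrixStats::rowSds(expr, na.rm = TRUE) / mu, rownames(expr))
}

#' geNorm pairwise variation matrix
#'
#' For every feature pair (j, k), V_jk is the sample standard deviation over
#' samples of log2(a_ij / a_ik). V is symmetric, zero exactly when two
#' features are proportional across samples, and invariant to per-sample
#' scaling. With missing cells, each pair uses its complete samples (at least
#' two required).
#'
#' @param expr expression matrix with strictly positive values (apply a
#'   pseudocount first if zeros are present; see [stability_table()]).
#' @return symmetric numeric matrix with `NA` on the diagonal.
#' @export
pairwise_variation <- function(expr) {
  bad <- which(!is.na(expr) & expr <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("nonpositive value at (", rownames(expr)[bad[1, 1]], ", ",
         colnames(expr)[bad[1, 2]], "); add a pseudocount", call. = FALSE)
  if (ncol(expr) < 2) stop("need >= 2 samples", call. = FALSE)
  L <- log2(expr)
  n <- nrow(L)
  if (anyNA(L)) {
    V <- matrix(NA_real_, n, n, dimnames = list(rownames(L), rownames(L)))
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      d <- L[j, ] - L[k, ]
      d <- d[!is.na(d)]
      if (length(d) < 2)
        stop("< 2 complete samples for pair (", rownames(L)[j], ", ",
             rownames(L)[k], ")", call. = FALSE)
      V[j, k] <- V[k, j] <- sd(d)
    }
  } else {
    # sd(L_j - L_k)^2 = var_j + var_k - 2 cov_jk
    C <- stats::cov(t(L))
    d <- diag(C)
    V2 <- pmax(outer(d, d, "+") - 2 * C, 0)
    V <- sqrt(V2)
    diag(V) <- NA_real_
    dimnames(V) <- list(rownames(L), rownames(L))
  }
  V
}

#' geNorm average expression stability M
#'
#' M_j is the arithmetic mean of the pairwise variations V_jk over all other
#' candidate features k. Lower M means more stable; M < 1.5 is the
#' conventional acceptability bound for a reference gene. With exactly two
#' features, M_1 = M_2 = V_12.
#'
#' @param expr expression matrix with strictly positive values and >= 2
#'   features.
#' @return named numeric vector of M values.
#' @export
m_values <- function(expr) {
  if (nrow(expr) < 2) stop("M undefined for a single feature", call. = FALSE)
  V <- pairwise_variation(expr)
  rowMeans(V, na.rm = TRUE)
}

#' Combination stability AV (geometric mean of member M values)
#'
#' The stability of a multi-feature reference set is the geometric mean of
#' the members' M values; three equal members give back their common M, and
#' the result is invariant to member order. The three-member case is the
#' classic trio form; any size >= 2 is accepted.
#'
#' @param m named numeric vector of M values.
#' @param members feature identifiers (length >= 2) indexing `m`.
#' @return a list with `members` and the scalar `av`.
#' @export
av_combination <- function(m, members) {
  if (length(members) < 2) stop("a combination needs >= 2 members", call. = FALSE)
  miss <- setdiff(members, names(m))
  if (length(miss) > 0)
    stop("no M value for: ", paste(miss, collapse = ", "), call. = FALSE)
  mm <- m[members]
  if (any(!is.finite(mm)) || any(mm < 0))
    stop("member M values must be finite and >= 0", call. = FALSE)
  if (any(mm == 0)) {
    message("av_combination: member with M = 0; AV = 0 by limit convention")
    av <- 0
  } else {
    av <- exp(mean(log(mm)))
  }
  list(members = members, av = av)
}

# ordinal rank: 1 = smallest value, ties broken by identifier
ordinal_rank <- function(x, ids) {
  r <- integer(length(x))
  r[order(x, ids)] <- seq_along(x)
  r
}

#' Rank candidates by the CV + M rank sum
#'
#' Each feature gets an ordinal rank under CV and under M (1 = most stable;
#' ties within a metric broken by identifier), and the final rank orders
#' features by ascending rank sum. Rank-sum ties are broken by the lower M
#' value, then by identifier — a deterministic, documented policy (the
#' published tie order for such tables is not derivable from CV or M alone).
#'
#' @param cv named numeric vector of CV values.
#' @param m named numeric vector of M values over the same features.
#' @return data frame (one row per feature, sorted by `final_rank`) with
#'   columns `feature`, `cv`, `m`, `cv_rank`, `m_rank`, `rank_sum`,
#'   `final_rank`.
#' @export
rank_candidates <- function(cv, m) {
  if (is.null(names(cv)) || is.null(names(m)) ||
      !setequal(names(cv), names(m)) || length(cv) != length(m))
    stop("cv and m must be named over the same feature set", call. = FALSE)
  m <- m[names(cv)]
  ids <- names(cv)
  cv_rank <- ordinal_rank(cv, ids)
  m_rank <- ordinal_rank(m, ids)
  rank_sum <- cv_rank + m_rank
  final_rank <- integer(length(ids))
  final_rank[order(rank_sum, m, ids)] <- seq_along(ids)
  out <- data.frame(feature = ids, cv = unname(cv), m = unname(m),
                    cv_rank = cv_rank, m_rank = m_rank, rank_sum = rank_sum,
                    final_rank = final_rank, stringsAsFactors = FALSE)
  out <- out[order(out$final_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' NormFinder-style group-aware stability score
#'
#' Works on log2 values after removing per-sample (column) effects. For each
#' feature j and group g it measures the intergroup deviation
#' d_gj = mean of the centered values in g minus the feature's grand centered
#' mean, and the intragroup variance s2_gj. The stability score is the mean
#' over groups of |d_gj| + sqrt(s2_gj / n_g): a feature is penalized both for
#' shifting between groups and for intragroup noise. Lower = more stable.
#'
#' @param expr expression matrix with strictly positive values.
#' @param design sample design data frame; every group needs >= 2 samples and
#'   there must be >= 2 groups.
#' @return named numeric vector of nonnegative stability scores.
#' @export
normfinder_stability <- function(expr, design) {
  validate_design(design, colnames(expr))
  if (any(expr <= 0, na.rm = TRUE))
    stop("NormFinder scoring needs strictly positive values", call. = FALSE)
  design <- design[match(colnames(expr), design$sample), ]
  groups <- unique(design$group)
  sizes <- table(design$group)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2))
    stop("group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  L <- log2(expr)
  z <- sweep(L, 2, colMeans(L), "-")   # remove sample (column) effects
  grand <- rowMeans(z)
  score <- setNames(numeric(nrow(z)), rownames(z))
  for (g in groups) {
    idx <- design$group == g
    zg <- z[, idx, drop = FALSE]
    d <- rowMeans(zg) - grand
    s2 <- matrixStats::rowVars(zg)
    score <- score + abs(d) + sqrt(s2 / sum(idx))
  }
  score / length(groups)
}

#' Wilcoxon rank-sum comparison of two stability-score sets
#'
#' Compares, e.g., the CV (or M) values of discovered candidates against
#' those of classical housekeeping genes. Two-sided.
#'
#' @param candidate_scores numeric vector (nonempty).
#' @param housekeeping_scores numeric vector (nonempty).
#' @return list with `statistic` (W) and `p.value`.
#' @export
compare_stability_groups <- function(candidate_scores, housekeeping_scores) {
  if (length(candidate_scores) == 0 || length(housekeeping_scores) == 0)
    stop("both score lists must be nonempty", call. = FALSE)
  wt <- suppressWarnings(
    wilcox.test(candidate_scores, housekeeping_scores,
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Stability table: CV, M, optional NormFinder, and rank-sum ranks
#'
#' Convenience wrapper producing the per-candidate stability report. Scores
#' are computed on the linear normalized scale; if zeros are present a
#' pseudocount (default 1 unit of the matrix's scale) is added first, with a
#' loud message, so the log-ratio machinery stays defined.
#'
#' @param expr expression matrix (normalized linear scale) restricted to the
#'   candidate features.
#' @param design optional design table; required for the NormFinder scorer.
#' @param scorers subset of `c("cv", "m", "normfinder")`.
#' @param pseudocount value added when zeros are present (default 1).
#' @return data frame sorted by `final_rank`, with `mean_log_expr` (mean
#'   log2(x+1) across samples), CV/M columns and ranks, plus `normfinder`
#'   when requested.
#' @export
stability_table <- function(expr, design = NULL,
                            scorers = c("cv", "m"), pseudocount = 1) {
  scorers <- match.arg(scorers, c("cv", "m", "normfinder"), several.ok = TRUE)
  if (any(expr == 0, na.rm = TRUE)) {
    message("stability_table: zeros present; adding pseudocount ", pseudocount)
    sc <- expr_scale(expr)
    expr <- expr + pseudocount
    attr(expr, "scale") <- sc
  }
  cv <- cv_stability(expr)
  m <- m_values(expr)
  tab <- rank_candidates(cv, m)
  tab <- cbind(tab[1],
               mean_log_expr = rowMeans(log2p1(expr))[tab$feature],
               tab[-1])
  tab$expr_rank <- ordinal_rank(-tab$mean_log_expr, tab$feature)
  if ("normfinder" %in% scorers) {
    if (is.null(design))
      stop("NormFinder scoring needs a design table", call. = FALSE)
    nf <- normfinder_stability(expr, design)
    tab$normfinder <- unname(nf[tab$feature])
  }
  rownames(tab) <- NULL
  tab
}
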