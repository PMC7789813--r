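#' Simulation configuration for exosome-like count data
#'
#' The defaults describe the stated test world: 2000 features of which 5 are
#' planted stable reference candidates, three case groups of 8 serum-exosome
#' samples (subtype labels PAAD/CRC/HCC) plus 8 healthy controls (HC),
#' negative-binomial counts with Var = mu + dispersion * mu^2, per-sample
#' log-normal library-size factors (sigma 0.3), and i.i.d. per-group log2
#' effects of scale 1.0 on the unstable majority. Planted stable features
#' draw their baseline mean from the upper tail (quantile >= 0.9) of the
#' baseline log2-mean distribution, carry no group effect and have the low
#' stable dispersion, so a correct pipeline should recover them.
#'
#' @param n_features total number of features.
#' @param n_stable number of planted stable features (<= `n_features`).
#' @param groups data frame with columns `label`, `condition`, `n`.
#' @param baseline_log2_mean,baseline_log2_sd location/spread of the
#'   per-feature baseline mean on the log2 scale (counts around
#'   2^baseline_log2_mean).
#' @param dispersion_range_unstable range of NB dispersions for unstable
#'   features (drawn uniformly).
#' @param dispersion_stable NB dispersion of planted stable features.
#' @param group_effect_sd standard deviation, in log2-fold units, of the
#'   i.i.d. per-group effects on unstable features (0 = null world).
#' @param libsize_sigma sigma of the log-normal per-sample library factor.
#' @param high_expression_quantile planted features draw baseline means from
#'   above this quantile.
#' @param seed integer seed; one seed drives a documented per-stage stream.
#' @return a validated config list of class `sim_config`.
#' @export
simulation_config <- function(n_features = 2000,
                              n_stable = 5,
                              groups = data.frame(
                                label = c("PAAD", "CRC", "HCC", "HC"),
                                condition = c("case", "case", "case", "control"),
                                n = c(8L, 8L, 8L, 8L),
                                stringsAsFactors = FALSE),
                              baseline_log2_mean = 5,
                              baseline_log2_sd = 2,
                              dispersion_range_unstable = c(0.05, 0.6),
                              dispersion_stable = 0.05,
                              group_effect_sd = 1.0,
                              libsize_sigma = 0.3,
                              high_expression_quantile = 0.9,
                              seed = 1L) {
  cfg <- list(n_features = as.integer(n_features),
              n_stable = as.integer(n_stable), groups = groups,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              dispersion_range_unstable = dispersion_range_unstable,
              dispersion_stable = dispersion_stable,
              group_effect_sd = group_effect_sd,
              libsize_sigma = libsize_sigma,
              high_expression_quantile = high_expression_quantile,
              seed = as.integer(seed))
  if (cfg$n_features < 1) stop("n_features must be >= 1", call. = FALSE)
  if (cfg$n_stable < 0 || cfg$n_stable > cfg$n_features)
    stop("need 0 <= n_stable <= n_features", call. = FALSE)
  if (!all(c("label", "condition", "n") %in% colnames(groups)))
    stop("groups needs columns label, condition, n", call. = FALSE)
  if (!any(groups$condition == "case") || !any(groups$condition == "control"))
    stop("need at least one case and one control group", call. = FALSE)
  if (any(groups$n < 1)) stop("every group needs >= 1 sample", call. = FALSE)
  if (cfg$dispersion_stable <= 0 || any(cfg$dispersion_range_unstable <= 0))
    stop("dispersions must be positive", call. = FALSE)
  if (cfg$group_effect_sd < 0 || cfg$libsize_sigma < 0)
    stop("group_effect_sd and libsize_sigma must be >= 0", call. = FALSE)
  if (cfg$high_expression_quantile <= 0 || cfg$high_expression_quantile >= 1)
    stop("high_expression_quantile must be in (0, 1)", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# per-stage seed stream: fixed documented offsets from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(means = 101L, dispersion = 211L, effects = 307L,
               libsize = 401L, counts = 503L, ct = 601L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate an exosome-like count dataset with planted stable features
#'
#' Counts are negative binomial with mean
#' mu_j * 2^(group effect) * library factor and Var = mu + dispersion * mu^2
#' (so `size = 1/dispersion` in R's parameterization). Fully reproducible
#' from the config seed.
#'
#' @param config a [simulation_config()] object (or arguments for one).
#' @return list with `counts` (count-scale expression matrix), `design`
#'   (sample design data frame), `truth` (data frame with
#'   `is_planted_stable`), and `lengths` (uniform 1000 bp, for TPM plumbing).
#' @export
simulate_counts <- function(config = simulation_config()) {
  if (!inherits(config, "sim_config"))
    stop("config must come from simulation_config()", call. = FALSE)
  nf <- config$n_features; ns <- config$n_stable
  g <- config$groups
  m <- sum(g$n)
  stable <- seq_len(nf) <= ns   # planted features first; names hide nothing
  feats <- sprintf("gene%04d", seq_len(nf))
  samples <- unname(unlist(mapply(function(lab, n) paste0(lab, "_", seq_len(n)),
                                  g$label, g$n, SIMPLIFY = FALSE)))
  grp_of <- rep(g$label, g$n)
  cond_of <- rep(g$condition, g$n)

  set.seed(stage_seed(config$seed, "means"))
  log2mu <- rnorm(nf, config$baseline_log2_mean, config$baseline_log2_sd)
  if (ns > 0) {
    u <- runif(ns, config$high_expression_quantile, 1)
    log2mu[stable] <- qnorm(u, config$baseline_log2_mean, config$baseline_log2_sd)
  }
  mu <- 2^log2mu

  set.seed(stage_seed(config$seed, "dispersion"))
  disp <- runif(nf, config$dispersion_range_unstable[1],
                config$dispersion_range_unstable[2])
  disp[stable] <- config$dispersion_stable

  set.seed(stage_seed(config$seed, "effects"))
  eff <- matrix(rnorm(nf * nrow(g), 0, config$group_effect_sd), nf, nrow(g),
                dimnames = list(feats, g$label))
  eff[stable, ] <- 0

  set.seed(stage_seed(config$seed, "libsize"))
  lib <- exp(rnorm(m, 0, config$libsize_sigma))

  set.seed(stage_seed(config$seed, "counts"))
  mu_mat <- (mu * 2^eff[, grp_of, drop = FALSE]) %*% diag(lib)
  counts <- matrix(rnbinom(nf * m, mu = mu_mat, size = rep(1 / disp, m)),
                   nf, m, dimnames = list(feats, samples))
  counts <- expression_matrix(counts, scale = "count")

  design <- data.frame(sample = samples, group = grp_of,
                       condition = cond_of, stringsAsFactors = FALSE)
  truth <- data.frame(feature = feats, is_planted_stable = stable,
                      stringsAsFactors = FALSE)
  lengths <- setNames(rep(1000, nf), feats)
  list(counts = counts, design = design, truth = truth, lengths = lengths)
}

#' Simulate a qPCR Ct table from an abundance matrix
#'
#' Ct is the negative log2 of the abundance relative to the control
#' (housekeeping) feature in the same sample, plus Gaussian technical noise:
#' doubling an abundance lowers its Ct by exactly one cycle at zero noise,
#' and at `noise_sd = 0` the table round-trips through [ct_to_abundance()]
#' up to a per-sample proportionality constant (the control's abundance).
#' The control feature itself is included, with Ct 0 before noise.
#'
#' @param expr expression matrix with strictly positive values.
#' @param noise_sd standard deviation of the technical noise in cycles.
#' @param control_feature identifier of the housekeeping control; must be a
#'   row of `expr`.
#' @param seed integer seed.
#' @return numeric Ct matrix (features x samples).
#' @export
simulate_ct <- function(expr, noise_sd = 0.2, control_feature = rownames(expr)[1],
                        seed = 1L) {
  if (any(expr <= 0, na.rm = TRUE))
    stop("Ct simulation needs strictly positive abundances", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!control_feature %in% rownames(expr))
    stop("control feature '", control_feature, "' not in matrix", call. = FALSE)
  rel <- sweep(expr, 2, expr[control_feature, ], "/")
  set.seed(stage_seed(as.integer(seed), "ct"))
  ct <- -log2(rel) + matrix(rnorm(length(rel), 0, noise_sd),
                            nrow(rel), ncol(rel))
  dimnames(ct) <- dimnames(expr)
  ct
}
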