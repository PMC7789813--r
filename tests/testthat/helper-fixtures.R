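# shared fixtures and independent (naive-loop) oracles

# strip the scale attribute and dimnames for bare numeric comparison
bare <- function(m) {
  attr(m, "scale") <- NULL
  unname(m)
}

mk_expr <- function(values, scale = "count", feats = NULL, samps = NULL) {
  m <- as.matrix(values)
  rownames(m) <- feats %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samps %||% sprintf("s%02d", seq_len(ncol(m)))
  expression_matrix(m, scale = scale)
}

rand_pos_expr <- function(nf, ns, scale = "TPM") {
  mk_expr(matrix(exp(rnorm(nf * ns, 3, 1)), nf, ns), scale = scale)
}

two_group_design <- function(n1 = 8, n0 = 8, label = "A") {
  data.frame(sample = c(paste0(label, "_", seq_len(n1)),
                        paste0("HC_", seq_len(n0))),
             group = rep(c(label, "HC"), c(n1, n0)),
             condition = rep(c("case", "control"), c(n1, n0)),
             stringsAsFactors = FALSE)
}

# brute-force pairwise variation: sd over samples of log2 ratios, two loops
naive_pairwise_variation <- function(x) {
  n <- nrow(x)
  V <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    V[j, k] <- sd(log2(x[j, ] / x[k, ]))
  }
  V
}

naive_m_values <- function(x) {
  V <- naive_pairwise_variation(x)
  out <- numeric(nrow(x))
  for (j in seq_len(nrow(x))) out[j] <- mean(V[j, -j])
  setNames(out, rownames(x))
}

# loop recomputation of the group-aware stability score
naive_normfinder <- function(x, design) {
  L <- log2(x)
  for (i in seq_len(ncol(L))) L[, i] <- L[, i] - mean(L[, i])
  groups <- unique(design$group)
  out <- setNames(numeric(nrow(L)), rownames(L))
  for (j in seq_len(nrow(L))) {
    grand <- mean(L[j, ])
    acc <- 0
    for (g in groups) {
      idx <- which(design$group[match(colnames(L), design$sample)] == g)
      zg <- L[j, idx]
      acc <- acc + abs(mean(zg) - grand) + sqrt(var(zg) / length(zg))
    }
    out[j] <- acc / length(groups)
  }
  out
}

# published worked-example tables (gene symbol, mean log2 expr, CV, M)
mrna_candidates <- data.frame(
  feature = c("OAZ1", "SERF2", "MPP1", "H3F3AP4", "WIPF1",
              "PCMTD1", "ARF1", "SOD2", "B2M", "ITM2B"),
  log_expr = c(9.289, 8.608, 7.748, 7.750, 7.645,
               8.067, 7.850, 8.696, 12.826, 8.754),
  cv = c(0.405, 0.492, 0.460, 0.654, 0.538,
         0.511, 0.660, 0.655, 0.688, 0.723),
  m = c(0.561, 0.588, 0.597, 0.563, 0.626,
        0.704, 0.564, 0.725, 0.827, 0.934),
  stringsAsFactors = FALSE
)

mirna_candidates <- data.frame(
  feature = c("hsa-miR-4468", "hsa-miR-6835-3p", "hsa-miR-192-3p",
              "hsa-miR-125a-5p", "hsa-miR-4469", "hsa-miR-6731-5p"),
  log_expr = c(11.743, 12.208, 11.223, 11.102, 11.756, 12.087),
  cv = c(0.476, 0.498, 0.543, 0.557, 0.515, 0.667),
  m = c(0.304, 0.455, 0.340, 0.336, 0.521, 0.601),
  stringsAsFactors = FALSE
)

`%||%` <- function(a, b) if (is.null(a)) b else a
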