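test_that("CV matches hand computation and is scale invariant per feature", {
  x <- mk_expr(rbind(c(2, 4, 6), c(5, 5, 5)), scale = "TPM")
  cv <- cv_stability(x)
  expect_equal(unname(cv), c(0.5, 0))

  set.seed(3)
  y <- rand_pos_expr(6, 8)
  y2 <- mk_expr(unclass(y) * c(3, 0.01, 7, 1, 100, 0.5), scale = "TPM",
                feats = rownames(y))
  expect_equal(cv_stability(y2), cv_stability(y), tolerance = 1e-12)

  expect_error(cv_stability(mk_expr(matrix(0, 1, 3), "TPM")), "nonpositive mean")
  na1 <- unclass(y); na1[1, 1:7] <- NA
  expect_error(cv_stability(na1), "< 2 non-missing")
  na2 <- unclass(y); na2[1, 1] <- NA
  expect_message(cv_stability(na2), "1 missing")
})

test_that("pairwise variation matches its definition and brute force", {
  x <- mk_expr(rbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(1, 1, 1)),
               scale = "TPM", feats = c("g1", "g2", "g3"))
  V <- pairwise_variation(x)
  expect_equal(V["g1", "g2"], 0)            # proportional features
  expect_equal(V["g1", "g3"], 1)            # sd of log2 ratios (0, 1, 2)
  expect_equal(V, t(V))
  expect_true(all(is.na(diag(V))))

  set.seed(11)
  for (i in 1:10) {
    y <- rand_pos_expr(6, 8)
    expect_equal(pairwise_variation(y), naive_pairwise_variation(unclass(y)),
                 tolerance = 1e-10)
  }
  expect_error(pairwise_variation(mk_expr(rbind(c(1, 0)), "TPM")), "nonpositive")
})

test_that("M values: hand example, two-feature identity, sample-scaling invariance", {
  x <- mk_expr(rbind(g1 = c(1, 2, 4), g2 = c(2, 4, 8), g3 = c(1, 1, 1)),
               scale = "TPM", feats = c("g1", "g2", "g3"))
  m <- m_values(x)
  expect_equal(m[["g1"]], 0.5)              # (0 + 1) / 2

  two <- mk_expr(rbind(c(1, 2, 4), c(2, 4, 8)), scale = "TPM")
  m2 <- m_values(two)
  expect_equal(unname(m2), c(0, 0))
  set.seed(21)
  tw <- rand_pos_expr(2, 7)
  expect_equal(m_values(tw)[[1]], m_values(tw)[[2]])
  expect_equal(m_values(tw)[[1]], pairwise_variation(tw)[1, 2])

  y <- rand_pos_expr(7, 9)
  ys <- mk_expr(sweep(unclass(y), 2, exp(rnorm(9)), "*"), scale = "TPM",
                feats = rownames(y))
  expect_equal(m_values(ys), m_values(y), tolerance = 1e-10)
  expect_error(m_values(y[1, , drop = FALSE]), "single feature")
})

test_that("combination stability is a geometric mean, permutation invariant", {
  m <- c(a = 0.5, b = 0.5, c = 0.5, d = 0.2, e = 0)
  expect_equal(av_combination(m, c("a", "b", "c"))$av, 0.5)
  expect_equal(av_combination(m, c("a", "d"))$av, sqrt(0.1))
  expect_equal(av_combination(m, c("c", "a", "b"))$av,
               av_combination(m, c("a", "b", "c"))$av)
  expect_message(z <- av_combination(m, c("a", "e")), "limit convention")
  expect_equal(z$av, 0)
  expect_error(av_combination(m, "a"), ">= 2")
  expect_error(av_combination(m, c("a", "zz")), "zz")
})

test_that("rank aggregation is deterministic with the documented tie policy", {
  cv <- c(x = 0.3, y = 0.3, z = 0.3)
  m <- c(x = 0.5, y = 0.5, z = 0.5)
  tab <- rank_candidates(cv, m)
  expect_identical(tab$feature, c("x", "y", "z"))   # identifier order on ties
  expect_identical(tab$final_rank, 1:3)

  set.seed(13)
  cv2 <- setNames(runif(8), sprintf("f%d", 1:8))
  m2 <- setNames(runif(8), names(cv2))
  t1 <- rank_candidates(cv2, m2)
  perm <- sample(8)
  t2 <- rank_candidates(cv2[perm], m2[perm])
  expect_identical(t1, t2)
  expect_setequal(t1$cv_rank, 1:8)
  expect_identical(t1$rank_sum, t1$cv_rank + t1$m_rank)
  expect_error(rank_candidates(cv2, m2[-1]), "same feature set")
})

test_that("group-aware stability penalizes planted shifts and matches loops", {
  des <- rbind(two_group_design(6, 6))
  # no intergroup signal, equal variance -> near-equal near-minimal scores
  set.seed(17)
  base <- mk_expr(matrix(2^rnorm(8 * 12, 6, 0.3), 8, 12), scale = "TPM",
                  samps = des$sample)
  s0 <- normfinder_stability(base, des)
  expect_lt(diff(range(s0)), 0.25)

  # large planted shift in one feature -> maximal score
  shifted <- unclass(base)
  shifted[3, des$condition == "case"] <- shifted[3, des$condition == "case"] * 8
  sh <- mk_expr(shifted, scale = "TPM", feats = rownames(base),
                samps = des$sample)
  s1 <- normfinder_stability(sh, des)
  expect_identical(names(which.max(s1)), rownames(base)[3])

  for (i in 1:10) {
    y <- mk_expr(matrix(2^rnorm(8 * 12, 5, 1), 8, 12), scale = "TPM",
                 samps = des$sample)
    expect_equal(normfinder_stability(y, des), naive_normfinder(y, des),
                 tolerance = 1e-10)
  }
  expect_error(normfinder_stability(base, transform(des, group = "one")),
               ">= 2 groups")
})

test_that("Wilcoxon comparison is two-sided, symmetric, exact at tiny n", {
  same <- compare_stability_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  ext <- compare_stability_groups(c(1, 2, 3), c(101, 102, 103))
  expect_equal(ext$p.value, 2 / choose(6, 3))   # minimal attainable, 3 vs 3
  swap <- compare_stability_groups(c(101, 102, 103), c(1, 2, 3))
  expect_equal(swap$p.value, ext$p.value)
  expect_error(compare_stability_groups(numeric(0), 1), "nonempty")
})

test_that("stability_table wires scorers, pseudocount and expression ranks", {
  des <- two_group_design(4, 4)
  set.seed(19)
  x <- mk_expr(matrix(2^rnorm(5 * 8, 8, 0.5), 5, 8), scale = "TPM",
               samps = des$sample)
  tab <- stability_table(x, des, scorers = c("cv", "m", "normfinder"))
  expect_identical(tab$final_rank, 1:5)
  expect_true(all(c("mean_log_expr", "normfinder", "expr_rank") %in%
                  colnames(tab)))
  expect_setequal(tab$expr_rank, 1:5)

  xz <- unclass(x); xz[2, 1] <- 0
  xz <- mk_expr(xz, scale = "TPM", feats = rownames(x), samps = des$sample)
  expect_message(stability_table(xz, des), "pseudocount")
  expect_error(stability_table(x, scorers = "normfinder"), "design")
})
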