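test_that("median-of-ratios size factors behave on constructed columns", {
  x <- mk_expr(matrix(c(10, 20, 30, 10, 20, 30), 3, 2))
  expect_equal(unname(size_factors(x)), c(1, 1))

  # doubled column: factor ratio exactly 2, geometric mean 1
  y <- mk_expr(cbind(c(10, 20, 30), c(20, 40, 60)))
  f <- size_factors(y)
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  set.seed(5)
  z <- mk_expr(matrix(rpois(60, 50) + 1, 10, 6))
  perm <- sample(6)
  zp <- mk_expr(unclass(z)[, perm], samps = colnames(z)[perm])
  expect_equal(size_factors(z)[perm], size_factors(zp))

  # no feature positive everywhere -> total-count fallback with warning
  w <- mk_expr(rbind(c(10, 0), c(0, 10), c(5, 0)))
  expect_warning(fw <- size_factors(w), "total-count")
  expect_equal(unname(fw[1] / fw[2]), 1.5)
})

test_that("NB Wald test flags overwhelming effects and honors conventions", {
  set.seed(42)
  des <- two_group_design(10, 10)
  cnt <- rbind(
    big = rnbinom(20, mu = rep(c(1000, 10), each = 10), size = 10),
    null = rnbinom(20, mu = 100, size = 10),
    zero = rep(0, 20)
  )
  cnt <- mk_expr(cnt, feats = rownames(cnt), samps = des$sample)
  p <- nb_two_group_test(cnt, des, "A")
  expect_lt(p[["big"]], 1e-6)
  expect_identical(p[["zero"]], 1)
  expect_true(all(p >= 0 & p <= 1))

  # sample order is irrelevant
  perm <- sample(20)
  cntp <- mk_expr(unclass(cnt)[, perm], feats = rownames(cnt),
                  samps = colnames(cnt)[perm])
  expect_equal(nb_two_group_test(cntp, des, "A"), p)

  expect_error(nb_two_group_test(cnt[, 1:3], des[1:3, ], "A"), ">= 2")
})

test_that("non-DE filter uses strict inequality and intersection is order-free", {
  p <- c(a = 0.05, b = 0.10, c = 0.50)
  expect_identical(nonde_filter(p, 0.1), "c")
  expect_identical(nonde_filter(setNames(rep(1, 3), names(p))), names(p))
  expect_identical(nonde_filter(p, 0), names(p))
  expect_error(nonde_filter(c(a = 1.2)), "\\[0, 1\\]")

  sets <- list(c("A", "B", "C"), c("B", "C"), c("B", "C", "D"))
  expect_identical(intersect_subtypes(sets), c("B", "C"))
  expect_identical(intersect_subtypes(sets[c(3, 1, 2)]), c("B", "C"))
  expect_identical(intersect_subtypes(sets[1]), sets[[1]])
  expect_length(intersect_subtypes(list("A", "B")), 0)

  # relaxing the threshold never drops a retained feature
  set.seed(7)
  pv <- setNames(runif(50), sprintf("f%02d", 1:50))
  for (th in c(0.2, 0.1, 0.05))
    expect_true(all(nonde_filter(pv, th) %in% nonde_filter(pv, th / 2)))
})

test_that("high-expression filter compares to the pooled log mean, strictly", {
  des <- two_group_design(3, 3)
  # one feature at 100x the level of 99 identical others -> retained
  vals <- matrix(10, 100, 6)
  vals[1, ] <- 1000
  x <- mk_expr(vals, scale = "TPM", samps = des$sample)
  keep <- high_expression_filter(x, des, rownames(x))
  expect_identical(keep, rownames(x)[1])

  # all identical -> nothing exceeds the mean (strict inequality)
  flat <- mk_expr(matrix(10, 5, 6), scale = "TPM", samps = des$sample)
  expect_length(high_expression_filter(flat, des, rownames(flat)), 0)
  expect_length(high_expression_filter(flat, des, character(0)), 0)
  expect_error(high_expression_filter(mk_expr(matrix(1, 2, 6), "count",
                                              samps = des$sample),
                                      des, "g01"), "normalized")
})

test_that("top-n selection sorts by mean log expression with identifier ties", {
  des <- two_group_design(2, 2)
  x <- mk_expr(rbind(a = rep(2^5 - 1, 4), b = rep(2^9 - 1, 4),
                     c = rep(2^7 - 1, 4)),
               scale = "TPM", feats = c("a", "b", "c"), samps = des$sample)
  expect_identical(select_top(x, c("a", "b", "c"), 2), c("b", "c"))
  expect_message(full <- select_top(x, c("a", "b", "c"), 5), "3 survivors")
  expect_identical(full, c("b", "c", "a"))

  tied <- mk_expr(matrix(10, 3, 2), scale = "TPM",
                  feats = c("zz", "aa", "mm"))
  expect_identical(select_top(tied, rownames(tied), 3), c("aa", "mm", "zz"))
})

test_that("screening cascade output is consistent and sample-order invariant", {
  sim <- simulate_counts(simulation_config(n_features = 300, n_stable = 3,
                                           seed = 33))
  tpm <- compute_tpm(sim$counts, sim$lengths)
  scr <- suppressMessages(
    screen_candidates(sim$counts, sim$design, tpm, top_n = 5))
  sc <- scr$stage_counts
  expect_lte(sc[["universal"]], min(sc[grep("non_de", names(sc))]))
  expect_lte(sc[["high_expression"]], sc[["universal"]])
  expect_lte(sc[["candidates"]], min(sc[["high_expression"]], 5))
  # selected => non-DE everywhere and above-average in both conditions
  sel <- scr$result[scr$result$selected, ]
  expect_true(all(sel$non_de_all_subtypes & sel$above_average_both))

  perm <- sample(ncol(sim$counts))
  cntp <- mk_expr(unclass(sim$counts)[, perm], feats = rownames(sim$counts),
                  samps = colnames(sim$counts)[perm])
  tpmp <- compute_tpm(cntp, sim$lengths)
  scrp <- suppressMessages(
    screen_candidates(cntp, sim$design, tpmp, top_n = 5))
  expect_identical(scrp$candidates, scr$candidates)
  expect_equal(scrp$stage_counts, scr$stage_counts)
})
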