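test_that("p-values are proper and monotone in the statistic", {
  expect_identical(p_dm(0, 3), 1)
  expect_identical(p_wdmo(0, 2, c(0.3, 0.6)), 1)
  expect_identical(p_lmuo(0, 2, 4), 1)
  cs <- seq(0.2, 3, by = 0.4)
  for (pf in list(function(c) p_dm(c, 2),
                  function(c) p_wdmo(c, 2, c(0.25, 0.5, 0.75)),
                  function(c) p_lmuo(c, 2, 4))) {
    ps <- vapply(cs, pf, 0)
    expect_true(all(ps >= 0 & ps <= 1))
    expect_true(all(diff(ps) <= 0))
  }
  # defining identity of the DM tail across k
  for (c in c(0.8, 1.3, 2)) {
    expect_equal(p_dm(c, 4), 1 - (1 - p_dm(c, 1))^4, tolerance = 1e-12)
  }
})

test_that("simulated tables are reproducible and self-describing", {
  t1 <- ord_l2bb(c(0.25, 0.5, 0.75), nproc = c(1, 3), nrep = 3000, seed = 4)
  t2 <- ord_l2bb(c(0.25, 0.5, 0.75), nproc = c(1, 3), nrep = 3000, seed = 4)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$seed, 4L)
  expect_error(p_maxlmo(1, 2, t1), "nproc")
  expect_error(p_maxlmo(1, 1, t1, t_check = c(0.2, 0.5, 0.8)),
               "different level proportions")
  expect_warning(ord_l2bb(0.5, nproc = 1, nrep = 500, seed = 1), "small")
})

test_that("simulated and analytic null routes agree where both exist", {
  # WDMo at m = 2, k = 1: weighted tie value is standard normal
  expect_equal(p_wdmo(1.6, 1, 0.5), 2 * pnorm(1.6, lower.tail = FALSE),
               tolerance = 1e-4)
  # the tie-point Gaussian rectangle agrees with raw simulation at m=5, k=4
  tl <- (1:4) / 5
  c0 <- 2.4
  analytic <- 1 - bb_rect_prob(c0, tl)^4
  tab_seeds <- vapply(c(21, 22), function(sd) {
    set.seed(sd)
    nr <- 20000
    dt <- diff(c(0, tl, 1))
    worst <- rep(0, nr)
    for (j in 1:4) {
      W <- apply(matrix(rnorm(nr * 5), nr, 5) %*% diag(sqrt(dt)), 1, cumsum)
      B <- t(W)[, 1:4] - outer(t(W)[, 5], tl)
      worst <- pmax(worst, apply(abs(B) / rep(sqrt(tl * (1 - tl)),
                                              each = nr), 1, max))
    }
    mean(worst > c0)
  }, 0)
  mc_se <- sqrt(analytic * (1 - analytic) / 20000)
  expect_lt(abs(tab_seeds[1] - analytic), 3 * mc_se)
  expect_lt(abs(tab_seeds[2] - analytic), 3 * mc_se)
  # sup|BB| simulated path quantile close to the crossing-series quantile
  s <- simulate_bb_functionals("DM", 1, nrep = 10000, grid = 1500, seed = 6)
  q <- uniroot(function(c) bb_sup_cdf(c) - 0.9, c(0.5, 3))$root
  expect_equal(unname(quantile(s, 0.9)), q, tolerance = 0.02)
})

test_that("maxLM and CvM simulated quantiles are stable across seeds", {
  q1 <- quantile(simulate_bb_functionals("maxLM", 1, nrep = 8000,
                                         grid = 600, seed = 1), 0.95)
  q2 <- quantile(simulate_bb_functionals("maxLM", 1, nrep = 8000,
                                         grid = 600, seed = 2), 0.95)
  expect_equal(unname(q1), unname(q2), tolerance = 0.05)
  c1 <- quantile(simulate_bb_functionals("CvM", 2, nrep = 8000,
                                         grid = 600, seed = 1), 0.95)
  c2 <- quantile(simulate_bb_functionals("CvM", 2, nrep = 8000,
                                         grid = 600, seed = 2), 0.95)
  expect_equal(unname(c1), unname(c2), tolerance = 0.05)
})

test_that("bridge grid resolution does not move continuous quantiles", {
  q_coarse <- quantile(simulate_bb_functionals("maxLM", 1, nrep = 10000,
                                               grid = 500, seed = 8), 0.95)
  q_fine <- quantile(simulate_bb_functionals("maxLM", 1, nrep = 10000,
                                             grid = 2000, seed = 8), 0.95)
  expect_lt(abs(q_fine - q_coarse) / q_fine, 0.03)
})
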