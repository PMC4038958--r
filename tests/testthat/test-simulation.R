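test_that("asymptotic standard errors scale as 1/sqrt(n) and match sampling SDs", {
  dgp <- cfa_dgp()
  expect_equal(asymptotic_se(dgp, 480, "f1=~y1"),
               asymptotic_se(dgp, 120, "f1=~y1") / 2, tolerance = 1e-12)
  for (p in names(dgp$theta)) expect_gt(asymptotic_se(dgp, 100, p), 0)
  expect_error(asymptotic_se(dgp, 100, "f9=~y1"), "unknown parameter")
  # sampling-distribution check for a couple of parameters
  est <- vapply(1:120, function(r) {
    d <- generate_dataset(dgp, n = 480, m = 4, seed = 5000 + r)
    coef(cfa_fit(sim_model(), d, identification = "variance"))[
      c("f1=~y1", "f1~~f2")]
  }, c(0, 0))
  for (p in rownames(est)) {
    expect_equal(sd(est[p, ]), asymptotic_se(dgp, 480, p),
                 tolerance = 0.2)
  }
})

test_that("generated data respect the changepoint and the seed", {
  dgp <- cfa_dgp()
  d1 <- generate_dataset(dgp, n = 480, m = 8, violate = "y1~1", d = 4,
                         seed = 3)
  d2 <- generate_dataset(dgp, n = 480, m = 8, violate = "y1~1", d = 4,
                         seed = 3)
  expect_identical(d1, d2)
  # m = 8: levels 1-4 deviated, 5-8 baseline; with a large intercept shift
  # the group means separate accordingly
  dev <- 4 * asymptotic_se(dgp, 480, "y1~1")
  pre <- mean(d1$y1[d1$level <= 4])
  post <- mean(d1$y1[d1$level >= 5])
  expect_gt(pre - post, dev / 2)
  # balanced allocation by largest remainder
  expect_identical(as.vector(table(generate_dataset(dgp, 123, 4,
                                                    seed = 1)$level)),
                   c(31L, 31L, 31L, 30L))
})

test_that("null data pool to the implied moments as n grows", {
  dgp <- cfa_dgp()
  d <- generate_dataset(dgp, n = 50000, m = 4, seed = 77)
  mom <- scoremiv:::implied_moments(
    scoremiv:::pt_matrices(dgp$ptable, dgp$theta, 1L))
  X <- as.matrix(d[paste0("y", 1:6)])
  expect_equal(colMeans(X), mom$mu, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(cov(X), mom$Sigma, tolerance = 0.03, ignore_attr = TRUE)
})

test_that("non-PD violations are refused with the cell named", {
  dgp <- cfa_dgp()
  expect_error(generate_dataset(dgp, n = 480, m = 4, violate = "f1~~f2",
                                d = 40, seed = 1),
               "non-positive-definite")
})

test_that("the gratitude-like fixture has the documented shape", {
  d <- simulate_gratitude(n = 301, seed = 2)
  expect_identical(names(d), c(paste0("gq_", 1:5), "agegroup"))
  expect_true(all(as.matrix(d[1:5]) %in% 1:7))
  expect_identical(nlevels(d$agegroup), 6L)
  expect_true(is.ordered(d$agegroup))
  expect_lte(diff(range(table(d$agegroup))), 1)
  expect_identical(d, simulate_gratitude(n = 301, seed = 2))
})

test_that("power study bookkeeping records cells, seeds and convergence", {
  dgp <- cfa_dgp()
  pt <- run_power_study(dgp, data.frame(n = 120, m = 4, d = 0),
                        tested = list(lambda11 = "f1=~y1"),
                        functionals = c("WDMo", "LMuo"),
                        nrep = 20, seed = 99, keep_reps = TRUE)
  expect_s3_class(pt, "power_table")
  expect_identical(nrow(pt), 2L)
  expect_true(all(pt$proportion >= 0 & pt$proportion <= 1))
  expect_identical(attr(pt, "seed"), 99)
  reps <- attr(pt, "reps")[[1L]]
  expect_identical(dim(reps), c(20L, 1L, 2L))
  # rerunning with the same master seed reproduces the table
  pt2 <- run_power_study(dgp, data.frame(n = 120, m = 4, d = 0),
                         tested = list(lambda11 = "f1=~y1"),
                         functionals = c("WDMo", "LMuo"),
                         nrep = 20, seed = 99)
  expect_identical(pt$rejections, pt2$rejections)
})
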