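test_that("all-zero processes give zero statistics", {
  proc <- toy_process(matrix(0, 10, 2), counts = c(4, 3, 3))
  expect_identical(stat_dm(proc), 0)
  expect_identical(stat_cvm(proc), 0)
  expect_identical(stat_maxlm(proc), 0)
  expect_identical(stat_wdmo(proc), 0)
  expect_identical(stat_maxlmo(proc), 0)
  expect_identical(stat_lmuo(proc), 0)
})

test_that("statistics have their defining structure", {
  set.seed(5)
  B <- matrix(rnorm(30), 10, 3)
  B[10, ] <- 0
  proc <- toy_process(B, counts = c(4, 3, 3))
  # sign flips leave DM unchanged
  flip <- toy_process(B %*% diag(c(-1, 1, -1)), counts = c(4, 3, 3))
  expect_equal(stat_dm(flip), stat_dm(proc))
  # CvM is additive over disjoint column subsets
  expect_equal(stat_cvm(proc, 1:2) + stat_cvm(proc, 3), stat_cvm(proc))
  # widening the maxLM window never decreases the statistic
  expect_gte(stat_maxlm(proc, trim = c(0.05, 0.95)),
             stat_maxlm(proc, trim = c(0.2, 0.8)))
  # k = 1: maxLMo is the square of WDMo
  expect_equal(stat_maxlmo(proc, 2), stat_wdmo(proc, 2)^2)
  expect_error(stat_maxlm(proc, trim = c(0.9, 0.1)), "trim")
  expect_error(stat_dm(proc, integer(0)), "indices")
  expect_error(stat_dm(proc, "nope"), "unknown parameter")
})

test_that("score_test orchestration is deterministic and validates inputs", {
  s <- fit_small_sim()
  r1 <- score_test(s$fit, s$data$level, parm = "f1=~y1",
                   functional = "maxLMo", nrep = 2000, seed = 9)
  r2 <- score_test(s$fit, s$data$level, parm = "f1=~y1",
                   functional = "maxLMo", nrep = 2000, seed = 9)
  expect_identical(r1$statistic, r2$statistic)
  expect_identical(r1$p.value, r2$p.value)
  # positional and label addressing agree
  r3 <- score_test(s$fit, s$data$level, parm = 1, functional = "maxLMo",
                   nrep = 2000, seed = 9)
  expect_identical(r3$statistic, r1$statistic)
  # ordinal functionals refuse an all-unique continuous ordering
  expect_error(score_test(s$fit, seq_len(s$fit$n), functional = "WDMo"),
               "DM, CvM or maxLM")
  # continuous treatment of tied data is allowed but warned about
  expect_warning(score_test(s$fit, s$data$level, parm = 1,
                            functional = "DM"), "ties")
  # LMuo p-value equals the chi-squared tail of the statistic
  rl <- score_test(s$fit, s$data$level, parm = 1:4, functional = "LMuo")
  expect_equal(rl$p.value,
               pchisq(rl$statistic, 4 * (rl$m - 1), lower.tail = FALSE))
})

test_that("single-parameter WDMo and maxLMo agree in p-value", {
  s <- fit_small_sim()
  rw <- score_test(s$fit, s$data$level, parm = "f1=~y1",
                   functional = "WDMo")
  rm <- score_test(s$fit, s$data$level, parm = "f1=~y1",
                   functional = "maxLMo", nrep = 50000, seed = 3)
  expect_equal(rm$statistic, rw$statistic^2, tolerance = 1e-10)
  expect_equal(rm$p.value, rw$p.value, tolerance = 0.01)
})

test_that("LMuo approaches the likelihood ratio statistic at large n", {
  dgp <- cfa_dgp()
  d <- generate_dataset(dgp, n = 4000, m = 2, seed = 11)
  pooled <- cfa_fit(sim_model(), d, identification = "variance")
  grouped <- cfa_fit(sim_model(), d, group = "level",
                     identification = "variance")
  lrt <- 2 * (grouped$loglik - pooled$loglik)
  st <- score_test(pooled, d$level, functional = "LMuo")
  expect_equal(st$statistic, lrt, tolerance = 0.05)
})
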