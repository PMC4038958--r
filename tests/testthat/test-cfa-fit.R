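test_that("log-likelihood equals an independent MVN density sum", {
  s <- fit_small_sim()
  fit <- s$fit
  # rebuild the implied moments by hand from the labeled estimates and sum
  # MVN log-densities case by case, independently of the package internals
  th <- coef(fit)
  Lam <- matrix(0, 6, 2)
  Lam[1:3, 1] <- th[c("f1=~y1", "f1=~y2", "f1=~y3")]
  Lam[4:6, 2] <- th[c("f2=~y4", "f2=~y5", "f2=~y6")]
  Phi <- matrix(c(1, th["f1~~f2"], th["f1~~f2"], 1), 2)
  Psi <- diag(th[paste0("y", 1:6, "~~y", 1:6)])
  nu <- th[paste0("y", 1:6, "~1")]
  Sigma <- Lam %*% Phi %*% t(Lam) + Psi
  X <- as.matrix(s$data[paste0("y", 1:6)])
  Sinv <- solve(Sigma)
  ld <- as.numeric(determinant(Sigma)$modulus)
  ll <- 0
  for (i in seq_len(nrow(X))) {
    d <- X[i, ] - nu
    ll <- ll - 0.5 * (6 * log(2 * pi) + ld + drop(d %*% Sinv %*% d))
  }
  expect_equal(unname(logLik(fit)[1]), unname(ll), tolerance = 1e-8)
  # additivity of casewise contributions
  expect_equal(sum(casewise_loglik(fit)), fit$loglik, tolerance = 1e-10)
})

test_that("first-order condition holds and estimates are order-invariant", {
  s <- fit_small_sim()
  expect_true(s$fit$converged)
  expect_lt(max(abs(colSums(scores(s$fit)))), 1e-4 * sqrt(s$fit$n))
  set.seed(7)
  perm <- sample(nrow(s$data))
  fit2 <- cfa_fit(sim_model(), s$data[perm, ], identification = "variance")
  expect_equal(coef(fit2), coef(s$fit), tolerance = 1e-7)
})

test_that("identification and input errors are explicit", {
  d <- fit_small_sim()$data
  expect_error(cfa_fit(cfa_model("f1 =~ y1 + y2 + y3\nf2 =~ y4"), d),
               "single indicator")
  expect_error(cfa_fit(sim_model(), d[-(1:3)]), "not found")
  d2 <- d
  d2$y1 <- as.character(d2$y1)
  expect_error(cfa_fit(sim_model(), d2), "not numeric")
})

test_that("incomplete rows are dropped and counted", {
  d <- fit_small_sim()$data
  d$y3[c(5, 9, 50)] <- NA
  fit <- cfa_fit(sim_model(), d, identification = "variance")
  expect_identical(fit$n_dropped, 3L)
  expect_identical(fit$n, nrow(d) - 3L)
})

test_that("information matrices are symmetric PSD and mutually consistent", {
  fit <- fit_small_sim()$fit
  for (kind in c("observed", "opg", "expected")) {
    I <- info_matrix(fit, kind)
    expect_lt(max(abs(I - t(I))), 1e-8)
    ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(I)))
  }
  # under a correctly specified model the information equality holds
  # approximately at moderate n
  Io <- info_matrix(fit, "observed")
  Ie <- info_matrix(fit, "expected")
  expect_lt(norm(Io - Ie, "F") / norm(Io, "F"), 0.10)
})

test_that("likelihood ratio test behaves on nested and identical fits", {
  d <- simulate_gratitude(400, seed = 3)
  m <- cfa_model("f1 =~ gq_1 + gq_2 + gq_3 + gq_4 + gq_5")
  restr <- cfa_fit(m, d, group = "agegroup", group_equal = "loadings")
  full <- cfa_fit(m, d, group = "agegroup")
  lrt <- lr_test(full, restr)
  expect_identical(lrt$df, 20L)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p.value,
               pchisq(lrt$statistic, 20, lower.tail = FALSE))
  self <- lr_test(restr, restr)
  expect_equal(self$statistic, 0, tolerance = 1e-8)
  expect_identical(self$p.value, 1)
  tab <- anova(full, restr)
  expect_equal(tab[2L, "Chisq diff"], lrt$statistic)
})

test_that("model and summary methods report coherently", {
  fit <- fit_small_sim()$fit
  s <- summary(fit)
  expect_identical(nrow(s$table), fit$k)
  expect_true(all(s$table$se > 0))
  expect_equal(s$aic, -2 * fit$loglik + 2 * fit$k)
  mom <- fitted(fit)[[1L]]
  expect_equal(dim(mom$Sigma), c(6L, 6L))
  r <- residuals(fit)
  expect_equal(colMeans(r), drop(colMeans(fit$X) - mom$mu),
               tolerance = 1e-12, ignore_attr = TRUE)
  sim <- simulate(fit, seed = 1)
  expect_identical(nrow(sim), fit$n)
})
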