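#' Two-factor simulation data-generating process
#'
#' The study design: two factors with three indicators each (y1..y3 on f1,
#' y4..y6 on f2), variance identification (factor variances fixed to 1, all
#' loadings free), mean structure. True values: loadings 1, intercepts 0,
#' unique variances 1, factor covariance 0.5. Optionally an extra
#' cross-loading from the second factor to the first indicator (default
#' value 0.5 when enabled) for misspecification studies, where the fitted
#' model omits it.
#'
#' @param cross_loading numeric; 0 (default) for the correctly specified
#'   design, or the true value of the unmodeled loading f2 -> y1.
#' @return Object of class \code{"cfa_dgp"}: list with the generating
#'   \code{model}, its \code{ptable} (single group, variance
#'   identification), the true free-parameter vector \code{theta}, and
#'   \code{cross_loading}.
#' @export
cfa_dgp <- function(cross_loading = 0) {
  syntax <- if (cross_loading != 0)
    "f1 =~ y1 + y2 + y3\nf2 =~ y4 + y5 + y6 + y1"
  else "f1 =~ y1 + y2 + y3\nf2 =~ y4 + y5 + y6"
  model <- cfa_model(syntax)
  ptable <- cfa_ptable(model, 1L, meanstructure = TRUE,
                       identification = "variance")
  labels <- free_labels(ptable)
  theta <- numeric(length(labels))
  names(theta) <- labels
  theta[grepl("=~", labels)] <- 1
  theta[grepl("~1$", labels)] <- 0
  theta[labels %in% paste0("y", 1:6, "~~y", 1:6)] <- 1
  theta["f1~~f2"] <- 0.5
  if (cross_loading != 0) theta["f2=~y1"] <- cross_loading
  mom <- implied_moments(pt_matrices(ptable, theta, 1L))
  if (min(eigen(mom$Sigma, symmetric = TRUE,
                only.values = TRUE)$values) <= 0)
    stop("implied covariance of the DGP is not positive definite",
         call. = FALSE)
  structure(list(model = model, ptable = ptable, theta = theta,
                 cross_loading = cross_loading),
            class = "cfa_dgp")
}

#' The fitted simulation model
#'
#' The two-factor, three-indicators-each model estimated in the power
#' studies; it never includes the cross-loading, so fitting it to data from
#' \code{cfa_dgp(cross_loading = 0.5)} is deliberately misspecified.
#' @return a \code{\link{cfa_model}}.
#' @export
sim_model <- function() {
  cfa_model("f1 =~ y1 + y2 + y3\nf2 =~ y4 + y5 + y6")
}

#' Asymptotic standard error of a DGP parameter
#'
#' Square root of the parameter's diagonal entry of the inverse of n times
#' the expected information at the true values; violation magnitudes d are
#' expressed in multiples of this, so they are comparable across sample
#' sizes.
#' @param dgp a \code{\link{cfa_dgp}}.
#' @param n sample size.
#' @param parameter free-parameter label, e.g. \code{"f1=~y1"}.
#' @export
asymptotic_se <- function(dgp, n, parameter) {
  stopifnot(inherits(dgp, "cfa_dgp"), n >= 1)
  if (!parameter %in% names(dgp$theta))
    stop("unknown parameter ", sQuote(parameter), "; available: ",
         paste(names(dgp$theta), collapse = ", "), call. = FALSE)
  I <- expected_info_internal(dgp$theta, dgp$ptable, 1)
  V <- tryCatch(solve(n * I), error = function(e)
    stop("expected information at the true values is singular",
         call. = FALSE))
  sqrt(V[match(parameter, names(dgp$theta)),
         match(parameter, names(dgp$theta))])
}

# balanced level sizes by largest remainder: the first (n mod m) levels get
# one extra observation
level_counts <- function(n, m) {
  base <- n %/% m
  extra <- n - base * m
  base + as.integer(seq_len(m) <= extra)
}

#' Generate a simulation data set with an optional invariance violation
#'
#' Individuals are assigned to m balanced ordinal levels. Individuals below
#' the changepoint level \eqn{1 + m/2} use the violating parameter's value
#' shifted by \eqn{d} times its asymptotic standard error at this n;
#' individuals at or above the changepoint use the baseline values. With
#' \code{d = 0} all levels share one DGP.
#'
#' @param dgp a \code{\link{cfa_dgp}}.
#' @param n sample size (balanced over levels by largest remainder).
#' @param m number of ordinal levels.
#' @param violate free-parameter label of the violating parameter, or
#'   \code{NULL} for the null design.
#' @param d violation magnitude in asymptotic standard errors.
#' @param seed integer seed.
#' @return data frame with indicator columns and an integer \code{level}
#'   column (1..m).
#' @export
generate_dataset <- function(dgp, n, m, violate = NULL, d = 0, seed = 1L) {
  stopifnot(inherits(dgp, "cfa_dgp"), n >= m, m >= 2, d >= 0)
  set.seed(seed)
  counts <- level_counts(n, m)
  level <- rep.int(seq_len(m), counts)
  theta0 <- dgp$theta
  theta1 <- theta0
  if (!is.null(violate) && d > 0) {
    dev <- d * asymptotic_se(dgp, n, violate)
    theta1[violate] <- theta1[violate] + dev
  }
  changepoint <- 1 + m / 2
  pre <- level < changepoint
  X <- matrix(NA_real_, n, length(dgp$model$indicators))
  colnames(X) <- dgp$model$indicators
  for (phase in 1:2) {
    idx <- if (phase == 1L) which(pre) else which(!pre)
    if (!length(idx)) next
    th <- if (phase == 1L) theta1 else theta0
    mom <- implied_moments(pt_matrices(dgp$ptable, th, 1L))
    ch <- tryCatch(chol(mom$Sigma), error = function(e)
      stop("violation of ", sQuote(violate), " by d = ", d,
           " at n = ", n, " yields a non-positive-definite covariance",
           call. = FALSE))
    Z <- matrix(stats::rnorm(length(idx) * ncol(X)), length(idx))
    X[idx, ] <- sweep(Z %*% ch, 2, mom$mu, `+`)
  }
  out <- as.data.frame(X)
  out$level <- level
  out
}

#' Monte-Carlo size and power study
#'
#' For every condition (row of \code{conditions}): generate data sets from
#' the DGP, fit \code{fit_model} to each, run the score-based tests for
#' every tested parameter subset and functional, and record rejection
#' proportions at level \code{alpha}. Non-converged replications are dropped
#' and counted; a cell losing more than 5\% of replications is flagged.
#' Ordinal maxLMo critical-value tables are simulated once per distinct tie
#' structure and reused across replications.
#'
#' @param dgp a \code{\link{cfa_dgp}}.
#' @param conditions data frame with columns \code{n}, \code{m}, \code{d}
#'   and optionally \code{violate} (label, \code{NA} for the null).
#' @param tested named list of tested parameter subsets (label vectors).
#' @param functionals subset of \code{c("maxLMo", "WDMo", "LMuo")}.
#' @param fit_model model to estimate (default \code{\link{sim_model}()}).
#' @param nrep replications per cell.
#' @param alpha significance level.
#' @param seed master seed; per-cell and per-replication streams are derived
#'   from it and recorded.
#' @param vcov information matrix for decorrelation.
#' @param ord_nrep replications for the maxLMo critical-value tables.
#' @param keep_reps logical; if \code{TRUE}, attach the per-replication
#'   rejection indicators (list over cells of logical arrays
#'   replication x tested set x functional) as attribute \code{"reps"},
#'   enabling paired comparisons between functionals.
#' @return data frame of class \code{"power_table"}: one row per cell x
#'   tested set x functional with columns \code{functional},
#'   \code{tested_set}, \code{violating_param}, \code{n}, \code{m},
#'   \code{d}, \code{nrep}, \code{rejections}, \code{proportion},
#'   \code{mc_se}, \code{nonconverged}, \code{flagged}.
#' @export
run_power_study <- function(dgp, conditions, tested,
                            functionals = c("maxLMo", "WDMo", "LMuo"),
                            fit_model = sim_model(), nrep = 500L,
                            alpha = 0.05, seed = 1L, vcov = "observed",
                            ord_nrep = 50000L, keep_reps = FALSE) {
  stopifnot(inherits(dgp, "cfa_dgp"), is.data.frame(conditions),
            all(c("n", "m", "d") %in% names(conditions)),
            is.list(tested), length(names(tested)) == length(tested))
  functionals <- match.arg(functionals, c("maxLMo", "WDMo", "LMuo"),
                           several.ok = TRUE)
  if (!"violate" %in% names(conditions)) conditions$violate <- NA_character_

  ks <- sort(unique(lengths(tested)))
  tables <- new.env(parent = emptyenv())
  get_table <- function(t_l, cell_seed) {
    key <- paste(format(t_l, digits = 12), collapse = ",")
    if (is.null(tables[[key]]))
      tables[[key]] <- ord_l2bb(t_l, nproc = ks, nrep = ord_nrep,
                                seed = cell_seed)
    tables[[key]]
  }

  out <- list()
  repkeep <- if (keep_reps) vector("list", nrow(conditions))
  for (cell in seq_len(nrow(conditions))) {
    n <- conditions$n[cell]; m <- conditions$m[cell]
    dd <- conditions$d[cell]
    viol <- conditions$violate[cell]
    if (is.na(viol)) viol <- NULL
    cell_seed <- as.integer((as.numeric(seed) * 7919 + cell * 104729) %%
                              2147483647) + 1L
    counts <- level_counts(n, m)
    t_l <- cumsum(counts)[-m] / n
    tab <- if ("maxLMo" %in% functionals) get_table(t_l, cell_seed)

    rej <- array(0L, dim = c(length(tested), length(functionals)),
                 dimnames = list(names(tested), functionals))
    if (keep_reps)
      repkeep[[cell]] <- array(NA, dim = c(nrep, length(tested),
                                           length(functionals)),
                               dimnames = list(NULL, names(tested),
                                               functionals))
    nonconv <- 0L
    done <- 0L
    for (r in seq_len(nrep)) {
      rep_seed <- as.integer((cell_seed + as.numeric(r) * 15485863) %%
                               2147483647) + 1L
      dat <- generate_dataset(dgp, n, m, violate = viol, d = dd,
                              seed = rep_seed)
      fit <- tryCatch(
        cfa_fit(fit_model, dat, identification = "variance",
                control = list(restarts = 2L)),
        error = function(e) NULL)
      if (is.null(fit)) { nonconv <- nonconv + 1L; next }
      proc <- tryCatch(
        empirical_process(scores(fit), info_matrix(fit, vcov),
                          order_observations(dat$level, "ordinal")),
        error = function(e) NULL)
      if (is.null(proc)) { nonconv <- nonconv + 1L; next }
      done <- done + 1L
      for (s in seq_along(tested)) {
        idx <- match(tested[[s]], proc$labels)
        if (anyNA(idx))
          stop("tested labels not in fitted model: ",
               paste(tested[[s]][is.na(idx)], collapse = ", "),
               call. = FALSE)
        kk <- length(idx)
        for (fn in functionals) {
          p <- switch(fn,
            maxLMo = p_maxlmo(stat_maxlmo(proc, idx), kk, tab),
            WDMo = p_wdmo(stat_wdmo(proc, idx), kk, proc$ordering$t),
            LMuo = p_lmuo(stat_lmuo(proc, idx), kk, m))
          if (p < alpha) rej[s, fn] <- rej[s, fn] + 1L
          if (keep_reps) repkeep[[cell]][r, s, fn] <- p < alpha
        }
      }
    }
    for (s in seq_along(tested)) for (fn in functionals) {
      prop <- if (done > 0) rej[s, fn] / done else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        functional = fn, tested_set = names(tested)[s],
        violating_param = if (is.null(viol)) "none" else viol,
        n = n, m = m, d = dd, nrep = done,
        rejections = rej[s, fn], proportion = prop,
        mc_se = if (done > 0) sqrt(prop * (1 - prop) / done) else NA_real_,
        nonconverged = nonconv,
        flagged = nonconv > 0.05 * nrep,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "alpha") <- alpha
  attr(res, "seed") <- seed
  if (keep_reps) attr(res, "reps") <- repkeep
  class(res) <- c("power_table", "data.frame")
  res
}

#' Synthetic gratitude-questionnaire-like fixture
#'
#' Generates a data set with the shape of a youth gratitude survey: five
#' 7-point Likert items loading on one factor and six ordered age groups of
#' near-equal size (largest-remainder allocation). Entirely synthetic: a
#' one-factor multivariate-normal draw discretized to 1..7, invariant across
#' groups, so it exercises the full tutorial pipeline without implying any
#' particular test outcome.
#'
#' @param n sample size (>= 60), default 1401.
#' @param seed integer seed.
#' @return data frame with items \code{gq_1}..\code{gq_5} and ordered factor
#'   \code{agegroup} with six levels.
#' @export
simulate_gratitude <- function(n = 1401L, seed = 1L) {
  stopifnot(n >= 60L)
  set.seed(seed)
  lambda <- c(1, 0.9, 1.1, 0.8, 1.05)
  psi <- c(1.1, 1.3, 0.9, 1.4, 1.0)
  f <- stats::rnorm(n)
  Y <- outer(f, lambda) +
    matrix(stats::rnorm(n * 5), n) %*% diag(sqrt(psi)) + 4.5
  Y <- pmin(pmax(round(Y), 1), 7)
  colnames(Y) <- paste0("gq_", 1:5)
  counts <- level_counts(n, 6L)
  labels <- c("10-11", "12-13", "14", "15", "16", "17-19")
  d <- as.data.frame(Y)
  d$agegroup <- factor(rep(labels, counts), levels = labels, ordered = TRUE)
  d
}
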