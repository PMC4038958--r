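# The six functionals of the decorrelated cumulative score process. Each is
# a pure function of the process (restricted to the tested columns) and, for
# the ordinal/categorical versions, the tie structure; p-values live in
# nulldist.R.

resolve_parm <- function(proc, parm) {
  if (is.null(parm)) return(seq_len(proc$k))
  if (is.character(parm)) {
    idx <- match(parm, proc$labels)
    if (anyNA(idx))
      stop("unknown parameter label(s): ",
           paste(parm[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  } else {
    idx <- as.integer(parm)
    if (length(idx) == 0L || any(idx < 1L) || any(idx > proc$k))
      stop("parameter indices out of range 1..", proc$k, call. = FALSE)
    idx
  }
}

proc_rows <- function(proc, parm) {
  # rows i = 1..n of the process (row 0 dropped), tested columns only
  proc$B[-1L, resolve_parm(proc, parm), drop = FALSE]
}

tie_struct <- function(proc) {
  o <- proc$ordering
  if (is.null(o$m))
    stop("this functional needs an ordinal or categorical auxiliary ",
         "variable; use DM, CvM or maxLM for continuous orderings",
         call. = FALSE)
  o
}

#' Double-maximum statistic
#'
#' Maximum of |B_ij| over all observations i and tested parameters j.
#' @param proc a \code{\link{empirical_process}} result.
#' @param parm tested parameters: integer indices (1-based, parameter-table
#'   order) or labels; \code{NULL} tests all.
#' @return nonnegative scalar.
#' @export
stat_dm <- function(proc, parm = NULL) {
  max(abs(proc_rows(proc, parm)))
}

#' Cramer-von Mises statistic
#'
#' \eqn{n^{-1} \sum_i \sum_j B_{ij}^2}.
#' @inheritParams stat_dm
#' @export
stat_cvm <- function(proc, parm = NULL) {
  sum(proc_rows(proc, parm)^2) / proc$n
}

#' Maximum Lagrange multiplier statistic (continuous ordering)
#'
#' \eqn{\max_i \{ (i/n)(1 - i/n) \}^{-1} \sum_j B_{ij}^2} over the trimmed
#' window; the weight diverges at the ends, so trimming is required.
#' @inheritParams stat_dm
#' @param trim lower/upper trimming fractions (defaults 0.1 and 0.9).
#' @export
stat_maxlm <- function(proc, parm = NULL, trim = c(0.1, 0.9)) {
  check_trim(trim)
  n <- proc$n
  lo <- max(1L, ceiling(n * trim[1L]))
  hi <- min(n - 1L, floor(n * trim[2L]))
  if (lo > hi) stop("trim window contains no observation index",
                    call. = FALSE)
  B <- proc_rows(proc, parm)
  i <- lo:hi
  w <- 1 / ((i / n) * (1 - i / n))
  max(w * rowSums(B[i, , drop = FALSE]^2))
}

check_trim <- function(trim) {
  if (length(trim) != 2L || !(0 < trim[1L] && trim[1L] < trim[2L] &&
                                trim[2L] < 1))
    stop("trim must satisfy 0 < lower < upper < 1", call. = FALSE)
}

#' Weighted ordinal double-maximum statistic
#'
#' Evaluated only at the tie points \eqn{i_\ell = \lfloor n t_\ell \rfloor}:
#' \eqn{\max_\ell \{ (i_\ell/n)(1 - i_\ell/n) \}^{-1/2} \max_j |B_{i_\ell j}|}.
#' Invariant to reordering individuals within a level.
#' @inheritParams stat_dm
#' @export
stat_wdmo <- function(proc, parm = NULL) {
  o <- tie_struct(proc)
  if (o$m < 2L) stop("ordinal statistics need at least 2 levels",
                     call. = FALSE)
  B <- proc_rows(proc, parm)
  tt <- o$i_l / proc$n
  w <- 1 / sqrt(tt * (1 - tt))
  max(w * apply(abs(B[o$i_l, , drop = FALSE]), 1, max))
}

#' Ordinal maximum Lagrange multiplier statistic
#'
#' \eqn{\max_\ell \{ (i_\ell/n)(1 - i_\ell/n) \}^{-1} \sum_j B_{i_\ell j}^2}.
#' With a single tested parameter it equals the square of
#' \code{\link{stat_wdmo}}.
#' @inheritParams stat_dm
#' @export
stat_maxlmo <- function(proc, parm = NULL) {
  o <- tie_struct(proc)
  if (o$m < 2L) stop("ordinal statistics need at least 2 levels",
                     call. = FALSE)
  B <- proc_rows(proc, parm)
  tt <- o$i_l / proc$n
  w <- 1 / (tt * (1 - tt))
  max(w * rowSums(B[o$i_l, , drop = FALSE]^2))
}

#' Unordered Lagrange multiplier statistic
#'
#' Sum over level blocks of the squared process increments weighted by the
#' inverse block length,
#' \eqn{\sum_{\ell} (t_\ell - t_{\ell-1})^{-1} \sum_j
#' (B_{i_\ell j} - B_{i_{\ell-1} j})^2} with \eqn{i_0 = 0} and
#' \eqn{i_m = n}; asymptotically \eqn{\chi^2_{k(m-1)}} and equivalent to
#' the likelihood ratio test across the level-defined groups.
#' @inheritParams stat_dm
#' @export
stat_lmuo <- function(proc, parm = NULL) {
  o <- tie_struct(proc)
  idx <- resolve_parm(proc, parm)
  bounds <- c(0L, o$i_l, proc$n)
  Bb <- proc$B[bounds + 1L, idx, drop = FALSE]  # rows of B including row 0
  w <- 1 / diff(bounds / proc$n)
  sum(diff(Bb)^2 * w)
}

#' Score-based measurement invariance test
#'
#' Orchestrates the full test: extracts the casewise scores of a fitted CFA
#' model, estimates the information matrix, orders observations by the
#' auxiliary variable, builds the decorrelated cumulative score process,
#' evaluates the requested functional on the tested parameter subset, and
#' attaches a p-value from the matching null distribution (analytic for DM,
#' WDMo and LMuo; simulated for CvM, maxLM and maxLMo).
#'
#' @param fit a converged \code{\link{cfa_fit}}.
#' @param order_by auxiliary variable, length n (rows retained by the fit,
#'   in input order), or the name of a column used when fitting.
#' @param parm tested parameters: 1-based indices into the free-parameter
#'   order or labels; \code{NULL} tests all.
#' @param functional one of \code{"DM"}, \code{"CvM"}, \code{"maxLM"}
#'   (continuous ordering), \code{"WDMo"}, \code{"maxLMo"} (ordinal),
#'   \code{"LMuo"} (categorical).
#' @param vcov information matrix used for decorrelation: \code{"observed"}
#'   (default), \code{"opg"}, or \code{"expected"}.
#' @param treatment override the functional's default treatment of
#'   \code{order_by}. Treating tied data as continuous is supported but
#'   warned against: the result then depends on the arbitrary within-tie
#'   order.
#' @param trim trimming window for \code{maxLM}.
#' @param nrep replications for simulated null distributions (default 50000
#'   for \code{maxLMo}, 20000 for \code{CvM}/\code{maxLM}).
#' @param seed integer seed for simulated null distributions.
#' @param critvals optional precomputed \code{\link{ord_l2bb}} table for
#'   \code{maxLMo}; must match the data's tie proportions.
#' @return Object of class \code{"score_test"} with the statistic, p-value,
#'   tested labels, tie structure and critical-value provenance.
#' @examples
#' d <- simulate_gratitude(n = 300, seed = 1)
#' fit <- cfa_fit("f1 =~ gq_1 + gq_2 + gq_3 + gq_4 + gq_5", d,
#'                group = "agegroup", group_equal = "loadings")
#' score_test(fit, order_by = "agegroup", parm = 1:4, functional = "LMuo")
#' @export
score_test <- function(fit, order_by, parm = NULL,
                       functional = c("DM", "CvM", "maxLM", "WDMo",
                                      "maxLMo", "LMuo"),
                       vcov = c("observed", "opg", "expected"),
                       treatment = NULL, trim = c(0.1, 0.9),
                       nrep = NULL, seed = 1L, critvals = NULL) {
  stopifnot(inherits(fit, "cfa_fit"))
  functional <- match.arg(functional)
  vcov <- match.arg(vcov)

  v <- if (is.character(order_by) && length(order_by) == 1L) {
    if (is.null(fit$group) || order_by != fit$group)
      stop("order_by column must be supplied as a vector unless it is the ",
           "fit's grouping column", call. = FALSE)
    factor(fit$group_levels[fit$group_index], levels = fit$group_levels)
  } else order_by
  if (length(v) != fit$n)
    stop("order_by has length ", length(v), " but the fit used ", fit$n,
         " rows", call. = FALSE)

  default_treat <- switch(functional,
    DM = , CvM = , maxLM = "continuous",
    WDMo = , maxLMo = "ordinal", LMuo = "categorical")
  if (is.null(treatment)) treatment <- default_treat
  if (treatment == "continuous") {
    if (is.factor(v)) v <- as.integer(v)
    if (functional %in% c("WDMo", "maxLMo", "LMuo"))
      stop("functional ", functional, " needs ordinal or categorical ",
           "treatment", call. = FALSE)
    if (anyDuplicated(v))
      warning("ties in the auxiliary variable under continuous treatment: ",
              "results depend on the arbitrary within-tie order; consider ",
              "the ordinal functionals WDMo/maxLMo")
  } else if (functional %in% c("WDMo", "maxLMo", "LMuo") &&
             !anyDuplicated(v)) {
    stop("all values of the auxiliary variable are unique; the ordinal/",
         "categorical functionals are undefined - use DM, CvM or maxLM",
         call. = FALSE)
  }

  ordering <- order_observations(v, treatment)
  S <- scores(fit)
  info <- info_matrix(fit, vcov)
  proc <- empirical_process(S, info, ordering)
  idx <- resolve_parm(proc, parm)
  kk <- length(idx)

  stat <- switch(functional,
    DM = stat_dm(proc, idx),
    CvM = stat_cvm(proc, idx),
    maxLM = stat_maxlm(proc, idx, trim),
    WDMo = stat_wdmo(proc, idx),
    maxLMo = stat_maxlmo(proc, idx),
    LMuo = stat_lmuo(proc, idx))

  m <- ordering$m
  prov <- switch(functional,
    DM = list(method = "analytic (Brownian-bridge crossing series)"),
    WDMo = list(method = "analytic (tie-point Gaussian rectangle)"),
    LMuo = list(method = sprintf("chi-squared, df = %d", kk * (m - 1L))),
    CvM = , maxLM = {
      nr <- if (is.null(nrep)) 20000L else nrep
      list(method = "simulated (Brownian-bridge paths)", nrep = nr,
           seed = seed)
    },
    maxLMo = {
      if (!is.null(critvals)) list(method = "simulated (ord_l2bb table)",
                                   nrep = critvals$nrep,
                                   seed = critvals$seed)
      else list(method = "simulated (tie-point law)",
                nrep = if (is.null(nrep)) 50000L else nrep, seed = seed)
    })

  p <- switch(functional,
    DM = p_dm(stat, kk),
    CvM = p_cvm(stat, kk, nrep = prov$nrep, seed = seed),
    maxLM = p_maxlm(stat, kk, trim = trim, nrep = prov$nrep, seed = seed),
    WDMo = p_wdmo(stat, kk, ordering$t),
    LMuo = p_lmuo(stat, kk, m),
    maxLMo = {
      tab <- if (is.null(critvals))
        ord_l2bb(ordering$t, nproc = kk, nrep = prov$nrep, seed = seed)
      else critvals
      p_maxlmo(stat, kk, tab, t_check = ordering$t)
    })

  structure(list(statistic = stat, p.value = p, functional = functional,
                 parm = proc$labels[idx], parm_idx = idx, k = kk, n = fit$n,
                 m = m, t = ordering$t, vcov = vcov, trim = trim,
                 provenance = prov, process = proc),
            class = "score_test")
}

#' @export
print.score_test <- function(x, digits = 4, ...) {
  cat("\n\tScore-based measurement invariance test\n\n")
  cat("functional:", x$functional, "  information:", x$vcov, "\n")
  cat("tested parameters (k =", paste0(x$k, "):"),
      paste(x$parm, collapse = ", "), "\n")
  if (!is.null(x$m)) cat("levels of auxiliary variable: m =", x$m, "\n")
  cat("f(efp) = ", format(x$statistic, digits = digits),
      ", p-value = ", format(x$p.value, digits = digits), "\n", sep = "")
  cat("critical values:", x$provenance$method)
  if (!is.null(x$provenance$nrep))
    cat(" (nrep = ", x$provenance$nrep, ", seed = ", x$provenance$seed, ")",
        sep = "")
  cat("\n")
  invisible(x)
}
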