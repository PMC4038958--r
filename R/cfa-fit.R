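#' Fit a (multigroup) confirmatory factor analysis model by maximum likelihood
#'
#' Estimates the model-implied mean vector \eqn{\mu_g(\theta)} and covariance
#' matrix \eqn{\Sigma_g(\theta) = \Lambda_g \Phi_g \Lambda_g' + \Psi_g} per
#' group under the casewise multivariate-normal log-likelihood
#' \eqn{\sum_i \ell(\theta; x_i)}, with optional cross-group equality
#' constraints. Factor means are fixed to 0 in every group. Optimization is
#' quasi-Newton (\code{\link[stats]{nlminb}} with analytic gradients) on a
#' transformed parameter scale on which the implied covariance is positive
#' definite by construction, followed by Fisher-scoring polish; jittered
#' restarts are attempted on failure, and non-convergence is reported as an
#' error rather than a silent partial result.
#'
#' @param model a \code{\link{cfa_model}}, or a model-syntax string.
#' @param data data frame holding numeric indicator columns (and, if used,
#'   the grouping column). Incomplete rows on the modeled columns are
#'   dropped; the count is stored in the fit and shown by \code{summary}.
#' @param group optional name of a grouping column (factor or vector);
#'   groups are taken in factor-level (or sorted) order.
#' @param group_equal parameter classes constrained equal across groups; see
#'   \code{\link{cfa_ptable}}.
#' @param meanstructure logical; estimate indicator intercepts (default
#'   \code{TRUE}).
#' @param identification \code{"marker"} or \code{"variance"}; see
#'   \code{\link{cfa_ptable}}.
#' @param control list of optimizer settings: \code{maxit} (default 500),
#'   \code{restarts} (3), \code{grad_tol} (1e-5; convergence requires the
#'   total-gradient infinity norm below \code{grad_tol * sqrt(n)}),
#'   \code{polish_iter} (50).
#' @return An object of class \code{"cfa_fit"}; see the methods
#'   \code{print}, \code{summary}, \code{coef}, \code{logLik}, \code{vcov},
#'   \code{fitted}, \code{residuals}, \code{simulate}, \code{anova}, and the
#'   extractors \code{\link{scores}} and \code{\link{info_matrix}}.
#' @examples
#' d <- simulate_gratitude(n = 300, seed = 1)
#' fit <- cfa_fit("f1 =~ gq_1 + gq_2 + gq_3 + gq_4 + gq_5", d,
#'                group = "agegroup", group_equal = "loadings")
#' fit
#' @export
cfa_fit <- function(model, data, group = NULL, group_equal = character(),
                    meanstructure = TRUE,
                    identification = c("marker", "variance"),
                    control = list()) {
  if (is.character(model)) model <- cfa_model(model)
  stopifnot(inherits(model, "cfa_model"))
  identification <- match.arg(identification)
  ctrl <- utils::modifyList(list(maxit = 500L, restarts = 3L, grad_tol = 1e-5,
                                 polish_iter = 50L), control)

  for (f in names(model$factors))
    if (length(model$factors[[f]]) < 2L)
      stop("factor ", sQuote(f), " has a single indicator; ",
           "the model is not identified", call. = FALSE)
  miss <- setdiff(model$indicators, names(data))
  if (length(miss))
    stop("indicator column(s) not found in data: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (y in model$indicators)
    if (!is.numeric(data[[y]]))
      stop("indicator column ", sQuote(y), " is not numeric", call. = FALSE)
  if (!is.null(group) && !group %in% names(data))
    stop("grouping column ", sQuote(group), " not found in data",
         call. = FALSE)

  cols <- c(model$indicators, group)
  cc <- stats::complete.cases(data[cols])
  n_dropped <- sum(!cc)
  data <- data[cc, , drop = FALSE]

  if (is.null(group)) {
    group_levels <- "all"
    group_index <- rep.int(1L, nrow(data))
  } else {
    gv <- data[[group]]
    group_levels <- if (is.factor(gv)) levels(gv)[levels(gv) %in% unique(gv)]
                    else as.character(sort(unique(gv)))
    group_index <- match(as.character(gv), group_levels)
  }
  G <- length(group_levels)
  if (any(tabulate(group_index, G) < length(model$indicators) + 1L))
    stop("every group needs more observations than indicators", call. = FALSE)

  ptable <- cfa_ptable(model, G, group_equal, meanstructure, identification)
  k <- n_free(ptable)
  X <- as.matrix(data[model$indicators])
  n <- nrow(X)

  ss <- lapply(seq_len(G), function(g) {
    Xg <- X[group_index == g, , drop = FALSE]
    ng <- nrow(Xg)
    xbar <- colMeans(Xg)
    list(n = ng, xbar = xbar,
         S = crossprod(sweep(Xg, 2, xbar)) / ng)
  })

  start <- start_values(ptable, model, ss, identification, meanstructure)
  units <- build_transform(ptable)
  negll <- function(opt) -loglik_suff(opt2nat(opt, units), ptable, ss)
  neggr <- function(opt) {
    th <- opt2nat(opt, units)
    -drop(crossprod(transform_jacobian(opt, units, k),
                    grad_suff(th, ptable, ss)))
  }

  tol <- ctrl$grad_tol * sqrt(n)
  best <- NULL
  for (r in 0:ctrl$restarts) {
    th0 <- if (r == 0L) start else jitter_start(start, ptable)
    opt0 <- tryCatch(nat2opt(th0, units), error = function(e) NULL)
    if (is.null(opt0)) next
    res <- tryCatch(
      stats::nlminb(opt0, negll, neggr,
                    control = list(iter.max = ctrl$maxit,
                                   eval.max = 4L * ctrl$maxit,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    theta <- opt2nat(res$par, units)
    theta <- fisher_polish(theta, ptable, ss, n, tol, ctrl$polish_iter)
    g <- grad_suff(theta, ptable, ss)
    if (is.null(best) || -loglik_suff(theta, ptable, ss) < best$obj)
      best <- list(theta = theta, obj = -loglik_suff(theta, ptable, ss),
                   gradnorm = max(abs(g)))
    if (max(abs(g)) < tol) break
  }
  if (is.null(best))
    stop("CFA optimization failed in all starts", call. = FALSE)
  converged <- best$gradnorm < tol
  if (!converged)
    stop("CFA fit did not converge after ", ctrl$restarts + 1L,
         " start(s); gradient infinity norm ",
         format(best$gradnorm, digits = 3), " exceeds tolerance ",
         format(tol, digits = 3), call. = FALSE)

  theta <- best$theta
  names(theta) <- free_labels(ptable)
  cw <- casewise_loglik_all(theta, ptable, X, group_index)

  structure(list(
    model = model, ptable = ptable, coefficients = theta,
    loglik = sum(cw), casewise = cw, n = n, k = k,
    group = group, group_levels = group_levels, group_index = group_index,
    X = X, suffstats = ss, n_dropped = n_dropped,
    meanstructure = meanstructure, identification = identification,
    group_equal = group_equal, converged = converged,
    gradnorm = best$gradnorm, call = match.call()),
    class = "cfa_fit")
}

# pooled-moment start values
start_values <- function(ptable, model, ss, identification, meanstructure) {
  k <- attr(ptable, "k")
  G <- attr(ptable, "n_groups")
  n <- sum(vapply(ss, `[[`, 0, "n"))
  Spool <- Reduce(`+`, lapply(ss, function(z) z$n * z$S)) / n
  xbar_pool <- Reduce(`+`, lapply(ss, function(z) z$n * z$xbar)) / n
  inds <- model$indicators
  theta <- rep(NA_real_, k)
  for (i in seq_len(nrow(ptable))) {
    if (!ptable$free[i]) next
    fi <- ptable$free_index[i]
    g <- ptable$group[i]
    val <- switch(ptable$role[i],
      nu = ss[[g]]$xbar[ptable$row[i]],
      psi = 0.5 * Spool[ptable$row[i], ptable$row[i]],
      lambda = {
        f <- names(model$factors)[ptable$col[i]]
        m <- match(model$factors[[f]][1L], inds)
        j <- ptable$row[i]
        if (identification == "marker")
          max(min(Spool[j, m] / Spool[m, m], 3), -3)
        else sqrt(0.5 * Spool[j, j])
      },
      phi = {
        if (ptable$row[i] == ptable$col[i]) {
          f <- names(model$factors)[ptable$row[i]]
          m <- match(model$factors[[f]][1L], inds)
          0.5 * Spool[m, m]
        } else 0.1
      })
    if (is.na(theta[fi])) theta[fi] <- val
  }
  theta
}

jitter_start <- function(start, ptable) {
  role <- character(length(start))
  for (i in seq_len(nrow(ptable)))
    if (ptable$free[i]) role[ptable$free_index[i]] <- ptable$role[i]
  mult <- exp(stats::runif(length(start), -0.25, 0.25))
  out <- ifelse(role %in% c("psi"), start * mult,
                ifelse(role == "nu", start + stats::rnorm(length(start), 0, 0.1),
                       start * mult))
  # keep factor correlations in range
  out
}

# Fisher scoring with step halving: drives the gradient infinity norm to the
# convergence tolerance; equals Newton under correct specification and is a
# fast linear polish otherwise
fisher_polish <- function(theta, ptable, ss, n, tol, maxit) {
  w <- vapply(ss, `[[`, 0, "n") / n
  var_idx <- unique(ptable$free_index[ptable$free &
    (ptable$role == "psi" |
       (ptable$role == "phi" & ptable$row == ptable$col))])
  ll <- loglik_suff(theta, ptable, ss)
  for (it in seq_len(maxit)) {
    g <- grad_suff(theta, ptable, ss)
    if (max(abs(g)) < 0.01 * tol) break
    I <- expected_info_internal(theta, ptable, w)
    step <- tryCatch(drop(solve(n * I + diag(1e-10 * n, nrow(I)), g)),
                     error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (h in 0:20) {
      cand <- theta + step / 2^h
      if (length(var_idx) && any(cand[var_idx] <= 0)) next
      llc <- tryCatch(loglik_suff(cand, ptable, ss),
                      error = function(e) -Inf)
      if (is.finite(llc) && llc >= ll - 1e-10 * abs(ll)) {
        theta <- cand; ll <- llc; ok <- TRUE; break
      }
    }
    if (!ok) break
  }
  theta
}
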