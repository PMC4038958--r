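# Null distributions of the six functionals. Under the invariance
# hypothesis the decorrelated cumulative score process converges to k
# independent Brownian bridges; everything here is a functional of that
# limit. DM, WDMo and LMuo admit analytic (series, Gaussian-rectangle,
# chi-squared) tail probabilities; CvM, maxLM and maxLMo are simulated.

#' Distribution function of the supremum of |Brownian bridge|
#'
#' \eqn{P(\sup_t |BB(t)| \le c) = 1 + 2 \sum_{i \ge 1} (-1)^i
#' \exp(-2 i^2 c^2)}, series truncated at relative 1e-12.
#' @param c nonnegative quantile.
#' @return probability.
#' @export
bb_sup_cdf <- function(c) {
  vapply(c, function(ci) {
    if (ci <= 0) return(0)
    total <- 1
    for (i in 1:1000) {
      term <- 2 * (-1)^i * exp(-2 * i^2 * ci^2)
      total <- total + term
      if (abs(term) < 1e-12 * max(abs(total), 1e-300)) break
    }
    max(min(total, 1), 0)
  }, 0)
}

#' p-value of the double-maximum statistic
#'
#' Uses independence of the k decorrelated components:
#' \eqn{p = 1 - F(c)^k} with F the distribution of sup|BB|.
#' @param statistic observed DM value.
#' @param k number of tested parameters.
#' @export
p_dm <- function(statistic, k) {
  stopifnot(statistic >= 0, k >= 1)
  1 - bb_sup_cdf(statistic)^k
}

#' Brownian-bridge rectangle probability at tie points
#'
#' \eqn{P(|BB(t_\ell)| \le c \sqrt{t_\ell (1 - t_\ell)}\ \forall \ell)},
#' computed by iterated one-dimensional integration over the bridge's Markov
#' transitions on a grid (trapezoidal rule); this is the multivariate-normal
#' rectangle probability with covariance \eqn{t_a (1 - t_b)}, \eqn{a \le b}.
#' @param c weighted bound.
#' @param t increasing vector of interior time points (0 < t < 1).
#' @param ngrid grid points per level (default 501).
#' @return probability.
#' @export
bb_rect_prob <- function(c, t, ngrid = 501L) {
  stopifnot(all(t > 0), all(t < 1), !is.unsorted(t, strictly = TRUE))
  if (c <= 0) return(0)
  bounds <- c * sqrt(t * (1 - t))
  x <- seq(-bounds[1L], bounds[1L], length.out = ngrid)
  f <- stats::dnorm(x, sd = sqrt(t[1L] * (1 - t[1L])))
  for (l in seq_along(t)[-1L]) {
    y <- seq(-bounds[l], bounds[l], length.out = ngrid)
    shrink <- (1 - t[l]) / (1 - t[l - 1L])
    v <- (t[l] - t[l - 1L]) * (1 - t[l]) / (1 - t[l - 1L])
    # transition density matrix: rows y, cols x
    Tm <- stats::dnorm(outer(y, shrink * x, `-`), sd = sqrt(v))
    w <- rep(diff(x)[1L], ngrid); w[c(1L, ngrid)] <- w[1L] / 2
    f <- drop(Tm %*% (f * w))
    x <- y
  }
  w <- rep(diff(x)[1L], ngrid); w[c(1L, ngrid)] <- w[1L] / 2
  min(max(sum(f * w), 0), 1)
}

#' p-value of the weighted ordinal double-maximum statistic
#'
#' The tie-point values of each decorrelated component are jointly Gaussian
#' with the Brownian-bridge covariance; the p-value is one minus the k-th
#' power of the rectangle probability.
#' @param statistic observed WDMo value.
#' @param k number of tested parameters.
#' @param t cumulative level proportions (length m-1).
#' @export
p_wdmo <- function(statistic, k, t) {
  stopifnot(k >= 1, length(t) >= 1)
  if (statistic <= 0) return(1)
  1 - bb_rect_prob(statistic, t)^k
}

#' Critical value of the WDMo statistic
#' @param alpha significance level.
#' @inheritParams p_wdmo
#' @export
wdmo_critval <- function(alpha, k, t) {
  stats::uniroot(function(c) p_wdmo(c, k, t) - alpha,
                 lower = 1e-6, upper = 20, tol = 1e-8)$root
}

#' p-value of the unordered Lagrange multiplier statistic
#'
#' Upper tail of the chi-squared distribution with k(m-1) degrees of
#' freedom; the statistic is asymptotically equivalent to the multigroup
#' likelihood ratio test.
#' @param statistic observed LMuo value.
#' @param k number of tested parameters.
#' @param m number of levels.
#' @export
p_lmuo <- function(statistic, k, m) {
  stopifnot(k >= 1, m >= 2)
  stats::pchisq(statistic, df = k * (m - 1), lower.tail = FALSE)
}

#' Simulate the exact tie-point law of the ordinal maxLM statistic
#'
#' Draws Brownian-bridge values at the tie points only (the finite
#' dimensional law is exact, no path grid needed), accumulates the weighted
#' sum of squares across components, and records the maximum over tie points
#' for each process dimension in \code{nproc}. Tables are reusable across
#' tests on the same data but not across data sets: they depend on the
#' cumulative level proportions.
#'
#' @param t cumulative level proportions (length m-1), e.g. from
#'   \code{\link{order_observations}}.
#' @param nproc process dimensions (numbers of tested parameters) to cover,
#'   default \code{1:20}.
#' @param nrep replications (default 50000).
#' @param seed integer seed.
#' @return Object of class \code{"ord_l2bb"}: list with the simulation
#'   settings and a \code{nrep x length(nproc)} sample matrix.
#' @export
ord_l2bb <- function(t, nproc = 1:20, nrep = 50000L, seed = 1L) {
  stopifnot(all(t > 0), all(t < 1), !is.unsorted(t, strictly = TRUE),
            all(nproc >= 1))
  nproc <- sort(unique(as.integer(nproc)))
  seed <- as.integer(seed)
  nrep <- as.integer(nrep)
  warn <- NULL
  if (nrep < 1000L) {
    warn <- sprintf("nrep = %d is small; critical values are unstable", nrep)
    warning(warn)
  }
  set.seed(seed)
  mlev <- length(t) + 1L
  dt <- diff(c(0, t, 1))
  wt <- 1 / (t * (1 - t))
  samples <- matrix(NA_real_, nrep, length(nproc))
  colnames(samples) <- as.character(nproc)
  running <- matrix(0, nrep, length(t))
  col <- 1L
  for (comp in seq_len(max(nproc))) {
    incr <- matrix(stats::rnorm(nrep * mlev), nrep, mlev)
    incr <- sweep(incr, 2, sqrt(dt), `*`)
    W <- t(apply(incr, 1, cumsum))
    B <- W[, seq_along(t), drop = FALSE] - outer(W[, mlev], t)
    running <- running + sweep(B^2, 2, wt, `*`)
    if (comp %in% nproc) {
      samples[, col] <- do.call(pmax, as.data.frame(running))
      col <- col + 1L
    }
  }
  structure(list(functional = "maxLMo", t = t, nproc = nproc, nrep = nrep,
                 seed = seed, samples = samples, warning = warn),
            class = "ord_l2bb")
}

#' @export
print.ord_l2bb <- function(x, ...) {
  cat("maxLMo critical-value table: m =", length(x$t) + 1L,
      "levels, nproc =", paste(range(x$nproc), collapse = ".."),
      ", nrep =", x$nrep, ", seed =", x$seed, "\n")
  cat("  t_l:", paste(format(x$t, digits = 4), collapse = " "), "\n")
  cat("  95% critical values:",
      paste(format(apply(x$samples, 2, stats::quantile, 0.95), digits = 4),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
quantile.ord_l2bb <- function(x, probs = 0.95, k = min(x$nproc), ...) {
  stats::quantile(x$samples[, as.character(k)], probs = probs, names = FALSE)
}

#' p-value of the ordinal maxLM statistic from a simulated table
#' @param statistic observed maxLMo value.
#' @param k number of tested parameters.
#' @param table an \code{\link{ord_l2bb}} table.
#' @param t_check optional tie proportions of the data at hand; an error is
#'   raised if they differ from the table's (tables are data specific).
#' @export
p_maxlmo <- function(statistic, k, table, t_check = NULL) {
  stopifnot(inherits(table, "ord_l2bb"))
  if (!is.null(t_check) &&
      (length(t_check) != length(table$t) ||
         max(abs(t_check - table$t)) > 1e-8))
    stop("critical-value table was simulated for different level ",
         "proportions; regenerate it with ord_l2bb() for this data",
         call. = FALSE)
  if (!k %in% table$nproc)
    stop("table does not cover k = ", k,
         "; regenerate it with ord_l2bb(..., nproc = ", k, ")",
         call. = FALSE)
  mean(table$samples[, as.character(k)] >= statistic)
}

#' Simulate Brownian-bridge functionals on a path grid
#'
#' Reference simulation for the continuous-ordering functionals: k
#' independent bridges on a regular grid, evaluated per replication.
#' @param functional \code{"DM"}, \code{"CvM"} or \code{"maxLM"}.
#' @param k number of components.
#' @param nrep replications.
#' @param grid number of grid points (default 1000).
#' @param seed integer seed.
#' @param trim trimming window (maxLM only).
#' @return numeric vector of \code{nrep} simulated functional values, with
#'   attributes \code{seed}, \code{nrep}, \code{grid}.
#' @export
simulate_bb_functionals <- function(functional = c("DM", "CvM", "maxLM"),
                                    k, nrep = 20000L, grid = 1000L,
                                    seed = 1L, trim = c(0.1, 0.9)) {
  functional <- match.arg(functional)
  stopifnot(k >= 1, nrep >= 1, grid >= 10)
  set.seed(seed)
  tg <- seq_len(grid) / grid
  use <- if (functional == "maxLM") {
    check_trim(trim)
    which(tg >= trim[1L] & tg <= trim[2L] & tg < 1)
  } else seq_len(grid)
  wlm <- if (functional == "maxLM") 1 / (tg[use] * (1 - tg[use]))
  out <- numeric(0)
  chunk <- max(1L, min(nrep, floor(4e6 / grid)))
  done <- 0L
  while (done < nrep) {
    nc <- min(chunk, nrep - done)
    acc <- NULL
    for (comp in seq_len(k)) {
      Z <- matrix(stats::rnorm(grid * nc, sd = sqrt(1 / grid)), grid, nc)
      W <- apply(Z, 2, cumsum)
      B <- W - outer(tg, W[grid, ])
      val <- switch(functional,
        DM = apply(abs(B), 2, max),
        CvM = colMeans(B^2),
        maxLM = B[use, , drop = FALSE]^2)
      acc <- if (is.null(acc)) val
             else if (functional == "DM") pmax(acc, val) else acc + val
    }
    stat <- switch(functional,
      DM = acc,
      CvM = acc,
      maxLM = apply(acc * wlm, 2, max))
    out <- c(out, stat)
    done <- done + nc
  }
  structure(out, seed = seed, nrep = nrep, grid = grid,
            functional = functional, k = k)
}

#' p-value of the Cramer-von Mises statistic (simulated)
#' @inheritParams p_dm
#' @param nrep,grid,seed simulation settings.
#' @export
p_cvm <- function(statistic, k, nrep = 20000L, grid = 1000L, seed = 1L) {
  s <- simulate_bb_functionals("CvM", k, nrep, grid, seed)
  mean(s >= statistic)
}

#' p-value of the maximum Lagrange multiplier statistic (simulated)
#' @inheritParams p_dm
#' @param trim trimming window.
#' @param nrep,grid,seed simulation settings.
#' @export
p_maxlm <- function(statistic, k, trim = c(0.1, 0.9), nrep = 20000L,
                    grid = 1000L, seed = 1L) {
  s <- simulate_bb_functionals("maxLM", k, nrep, grid, seed, trim)
  mean(s >= statistic)
}
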