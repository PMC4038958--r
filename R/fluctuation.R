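#' Order observations by an auxiliary variable
#'
#' Produces the ordering (and, for ordinal or categorical treatment, the tie
#' structure) used to build the cumulative score process. Continuous
#' treatment uses a stable sort, so tied observations keep their input order;
#' that order is arbitrary and test results depend on it, which is why the
#' ordinal statistics exist.
#'
#' @param v auxiliary variable, length n: numeric for continuous treatment;
#'   numeric, ordered factor, or factor for ordinal; anything coercible to a
#'   factor for categorical.
#' @param treatment \code{"continuous"}, \code{"ordinal"}, or
#'   \code{"categorical"}.
#' @return An object of class \code{"aux_ordering"}: list with the
#'   permutation \code{order}, \code{treatment}, and for tied treatments the
#'   level \code{labels}, \code{counts}, number of levels \code{m},
#'   cumulative proportions \code{t} (length m-1) and tie-point indices
#'   \code{i_l} = floor(n t).
#' @export
order_observations <- function(v,
                               treatment = c("continuous", "ordinal",
                                             "categorical")) {
  treatment <- match.arg(treatment)
  if (anyNA(v)) stop("auxiliary variable contains missing values",
                     call. = FALSE)
  n <- length(v)
  if (treatment == "continuous") {
    if (!is.numeric(v))
      stop("continuous treatment requires a numeric auxiliary variable",
           call. = FALSE)
    ord <- order(v)                       # stable: ties keep input order
    res <- list(treatment = treatment, order = ord, n = n,
                ties = anyDuplicated(v) > 0L)
  } else {
    f <- if (is.factor(v)) droplevels(v) else
      factor(v, levels = sort(unique(v)))
    ord <- order(as.integer(f))
    counts <- tabulate(as.integer(f), nbins = nlevels(f))
    m <- nlevels(f)
    t_l <- cumsum(counts)[-m] / n
    res <- list(treatment = treatment, order = ord, n = n,
                labels = levels(f), counts = counts, m = m,
                t = t_l, i_l = as.integer(floor(n * t_l)))
  }
  structure(res, class = "aux_ordering")
}

#' Symmetric inverse square root of a positive definite matrix
#'
#' Eigendecomposition-based root R with R M R = I. Near-singular input is an
#' error: a rank-deficient information matrix means some parameter
#' combination is not identified, and silently dropping directions would
#' change every downstream statistic.
#'
#' @param M symmetric positive definite matrix.
#' @param tol relative eigenvalue tolerance (default 1e-10).
#' @return symmetric matrix of the same dimension.
#' @export
matrix_inverse_sqrt <- function(M, tol = 1e-10) {
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop("matrix is not symmetric", call. = FALSE)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  bad <- e$values < tol * max(e$values)
  if (any(bad)) {
    labs <- colnames(M)
    hint <- if (!is.null(labs)) {
      w <- which.max(abs(e$vectors[, which(bad)[1L]]))
      paste0(" (largest weight on ", labs[w], ")")
    } else ""
    stop("information matrix is (near-)singular: ", sum(bad),
         " eigenvalue(s) below tolerance", hint, call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Decorrelated cumulative score process
#'
#' Builds the empirical fluctuation process: row r (r = 0..n) is
#' \eqn{\hat I^{-1/2} n^{-1/2} \sum_{i \le r} s(\hat\theta; x_{(i)})}, with
#' the observations ordered by the auxiliary variable. Decorrelation always
#' uses the full k x k information; testing a parameter subset is column
#' selection afterwards.
#'
#' @param S n x k score matrix (input row order).
#' @param info k x k per-observation information matrix.
#' @param ordering an \code{\link{order_observations}} result.
#' @param tol eigenvalue tolerance passed to
#'   \code{\link{matrix_inverse_sqrt}}.
#' @return object of class \code{"fluct_process"}: list with the (n+1) x k
#'   matrix \code{B}, the \code{ordering}, \code{n}, \code{k},
#'   \code{labels}.
#' @export
empirical_process <- function(S, info, ordering, tol = 1e-10) {
  stopifnot(inherits(ordering, "aux_ordering"))
  n <- nrow(S)
  if (n != ordering$n) stop("score matrix and ordering disagree on n",
                            call. = FALSE)
  if (ncol(S) != nrow(info)) stop("score and information dimensions disagree",
                                  call. = FALSE)
  if (is.null(colnames(info)) && !is.null(colnames(S)))
    dimnames(info) <- list(colnames(S), colnames(S))
  R <- matrix_inverse_sqrt(info, tol)
  CS <- apply(S[ordering$order, , drop = FALSE], 2, cumsum)
  B <- rbind(0, CS %*% R) / sqrt(n)
  colnames(B) <- colnames(S)
  structure(list(B = B, ordering = ordering, n = n, k = ncol(S),
                 labels = colnames(S)),
            class = "fluct_process")
}

#' @export
print.fluct_process <- function(x, ...) {
  cat("Cumulative score process: n =", x$n, ", k =", x$k,
      ", treatment =", x$ordering$treatment, "\n")
  invisible(x)
}
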