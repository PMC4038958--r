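# Optimizer parameterization. Free parameters are optimized on a transformed
# scale on which the implied covariance is positive definite by construction:
# unique variances on the log scale; factor covariance blocks either via a
# log-Cholesky factor (whole block free, marker identification) or via an
# atanh-transformed correlation (diagonal fixed to 1, variance
# identification, two factors). The natural scale remains the reporting and
# score scale throughout.

build_transform <- function(ptable) {
  k <- attr(ptable, "k")
  units <- list()
  covered <- logical(k)

  # psi: scalar log transforms
  psi_idx <- unique(ptable$free_index[ptable$role == "psi" & ptable$free])
  if (length(psi_idx)) {
    units[[length(units) + 1L]] <- list(type = "log", idx = psi_idx)
    covered[psi_idx] <- TRUE
  }

  # phi blocks, grouped by free-index signature (equality-shared blocks
  # appear once)
  G <- attr(ptable, "n_groups")
  sigs <- character(0)
  for (g in seq_len(G)) {
    rows <- which(ptable$group == g & ptable$role == "phi")
    if (!any(ptable$free[rows])) next
    q <- max(ptable$row[rows])
    fidx <- ptable$free_index[rows]
    sig <- paste(fidx, collapse = ",")
    if (sig %in% sigs) next
    sigs <- c(sigs, sig)
    diag_rows <- rows[ptable$row[rows] == ptable$col[rows]]
    off_rows <- rows[ptable$row[rows] != ptable$col[rows]]
    all_free <- all(ptable$free[rows])
    diag_fixed1 <- all(!ptable$free[diag_rows]) &&
      all(ptable$value[diag_rows] == 1) &&
      (length(off_rows) == 0L || all(ptable$free[off_rows]))
    if (all_free) {
      # order: (row, col) pairs with their free indices
      units[[length(units) + 1L]] <- list(
        type = "logchol", q = q,
        rc = cbind(ptable$row[rows], ptable$col[rows]),
        idx = fidx)
      covered[fidx] <- TRUE
    } else if (diag_fixed1) {
      if (length(off_rows) > 1L)
        stop("factor correlation structures with more than two factors and ",
             "fixed variances are not supported", call. = FALSE)
      if (length(off_rows) == 1L) {
        units[[length(units) + 1L]] <- list(type = "tanh",
                                            idx = ptable$free_index[off_rows])
        covered[ptable$free_index[off_rows]] <- TRUE
      }
    } else if (any(ptable$free[rows])) {
      stop("unsupported pattern of free/fixed factor (co)variances",
           call. = FALSE)
    }
  }

  # everything else: identity
  rest <- which(!covered)
  if (length(rest))
    units[[length(units) + 1L]] <- list(type = "identity", idx = rest)
  units
}

nat2opt <- function(theta, units) {
  out <- theta
  for (u in units) {
    switch(u$type,
      identity = NULL,
      log = out[u$idx] <- log(theta[u$idx]),
      tanh = out[u$idx] <- atanh(pmin(pmax(theta[u$idx], -0.999), 0.999)),
      logchol = {
        q <- u$q
        Phi <- matrix(0, q, q)
        for (a in seq_along(u$idx)) {
          Phi[u$rc[a, 1L], u$rc[a, 2L]] <- theta[u$idx[a]]
          Phi[u$rc[a, 2L], u$rc[a, 1L]] <- theta[u$idx[a]]
        }
        L <- t(chol(Phi))
        for (a in seq_along(u$idx)) {
          r <- u$rc[a, 1L]; s <- u$rc[a, 2L]
          out[u$idx[a]] <- if (r == s) log(L[r, r]) else L[r, s]
        }
      })
  }
  out
}

opt2nat <- function(opt, units) {
  out <- opt
  for (u in units) {
    switch(u$type,
      identity = NULL,
      log = out[u$idx] <- exp(opt[u$idx]),
      tanh = out[u$idx] <- tanh(opt[u$idx]),
      logchol = {
        q <- u$q
        L <- matrix(0, q, q)
        for (a in seq_along(u$idx)) {
          r <- u$rc[a, 1L]; s <- u$rc[a, 2L]
          L[r, s] <- if (r == s) exp(opt[u$idx[a]]) else opt[u$idx[a]]
        }
        Phi <- tcrossprod(L)
        for (a in seq_along(u$idx))
          out[u$idx[a]] <- Phi[u$rc[a, 1L], u$rc[a, 2L]]
      })
  }
  out
}

# Jacobian d(natural)/d(opt), as a sparse-ish dense matrix; block structure
# makes a numeric central difference per block both simple and accurate
transform_jacobian <- function(opt, units, k) {
  J <- diag(k)
  for (u in units) {
    switch(u$type,
      identity = NULL,
      log = {
        for (i in u$idx) J[i, i] <- exp(opt[i])
      },
      tanh = {
        for (i in u$idx) J[i, i] <- 1 - tanh(opt[i])^2
      },
      logchol = {
        h <- 1e-6
        for (a in seq_along(u$idx)) {
          op <- opt; om <- opt
          op[u$idx[a]] <- op[u$idx[a]] + h
          om[u$idx[a]] <- om[u$idx[a]] - h
          J[u$idx, u$idx[a]] <-
            (opt2nat(op, list(u))[u$idx] - opt2nat(om, list(u))[u$idx]) /
            (2 * h)
        }
      })
  }
  J
}
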