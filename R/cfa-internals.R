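# Internal machinery shared by the fitter, score extractor and information
# matrices. All functions take the free-parameter vector on the natural scale
# (theta) plus the parameter table; per-group model matrices are rebuilt on
# each call, which is cheap at CFA sizes.

# model matrices (Lambda, nu, psi vector, Phi) for one group
pt_matrices <- function(ptable, theta, g) {
  p <- max(ptable$row[ptable$role %in% c("lambda", "nu", "psi")])
  q <- max(ptable$row[ptable$role == "phi"])
  Lambda <- matrix(0, p, q)
  nu <- numeric(p)
  psi <- numeric(p)
  Phi <- matrix(0, q, q)
  rows <- which(ptable$group == g)
  for (i in rows) {
    val <- if (ptable$free[i]) theta[ptable$free_index[i]] else ptable$value[i]
    switch(ptable$role[i],
      lambda = Lambda[ptable$row[i], ptable$col[i]] <- val,
      nu = nu[ptable$row[i]] <- val,
      psi = psi[ptable$row[i]] <- val,
      phi = {
        Phi[ptable$row[i], ptable$col[i]] <- val
        Phi[ptable$col[i], ptable$row[i]] <- val
      })
  }
  list(Lambda = Lambda, nu = nu, psi = psi, Phi = Phi)
}

implied_moments <- function(mats) {
  Sigma <- mats$Lambda %*% mats$Phi %*% t(mats$Lambda) + diag(mats$psi,
                                                             length(mats$psi))
  list(mu = mats$nu, Sigma = Sigma)
}

# total multivariate-normal log-likelihood from per-group sufficient
# statistics ss: list of (n, xbar, S) with S the ML (divide-by-n) covariance
loglik_suff <- function(theta, ptable, ss) {
  G <- attr(ptable, "n_groups")
  total <- 0
  for (g in seq_len(G)) {
    mom <- implied_moments(pt_matrices(ptable, theta, g))
    ch <- tryCatch(chol(mom$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    p <- length(mom$mu)
    d <- ss[[g]]$xbar - mom$mu
    Sinv <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    total <- total - ss[[g]]$n / 2 *
      (p * log(2 * pi) + logdet + sum(Sinv * ss[[g]]$S) +
         drop(crossprod(d, Sinv %*% d)))
  }
  total
}

# analytic gradient of the total log-likelihood w.r.t. the natural-scale
# free parameters; equality-constrained entries accumulate across groups
grad_suff <- function(theta, ptable, ss) {
  G <- attr(ptable, "n_groups")
  k <- attr(ptable, "k")
  grad <- numeric(k)
  for (g in seq_len(G)) {
    mats <- pt_matrices(ptable, theta, g)
    mom <- implied_moments(mats)
    ch <- chol(mom$Sigma)
    Sinv <- chol2inv(ch)
    n_g <- ss[[g]]$n
    d <- ss[[g]]$xbar - mom$mu
    M <- Sinv %*% (ss[[g]]$S + tcrossprod(d) - mom$Sigma) %*% Sinv
    v <- drop(Sinv %*% d)
    LP <- mats$Lambda %*% mats$Phi          # p x q, column r = b for factor r
    rows <- which(ptable$group == g & ptable$free)
    for (i in rows) {
      fi <- ptable$free_index[i]
      j <- ptable$row[i]
      contrib <- switch(ptable$role[i],
        nu = n_g * v[j],
        lambda = n_g * drop(crossprod(LP[, ptable$col[i]], M[, j])),
        psi = n_g / 2 * M[j, j],
        phi = {
          r <- ptable$row[i]; s <- ptable$col[i]
          lr <- mats$Lambda[, r]; ls <- mats$Lambda[, s]
          if (r == s) n_g / 2 * drop(crossprod(lr, M %*% lr))
          else n_g * drop(crossprod(lr, M %*% ls))
        })
      grad[fi] <- grad[fi] + contrib
    }
  }
  grad
}

# casewise log-likelihoods (length n, original row order)
casewise_loglik_all <- function(theta, ptable, X, group_index) {
  G <- attr(ptable, "n_groups")
  out <- numeric(nrow(X))
  for (g in seq_len(G)) {
    idx <- which(group_index == g)
    if (!length(idx)) next
    mom <- implied_moments(pt_matrices(ptable, theta, g))
    ch <- chol(mom$Sigma)
    p <- length(mom$mu)
    Z <- backsolve(ch, t(X[idx, , drop = FALSE]) - mom$mu, transpose = TRUE)
    out[idx] <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          colSums(Z^2))
  }
  out
}

# n x k matrix of casewise scores (gradients of the casewise log-likelihood)
score_matrix_internal <- function(theta, ptable, X, group_index) {
  G <- attr(ptable, "n_groups")
  k <- attr(ptable, "k")
  S <- matrix(0, nrow(X), k)
  for (g in seq_len(G)) {
    idx <- which(group_index == g)
    if (!length(idx)) next
    mats <- pt_matrices(ptable, theta, g)
    mom <- implied_moments(mats)
    Sinv <- chol2inv(chol(mom$Sigma))
    D <- sweep(X[idx, , drop = FALSE], 2, mom$mu)
    Q <- D %*% Sinv
    LP <- mats$Lambda %*% mats$Phi
    rows <- which(ptable$group == g & ptable$free)
    for (i in rows) {
      fi <- ptable$free_index[i]
      j <- ptable$row[i]
      col <- switch(ptable$role[i],
        nu = Q[, j],
        psi = 0.5 * (Q[, j]^2 - Sinv[j, j]),
        lambda = {
          u <- drop(Sinv %*% LP[, ptable$col[i]])
          (D %*% u) * Q[, j] - u[j]
        },
        phi = {
          r <- ptable$row[i]; s <- ptable$col[i]
          ur <- drop(Sinv %*% mats$Lambda[, r])
          us <- drop(Sinv %*% mats$Lambda[, s])
          if (r == s)
            0.5 * ((D %*% ur)^2 - drop(crossprod(mats$Lambda[, r], ur)))
          else
            (D %*% ur) * (D %*% us) - drop(crossprod(mats$Lambda[, r], us))
        })
      S[idx, fi] <- S[idx, fi] + col
    }
  }
  S
}

# expected (Fisher) information per observation, weighted by group shares
expected_info_internal <- function(theta, ptable, weights) {
  G <- attr(ptable, "n_groups")
  k <- attr(ptable, "k")
  I <- matrix(0, k, k)
  for (g in seq_len(G)) {
    mats <- pt_matrices(ptable, theta, g)
    mom <- implied_moments(mats)
    Sinv <- chol2inv(chol(mom$Sigma))
    p <- length(mom$mu)
    rows <- which(ptable$group == g & ptable$free)
    fi <- ptable$free_index[rows]
    dmu <- matrix(0, p, length(rows))
    Clist <- vector("list", length(rows))   # Sinv %*% dSigma
    Dlist <- vector("list", length(rows))
    for (a in seq_along(rows)) {
      i <- rows[a]
      j <- ptable$row[i]
      if (ptable$role[i] == "nu") {
        dmu[j, a] <- 1
      } else {
        Dm <- switch(ptable$role[i],
          psi = {
            Z <- matrix(0, p, p); Z[j, j] <- 1; Z
          },
          lambda = {
            b <- drop(mats$Lambda %*% mats$Phi[, ptable$col[i]])
            Z <- matrix(0, p, p)
            Z[j, ] <- Z[j, ] + b; Z[, j] <- Z[, j] + b
            Z
          },
          phi = {
            r <- ptable$row[i]; s <- ptable$col[i]
            lr <- mats$Lambda[, r]; ls <- mats$Lambda[, s]
            if (r == s) tcrossprod(lr) else tcrossprod(lr, ls) +
              tcrossprod(ls, lr)
          })
        Dlist[[a]] <- Dm
        Clist[[a]] <- Sinv %*% Dm
      }
    }
    Ig <- matrix(0, length(rows), length(rows))
    for (a in seq_along(rows)) for (b in seq_len(a)) {
      val <- drop(crossprod(dmu[, a], Sinv %*% dmu[, b]))
      if (!is.null(Clist[[a]]) && !is.null(Clist[[b]]))
        val <- val + 0.5 * sum(Clist[[a]] * t(Clist[[b]]))
      Ig[a, b] <- Ig[b, a] <- val
    }
    I[fi, fi] <- I[fi, fi] + weights[g] * Ig
  }
  (I + t(I)) / 2
}

# observed information per observation: central finite differences of the
# analytic total gradient
observed_info_internal <- function(theta, ptable, ss, n) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- 6e-6 * (1 + abs(theta[i]))
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    H[, i] <- (grad_suff(tp, ptable, ss) - grad_suff(tm, ptable, ss)) / (2 * h)
  }
  -(H + t(H)) / (2 * n)
}
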