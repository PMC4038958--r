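# Independent brute-force oracles for the six functionals: explicit loops
# over (i, j), written directly from the definitions, sharing no code with
# the package implementations.

bf_dm <- function(B) {
  n <- nrow(B); k <- ncol(B)
  best <- 0
  for (i in 1:n) for (j in 1:k) best <- max(best, abs(B[i, j]))
  best
}

bf_cvm <- function(B) {
  n <- nrow(B); k <- ncol(B)
  total <- 0
  for (i in 1:n) for (j in 1:k) total <- total + B[i, j]^2
  total / n
}

bf_maxlm <- function(B, lower, upper) {
  n <- nrow(B)
  best <- -Inf
  for (i in ceiling(n * lower):floor(n * upper)) {
    if (i >= n) next
    ssq <- 0
    for (j in 1:ncol(B)) ssq <- ssq + B[i, j]^2
    val <- ssq / ((i / n) * (1 - i / n))
    best <- max(best, val)
  }
  best
}

bf_wdmo <- function(B, i_l) {
  n <- nrow(B)
  best <- -Inf
  for (il in i_l) {
    t <- il / n
    inner <- 0
    for (j in 1:ncol(B)) inner <- max(inner, abs(B[il, j]))
    best <- max(best, inner / sqrt(t * (1 - t)))
  }
  best
}

bf_maxlmo <- function(B, i_l) {
  n <- nrow(B)
  best <- -Inf
  for (il in i_l) {
    t <- il / n
    ssq <- 0
    for (j in 1:ncol(B)) ssq <- ssq + B[il, j]^2
    best <- max(best, ssq / (t * (1 - t)))
  }
  best
}

bf_lmuo <- function(B, i_l) {
  n <- nrow(B)
  bounds <- c(0, i_l, n)
  total <- 0
  for (l in 2:length(bounds)) {
    dt <- (bounds[l] - bounds[l - 1]) / n
    for (j in 1:ncol(B)) {
      prev <- if (bounds[l - 1] == 0) 0 else B[bounds[l - 1], j]
      total <- total + (B[bounds[l], j] - prev)^2 / dt
    }
  }
  total
}

# wrap an arbitrary n x k matrix (rows i = 1..n) as a fluctuation process
# with a fabricated ordinal tie structure
toy_process <- function(B, counts = NULL) {
  n <- nrow(B)
  if (is.null(counts)) counts <- rep(n %/% 2, 2)
  v <- rep(seq_along(counts), counts)
  o <- order_observations(v, "ordinal")
  structure(list(B = rbind(0, B), ordering = o, n = n, k = ncol(B),
                 labels = paste0("p", seq_len(ncol(B)))),
            class = "fluct_process")
}

# small two-factor null data set + fit, shared across tests
fit_small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dgp <- cfa_dgp()
      d <- generate_dataset(dgp, n = 240, m = 4, seed = 42)
      cache <<- list(dgp = dgp, data = d,
                     fit = cfa_fit(sim_model(), d,
                                   identification = "variance"))
    }
    cache
  }
})
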