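#' Build the parameter table of a (multigroup) CFA model
#'
#' Enumerates every model parameter (factor loadings, intercepts, unique
#' variances, factor variances/covariances) for each group, applies the
#' identification convention and any cross-group equality constraints, and
#' assigns free-parameter indices 1..k in deterministic order: within each
#' group, loadings (factor by factor, in syntax order), then intercepts, then
#' unique variances, then factor variances and covariances; groups in level
#' order. Equality-constrained parameters share the index of their first
#' occurrence, so e.g. in a loadings-constrained one-factor five-indicator
#' model the four free loadings occupy indices 1 to 4.
#'
#' @param model a \code{\link{cfa_model}}.
#' @param n_groups number of groups (>= 1).
#' @param group_equal character vector of parameter classes constrained equal
#'   across groups; any of \code{"loadings"}, \code{"intercepts"},
#'   \code{"residuals"}, \code{"lv.variances"}, \code{"lv.covariances"}.
#' @param meanstructure logical; include indicator intercepts.
#' @param identification \code{"marker"} fixes the first loading per factor
#'   to 1 and frees factor variances; \code{"variance"} fixes factor
#'   variances to 1 and frees all loadings.
#' @return A data frame of class \code{"cfa_ptable"} with one row per
#'   parameter and columns \code{label}, \code{base} (group-free label),
#'   \code{role} (\code{lambda}, \code{nu}, \code{psi}, \code{phi}),
#'   \code{group}, \code{row}, \code{col} (indices into the group's
#'   \eqn{\Lambda}, \eqn{\nu}, \eqn{\Psi}, \eqn{\Phi}), \code{free},
#'   \code{value} (fixed value or \code{NA}), and \code{free_index}.
#' @export
cfa_ptable <- function(model, n_groups = 1L, group_equal = character(),
                       meanstructure = TRUE,
                       identification = c("marker", "variance")) {
  stopifnot(inherits(model, "cfa_model"), n_groups >= 1L)
  identification <- match.arg(identification)
  ok <- c("loadings", "intercepts", "residuals", "lv.variances",
          "lv.covariances")
  if (length(group_equal) && !all(group_equal %in% ok))
    stop("unknown group_equal entries: ",
         paste(setdiff(group_equal, ok), collapse = ", "), call. = FALSE)

  inds <- model$indicators
  facs <- names(model$factors)
  p <- length(inds)
  q <- length(facs)

  rows <- list()
  add <- function(base, role, group, i, j, free, value, eq) {
    rows[[length(rows) + 1L]] <<- list(base = base, role = role,
                                       group = group, row = i, col = j,
                                       free = free, value = value, eq = eq)
  }
  for (g in seq_len(n_groups)) {
    for (r in seq_len(q)) {
      f <- facs[r]
      for (y in model$factors[[f]]) {
        i <- match(y, inds)
        marker <- identification == "marker" && y == model$factors[[f]][1L]
        add(paste0(f, "=~", y), "lambda", g, i, r,
            free = !marker, value = if (marker) 1 else NA_real_,
            eq = "loadings" %in% group_equal)
      }
    }
    if (meanstructure)
      for (y in inds)
        add(paste0(y, "~1"), "nu", g, match(y, inds), NA_integer_,
            free = TRUE, value = NA_real_,
            eq = "intercepts" %in% group_equal)
    for (y in inds)
      add(paste0(y, "~~", y), "psi", g, match(y, inds), NA_integer_,
          free = TRUE, value = NA_real_,
          eq = "residuals" %in% group_equal)
    for (r in seq_len(q)) {
      fixedvar <- identification == "variance"
      add(paste0(facs[r], "~~", facs[r]), "phi", g, r, r,
          free = !fixedvar, value = if (fixedvar) 1 else NA_real_,
          eq = "lv.variances" %in% group_equal)
    }
    if (q > 1L)
      for (s in seq_len(q - 1L)) for (r in seq.int(s + 1L, q))
        add(paste0(facs[s], "~~", facs[r]), "phi", g, r, s,
            free = TRUE, value = NA_real_,
            eq = "lv.covariances" %in% group_equal)
  }

  tab <- do.call(rbind, lapply(rows, function(z)
    data.frame(base = z$base, role = z$role, group = z$group, row = z$row,
               col = z$col, free = z$free, value = z$value, eq = z$eq,
               stringsAsFactors = FALSE)))

  # free-parameter indexing; equality sets collapse onto first occurrence
  tab$free_index <- NA_integer_
  seen <- new.env(parent = emptyenv())
  k <- 0L
  for (ii in seq_len(nrow(tab))) {
    if (!tab$free[ii]) next
    key <- tab$base[ii]
    if (tab$eq[ii] && !is.null(seen[[key]])) {
      tab$free_index[ii] <- seen[[key]]
    } else {
      k <- k + 1L
      tab$free_index[ii] <- k
      if (tab$eq[ii]) seen[[key]] <- k
    }
  }
  tab$label <- if (n_groups > 1L)
    ifelse(tab$eq, tab$base, paste0(tab$base, ".g", tab$group)) else tab$base
  tab$eq <- NULL
  attr(tab, "k") <- k
  attr(tab, "n_groups") <- n_groups
  attr(tab, "meanstructure") <- meanstructure
  attr(tab, "identification") <- identification
  class(tab) <- c("cfa_ptable", "data.frame")
  tab
}

#' Number of free parameters of a parameter table
#' @param ptable a \code{cfa_ptable}.
#' @return integer count of distinct free parameters.
#' @export
n_free <- function(ptable) attr(ptable, "k")

#' Model degrees of freedom
#'
#' Difference between the number of observed moments
#' (\eqn{G \cdot p(p+3)/2} with mean structure, \eqn{G \cdot p(p+1)/2}
#' without) and the number of distinct free parameters.
#'
#' @inheritParams cfa_ptable
#' @return integer degrees of freedom.
#' @examples
#' m <- cfa_model("f1 =~ y1 + y2 + y3 + y4 + y5")
#' model_df(m, n_groups = 6, group_equal = "loadings")  # 50
#' model_df(m, n_groups = 6)                            # 30
#' @export
model_df <- function(model, n_groups = 1L, group_equal = character(),
                     meanstructure = TRUE, identification = "marker") {
  tab <- cfa_ptable(model, n_groups, group_equal, meanstructure,
                    identification)
  p <- length(model$indicators)
  moments <- if (meanstructure) n_groups * p * (p + 3) / 2
             else n_groups * p * (p + 1) / 2
  as.integer(moments - n_free(tab))
}

# Free-parameter labels in index order
free_labels <- function(ptable) {
  k <- n_free(ptable)
  out <- character(k)
  for (i in seq_len(nrow(ptable)))
    if (ptable$free[i] && !nzchar(out[ptable$free_index[i]]))
      out[ptable$free_index[i]] <- ptable$label[i]
  out
}
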