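#' Read an observation table from delimited text
#'
#' Rectangular CSV/TSV with a header row, one observation per row. Named
#' item columns must be numeric; rows with missing values in the used
#' columns are dropped and the count is reported as a message and stored in
#' the \code{"n_dropped"} attribute.
#'
#' @param path file path; delimiter inferred from the extension
#'   (\code{.tsv}/\code{.tab} = tab, otherwise comma) unless given.
#' @param items optional character vector of item columns to validate.
#' @param aux optional auxiliary/grouping column name to require.
#' @param delimiter field separator override.
#' @return data frame.
#' @export
read_observations <- function(path, items = NULL, aux = NULL,
                              delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (!is.null(delimiter)) delimiter
         else if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t"
         else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  used <- c(items, aux)
  if (length(used)) {
    miss <- setdiff(used, names(d))
    if (length(miss))
      stop("missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(items))
    for (y in items)
      if (!is.numeric(d[[y]]))
        stop("item column ", sQuote(y), " is not numeric", call. = FALSE)
  check <- if (length(used)) d[used] else d
  cc <- stats::complete.cases(check)
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message(n_dropped, " incomplete row(s) dropped")
  d <- d[cc, , drop = FALSE]
  attr(d, "n_dropped") <- n_dropped
  d
}

#' Serialize a score test result to JSON
#'
#' Stable schema (\code{schema_version} 1) carrying the statistic, p-value,
#' functional, tested parameter labels and, for simulated critical values,
#' their seed and replication count.
#' @param x a \code{\link{score_test}} result.
#' @param path optional output file; if omitted the JSON string is returned.
#' @export
score_test_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "score_test"))
  obj <- list(schema_version = 1L,
              functional = x$functional,
              statistic = x$statistic,
              p_value = x$p.value,
              parameters = as.list(x$parm),
              k = x$k, n = x$n,
              m = if (is.null(x$m)) NULL else x$m,
              t = if (is.null(x$t)) NULL else as.list(x$t),
              vcov = x$vcov,
              critical_values = x$provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a power table as TSV
#' @param x a \code{power_table} from \code{\link{run_power_study}}.
#' @param path output file.
#' @export
write_power_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Instability plot for ordinal functionals
#'
#' Plots the per-tie-point contribution of the WDMo or maxLMo statistic
#' against the ordered levels, with a dashed horizontal line at the
#' critical value; the invariance hypothesis is rejected when the sequence
#' crosses the line.
#'
#' @param x a \code{\link{score_test}} result with functional \code{"WDMo"}
#'   or \code{"maxLMo"}.
#' @param alpha significance level of the critical-value line.
#' @param file optional output path ending in \code{.png}, \code{.svg} or
#'   \code{.pdf}; plots to the active device when omitted.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @return invisibly, the per-level statistic contributions.
#' @export
instability_plot <- function(x, alpha = 0.05, file = NULL,
                             main = NULL, ...) {
  stopifnot(inherits(x, "score_test"))
  if (!x$functional %in% c("WDMo", "maxLMo"))
    stop("instability plots are defined for the ordinal functionals ",
         "WDMo and maxLMo", call. = FALSE)
  proc <- x$process
  o <- proc$ordering
  B <- proc$B[-1L, x$parm_idx, drop = FALSE]
  tt <- o$i_l / proc$n
  contrib <- if (x$functional == "WDMo")
    apply(abs(B[o$i_l, , drop = FALSE]), 1, max) / sqrt(tt * (1 - tt))
  else rowSums(B[o$i_l, , drop = FALSE]^2) / (tt * (1 - tt))
  crit <- if (x$functional == "WDMo") wdmo_critval(alpha, x$k, o$t)
  else {
    tab <- ord_l2bb(o$t, nproc = x$k,
                    nrep = if (is.null(x$provenance$nrep)) 50000L
                           else x$provenance$nrep,
                    seed = if (is.null(x$provenance$seed)) 1L
                           else x$provenance$seed)
    quantile(tab, 1 - alpha, k = x$k)
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
      png = grDevices::png(file, width = 700, height = 500),
      svg = grDevices::svg(file, width = 7, height = 5),
      pdf = grDevices::pdf(file, width = 7, height = 5),
      stop("unsupported plot format: ", ext, call. = FALSE))
    on.exit(grDevices::dev.off())
  }
  labs <- if (!is.null(o$labels)) o$labels[-o$m] else seq_along(contrib)
  plot(seq_along(contrib), contrib, type = "b", pch = 19,
       xaxt = "n", xlab = "level of auxiliary variable",
       ylab = paste(x$functional, "contribution"),
       ylim = c(0, max(contrib, crit) * 1.1),
       main = if (is.null(main))
         paste("Instability plot:", x$functional) else main, ...)
  graphics::axis(1, at = seq_along(contrib), labels = labs)
  graphics::abline(h = crit, lty = 2)
  invisible(stats::setNames(contrib, labs))
}

#' @export
plot.score_test <- function(x, ...) instability_plot(x, ...)
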