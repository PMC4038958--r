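#' Specify a confirmatory factor analysis model
#'
#' Parses a small model syntax in which each line defines one common factor
#' and its indicators, e.g. \code{"f1 =~ y1 + y2 + y3"}. The first indicator
#' listed for a factor is its marker indicator (loading fixed to 1 under the
#' marker identification convention).
#'
#' @param syntax character scalar (possibly multi-line) or character vector,
#'   one factor definition per line. Lines that are empty or start with
#'   \code{#} are ignored.
#' @return An object of class \code{"cfa_model"}: a list with elements
#'   \item{factors}{named list mapping factor name to character vector of
#'     indicator names, in syntax order;}
#'   \item{indicators}{character vector of all distinct indicators, in order
#'     of first appearance;}
#'   \item{syntax}{the cleaned syntax lines.}
#' @examples
#' m <- cfa_model("visual =~ x1 + x2 + x3")
#' m$factors
#' @export
cfa_model <- function(syntax) {
  if (length(syntax) == 0L || (length(syntax) == 1L && !nzchar(trimws(syntax))))
    stop("empty model syntax", call. = FALSE)
  lines <- unlist(strsplit(syntax, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("empty model syntax", call. = FALSE)

  factors <- list()
  for (ln in lines) {
    if (!grepl("=~", ln, fixed = TRUE))
      stop("malformed model syntax line (expected '<factor> =~ <ind> + ...'): ",
           sQuote(ln), call. = FALSE)
    parts <- strsplit(ln, "=~", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("malformed model syntax line: ", sQuote(ln), call. = FALSE)
    fac <- trimws(parts[1L])
    inds <- trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1L]])
    if (!nzchar(fac) || !grepl("^[A-Za-z._][A-Za-z0-9._]*$", fac))
      stop("invalid factor name in line: ", sQuote(ln), call. = FALSE)
    if (length(inds) == 0L || any(!nzchar(inds)))
      stop("missing indicator in line: ", sQuote(ln), call. = FALSE)
    bad <- inds[!grepl("^[A-Za-z._][A-Za-z0-9._]*$", inds)]
    if (length(bad))
      stop("invalid indicator name(s) ", paste(sQuote(bad), collapse = ", "),
           " in line: ", sQuote(ln), call. = FALSE)
    if (fac %in% names(factors))
      stop("duplicate factor name: ", sQuote(fac), call. = FALSE)
    if (anyDuplicated(inds))
      stop("duplicate indicator within factor ", sQuote(fac), call. = FALSE)
    factors[[fac]] <- inds
  }
  indicators <- unique(unlist(factors, use.names = FALSE))
  structure(list(factors = factors, indicators = indicators, syntax = lines),
            class = "cfa_model")
}

#' @export
print.cfa_model <- function(x, ...) {
  cat("CFA model:", length(x$factors), "factor(s),",
      length(x$indicators), "indicator(s)\n")
  for (f in names(x$factors))
    cat("  ", f, "=~", paste(x$factors[[f]], collapse = " + "), "\n")
  invisible(x)
}
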