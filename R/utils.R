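#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet `{A,C,G,T,N}`
#' (case preserved for ACGT; other characters map to `N`).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  vapply(x, function(s) {
    r <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(r, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Complement of single bases
#' @param x character vector of single bases.
#' @return complemented bases.
#' @keywords internal
comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Round half away from zero
#'
#' Reporting convention for printed percentages and fold values: R's
#' [round()] rounds half to even (1.25 -> 1.2), whereas figure-style
#' reporting rounds half away from zero (1.25 -> 1.3). Stored values are
#' never rounded; this helper is applied only when rendering.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_report(1.25, 1)  # 1.3
round_report <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Internal: stop with a classed condition so callers can test on class.
bq_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "bequant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
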