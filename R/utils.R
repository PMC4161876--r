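# Internal helpers: argument checking and interval arithmetic.
# All genomic coordinates inside the package are 0-based, half-open;
# conversion to/from 1-based formats happens only in formats_io.

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

check_interval <- function(chrom, start, end) {
  ok <- !is.na(chrom) & nzchar(chrom) & start >= 0 & start < end
  if (!all(ok)) {
    abort(sprintf(
      "invalid genomic interval(s) at row(s) %s: need non-empty chrom and 0 <= start < end",
      paste(which(!ok), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  invisible(strand)
}

# overlap length of [s1,e1) and [s2,e2), vectorised
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
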