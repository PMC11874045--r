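# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; cohort percentages are reported with
#' conventional half-up rounding (31.6 for 18/57).
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a trioppv-classed condition so the CLI can map validation
# failures to exit code 2.
trioppv_stop <- function(..., class = "trioppv_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Reciprocal overlap of two closed 1-based intervals; 0 when disjoint.
reciprocal_overlap <- function(start1, end1, start2, end2) {
  ov <- pmin(end1, end2) - pmax(start1, start2) + 1
  ov <- pmax(ov, 0)
  len1 <- end1 - start1 + 1
  len2 <- end2 - start2 + 1
  pmin(ov / len1, ov / len2)
}

# Deterministic TSV writer (no quoting surprises, fixed na encoding, never
# scientific notation for coordinates).
write_tsv <- function(df, path) {
  old <- options(scipen = 999)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ".", ""), quote = "", comment.char = "",
                    check.names = FALSE, ...)
}
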