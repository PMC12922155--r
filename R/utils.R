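# Shared helpers: rounding, percent formatting, abundance-column grammar.

#' Round half away from zero
#'
#' Commercial rounding used for every reported percentage: exact halves move
#' away from zero, so `round_half_out(70.768, 0)` is 71 and
#' `round_half_out(52.25, 1)` is 52.3. Base R's `round()` rounds half to even,
#' which does not reproduce hand-computed percentages.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_out(c(0.5, 1.5, -0.5))
#' round_half_out(52.25, 1)
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with half-away-from-zero rounding
#'
#' @param num numerator count.
#' @param den denominator count; must be positive.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
percentage <- function(num, den, digits = 1) {
  stopifnot(den > 0)
  round_half_out(100 * num / den, digits)
}

#' Timepoints and replicates of the quantification design
#'
#' The design is four timepoints (0, 15, 30, 90 min after treatment) with
#' three biological replicates each.
#' @return integer vector of timepoints (minutes).
#' @export
quant_timepoints <- function() c(0L, 15L, 30L, 90L)

#' @rdname quant_timepoints
#' @return integer vector of replicate indices.
#' @export
quant_replicates <- function() 1:3

#' Names of the abundance columns of a phosphopeptide table
#'
#' Columns are named `t{timepoint}_r{replicate}`, ordered timepoint-major:
#' `t0_r1 ... t90_r3`.
#' @return character vector of 12 column names.
#' @export
abundance_columns <- function() {
  as.vector(t(outer(quant_timepoints(), quant_replicates(),
                    function(t, r) sprintf("t%d_r%d", t, r))))
}

# Columns of one condition (timepoint).
condition_columns <- function(timepoint) {
  sprintf("t%d_r%d", timepoint, quant_replicates())
}

# The 20 standard amino acids, alphabetical.
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Deterministic TSV writer: no quoting, unix EOLs, NA as empty cell.
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

# Coerce AAStringSet or character to a named character vector without
# losing names (base as.character drops names on character input).
as_named_seqs <- function(x) {
  if (is.character(x)) x else as.character(x)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
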