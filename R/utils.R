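# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounding convention used for printed percentages in composition summaries:
#' nearest value, ties away from zero (so 9.95 -> 10, -0.5 -> -1). Base R's
#' `round()` uses banker's rounding, which does not match how percentages are
#' conventionally printed.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 9.95 * 10)) # 1, 2, 100
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, printed-style
#'
#' Computes `100 * count / total` rounded half away from zero to `digits`
#' decimals — the convention used when classification shares are quoted
#' (e.g. 437 of 4392 micrographs -> 10).
#'
#' @param count numerator count.
#' @param total denominator count, > 0.
#' @param digits decimal places (default 0).
#' @return numeric percentage.
#' @export
percent_share <- function(count, total, digits = 0L) {
  stopifnot(is.numeric(count), is.numeric(total), total > 0)
  round_half_away(100 * count / total, digits)
}

# stop with a classed condition so tests can match on class
stop_fibril <- function(msg, class) {
  stop(structure(
    class = c(class, "fibril_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# canonical PDB heavy-atom ordering within a residue
.canonical_atoms <- c(
  "N", "CA", "C", "O", "CB", "CG", "CG1", "CG2", "OG", "OG1", "SG",
  "CD", "CD1", "CD2", "OD1", "OD2", "ND1", "ND2", "SD",
  "CE", "CE1", "CE2", "CE3", "OE1", "OE2", "NE", "NE1", "NE2",
  "CZ", "CZ2", "CZ3", "NZ", "CH2", "OH", "NH1", "NH2", "OXT"
)

atom_order_key <- function(atom_name) {
  k <- match(atom_name, .canonical_atoms)
  k[is.na(k)] <- length(.canonical_atoms) + 1L
  k
}

.backbone_atoms <- c("N", "CA", "C", "O")
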