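#' Round half away from zero
#'
#' Report-style rounding: ties go away from zero (so 0.005 -> 0.01 at two
#' digits), matching how trial results are conventionally tabulated, instead
#' of the IEEE round-half-even used by [round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places.
#' @examples
#' round_half_up(14.835, 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: consistent error signalling with a subclass so tests can target it
fe_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "feedenergy_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: check a scalar numeric
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

VALID_BASES <- c("as_fed", "dry_matter")

check_basis <- function(basis) {
  if (!(is.character(basis) && length(basis) == 1L && basis %in% VALID_BASES)) {
    fe_stop(sprintf("basis must be one of: %s", paste(VALID_BASES, collapse = ", ")),
            "feedenergy_basis_error")
  }
  basis
}
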