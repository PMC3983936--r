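# Internal helpers shared across modules.

#' Round half away from zero at pixel emission
#'
#' All layout arithmetic is done at full double precision; rounding to whole
#' pixels happens once, at emission, with halves rounded up (528.75 -> 529,
#' 151.25 -> 151). `base::round()` rounds half to even and is not used here.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Signal a classed condition so callers can test on error class, not message.
ft_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ft_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# scalar checks ---------------------------------------------------------

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Colors are stored verbatim: either "#RRGGBB" or a CSS-style name (letters
# only). Validation is by pattern, never by normalization.
is_color_spec <- function(x) {
  is_scalar_string(x) &&
    (grepl("^#[0-9A-Fa-f]{6}$", x) || grepl("^[A-Za-z]+$", x))
}
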