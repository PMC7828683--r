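# Internal helpers shared across modules.

# Stable substream seed for (global seed, participant index, stream offset).
# Plain integer arithmetic mod 2^31 - 1 so cohorts are extensible: adding
# participants never reshuffles existing ones.
substream_seed <- function(seed, index, offset = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) * 48271 + as.numeric(index) * 16807 +
          as.numeric(offset) * 69621) %% m
  as.integer(s)
}

# Undefined-value sentinel used when an indicator has too few inputs.
undefined_value <- function(what) {
  warning(sprintf("%s: too few usable values; returning NA", what),
          call. = FALSE)
  NA_real_
}

#' Round half away from zero
#'
#' Report tables round to 2 decimals with ties going away from zero (the
#' convention of the study's printed tables), unlike [round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.345, 2) # 2.35
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
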