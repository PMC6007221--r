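#' @keywords internal
"_PACKAGE"

#' @importFrom stats quantile cor.test phyper setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers/tests can match on failure kind.
cn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "comorbnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Truncate (not round) toward zero at a fixed number of decimals
#'
#' Reported pleiotropy rates are truncated at two decimals (10.5481 -> 10.54,
#' 0.0689 -> 0.06), never rounded. A tiny rounding at the 6th decimal first
#' absorbs binary floating-point noise without changing any truncation at the
#' reported precision.
#'
#' @param x numeric vector.
#' @param digits number of decimals kept.
#' @return numeric vector truncated toward zero at `digits` decimals.
#' @examples
#' trunc_decimals(10.5481)  # 10.54
#' trunc_decimals(0.0689)   # 0.06
#' @export
trunc_decimals <- function(x, digits = 2) {
  scale <- 10^digits
  trunc(round(x * scale, 6)) / scale
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_nonempty_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}
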