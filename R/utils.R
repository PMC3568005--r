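#' @keywords internal
"_PACKAGE"

## internal assertion / RNG helpers shared across modules

stop_mixqspr <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mixqspr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All randomness is drawn under a caller-supplied seed, kept inside 32-bit
# integer range, without disturbing the global RNG stream.
with_seed <- function(seed, code) {
  seed <- as.integer(abs(as.numeric(seed)) %% 2147483647)
  withr::with_seed(seed, code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Canonical unordered key for a component pair
#'
#' Builds the identity key of a mixture from its two canonical component
#' structures, independent of component order; pure records (absent second
#' component) key on the single compound. Records sharing this key describe
#' the same mixture.
#'
#' @param comp1,comp2 character vectors of canonical structures; `comp2` may
#'   be `NA` for pure records.
#' @return character vector of keys.
#' @examples
#' pair_key(c("B", "A"), c("A", "B"))  # same key either way
#' @export
pair_key <- function(comp1, comp2) {
  ifelse(
    is.na(comp2),
    comp1,
    paste(pmin(comp1, comp2), pmax(comp1, comp2), sep = " || ")
  )
}
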