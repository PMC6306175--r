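`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Condition labels recognised in spot tables. "other" is a catch-all for
# conditions outside the wash/regeneration and pressing designs.
SPOT_CONDITIONS <- c(
  "initial", "washed", "incubated_4d", "incubated_10d",
  "unpressed", "unpressed_sputtered", "pressed", "pressed_sputtered", "other"
)
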