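# internal helpers shared across modules

STATES <- c("disease_free", "local_recurrence", "metastasis", "death")
ALIVE_STATES <- STATES[1:3]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_prob <- function(x) is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x <= 1)

check_prob <- function(x, name, len = NULL) {
  if (!is_prob(x))
    stopf("'%s' must be numeric probabilities in [0, 1]", name)
  if (!is.null(len) && length(x) != len)
    stopf("'%s' must have length %d (one value per model year), got %d",
          name, len, length(x))
  invisible(x)
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
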