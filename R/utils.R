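# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_panel <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) x * (x > 0)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stable log(sum(exp(a), exp(b))) elementwise for two arrays.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(pmin(a, b) - m))
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}

#' Derive a named random-number substream seed from a global seed
#'
#' All stochastic operations in the package draw their seed from a single
#' global seed through this function, so that a pipeline run is reproducible
#' end to end while its stages remain independently re-runnable.
#'
#' @param seed integer global seed.
#' @param name character substream label (e.g. `"simulate"`, `"stage2"`).
#' @return An integer seed strictly below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629 + 1)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_panel("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "))
  }
  invisible(df)
}
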