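#' @keywords internal
"_PACKAGE"

## Deterministic substream seeds: every generator draws from a stream derived
## from one top-level seed and a stream name, so components can be regenerated
## independently without sharing state.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  if (seed < 0) stop("seed must be non-negative")
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  mix <- (((seed %% 2147483647) * 48271) %% 2147483647 + h) %% 2147483647
  as.integer(mix)
}

with_substream <- function(seed, name, expr) {
  if (!is.null(seed)) set.seed(substream_seed(seed, name))
  expr
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_prob <- function(x, name, open = FALSE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  stop_if(any(is.na(x)) || bad,
          sprintf("'%s' must lie in %s", name, if (open) "(0,1)" else "[0,1]"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
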