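# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named random stream from one master
# seed, so each table/stage consumes its own stream and adding draws to one
# stage never perturbs another. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.numeric(seed) * 2654435769 + h) %% 2147483647
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop2(what, " must lie in [0, 1]")
  invisible(x)
}

conditions3 <- c("AMI", "HF", "PN")
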