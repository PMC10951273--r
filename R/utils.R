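# Named substream seeds: every stochastic operation derives its own seed from
# the user's single integer seed plus an operation label, so adding a new
# stochastic step never perturbs the draws of existing ones.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bg <- function(..., class = "breedgain_error") {
  stop(errorCondition(paste0(...), class = c(class, "breedgain_error")))
}

assert <- function(ok, ..., class = "breedgain_error") {
  if (!isTRUE(ok)) stop_bg(..., class = class)
  invisible(TRUE)
}

harmonic_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  length(x) / sum(1 / x)
}
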