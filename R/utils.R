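#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the package draw their own seed from a single
#' master seed plus a stage label (and optionally a replicate index), so that
#' pipelines are reproducible end to end while stages stay independent of
#' each other's consumption of the random stream.
#'
#' @param seed Integer master seed.
#' @param ... Character labels and/or integers identifying the stage and
#'   replicate.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "founders")
#' derive_seed(42, "cv", 17)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(paste(p, collapse = "/")) else as.double(p)
    for (k in codes) {
      # 31-bit multiplicative mix; stays in double-exact integer range
      h <- (h * 69069 + k + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# run expr under a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

assert_scalar_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s", name,
      if (open) "(0, 1)" else "[0, 1]"
    ))
  }
  invisible(x)
}
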