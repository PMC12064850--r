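#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a set of integer
# tags (participant index, run index, stage id ...). Kept below 2^31 - 1.
substream_seed <- function(master, ...) {
  tags <- c(master, ...)
  m <- 2147483647
  h <- 0
  for (t in tags) h <- (h * 1103515245 + as.numeric(t) + 12345) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
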