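# small shared helpers

# evaluate expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# exact fingerprint of a (nested) list of numeric arrays, for freeze checks
param_fingerprint <- function(theta) {
  raw <- serialize(unlist(theta, use.names = FALSE), NULL, version = 2L)
  # fold the raw stream into a short stable hex string
  v <- as.integer(raw)
  acc <- c(1L, 0L)
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    acc[1L] <- (acc[1L] + sum(chunk * (seq_along(chunk) %% 97L + 1L))) %% 1000000007L
    acc[2L] <- (acc[2L] + sum(chunk)) %% 998244353L
  }
  sprintf("%08x%08x", acc[1L], acc[2L])
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
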