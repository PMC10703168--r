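# Internal helpers: deterministic seeding and scoped RNG.

# Polynomial string hash folded into [1, 2^31 - 2]. All arguments are pasted
# with a separator unlikely to occur in taxon names. Products stay below 2^53
# so double arithmetic is exact.
seed_hash <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 17
  m <- 2147483647 # 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 1L) + 1)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
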