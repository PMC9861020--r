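# Internal helpers shared across modules.

# Derive a reproducible child seed from a parent seed and a stage/index tag.
# Stays below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483629
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_param <- function(...) stop(..., call. = FALSE)

rel_l2 <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}
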