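# Deterministic seed derivation.  A master seed is split into independent
# child streams by chaining a Lehmer-style update; all arithmetic stays
# below 2^53 so the result is exact in doubles.  Identical (seed, path)
# always yields the identical child seed, so partial regeneration of a
# cohort is stable.
splitSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# evaluate expr under a temporary RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stable fingerprint of an R object (config provenance)
fingerprintOf <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper)
    stop(sprintf("'%s' must be a finite number in [%s, %s]",
                 name, lower, upper), call. = FALSE)
  invisible(x)
}
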