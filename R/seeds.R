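# Deterministic seed derivation. All arithmetic stays below 2^53 so the
# doubles are exact; results are in [0, 2^31 - 2] and valid as R seeds.

SEED_MOD <- 2147483647  # 2^31 - 1

# polynomial string hash, stable across platforms and locales
hash_key <- function(key) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(as.character(key)))) {
    h <- (h * 31 + b) %% SEED_MOD
  }
  h
}

# mix a base seed with one or more small integers
derive_seed <- function(base, ...) {
  s <- as.numeric(base) %% SEED_MOD
  for (k in c(...)) {
    s <- (s * 69069 + as.numeric(k) + 1) %% SEED_MOD
  }
  s
}

# per-target seed: master seed mixed with a stable hash of the gene key, so
# results for one gene do not depend on which other genes are present
target_seed <- function(master, key) {
  derive_seed(derive_seed(master, hash_key(key)))
}

# evaluate expr under a temporary R RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% SEED_MOD))
  expr
}
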