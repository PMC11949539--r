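# RNG plumbing: run code under a local seed without clobbering the caller's
# stream, and derive reproducible integer sub-seeds (always < 2^31) so that
# per-pair / per-cell analyses are individually replayable.

local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Large prime < 2^31 keeps arithmetic exact in doubles (< 2^53 throughout).
.seed_mod <- 2147483629

# Deterministic string hash -> sub-seed, so every (group, species) pair gets
# its own stream and adding a column never perturbs the others' results.
pair_seed <- function(seed, group, species) {
  key <- paste(group, species, sep = "\r")
  h <- 0
  for (ch in utf8ToInt(enc2utf8(key))) h <- (h * 131 + ch) %% .seed_mod
  as.integer((as.numeric(seed) %% .seed_mod + h) %% .seed_mod)
}

# Sub-seed for the i-th unit of work (grid cell, run index, ...).
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% .seed_mod * 48271 + index * 7919) %% .seed_mod)
}
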