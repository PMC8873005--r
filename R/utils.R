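# Run code with a local RNG state: seeds deterministically, then restores
# whatever state the caller had, so simulators behave as pure functions.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-cell, per-protocol child seed from a master seed. Keeps
# results below 2^31 so they remain valid R integer seeds.
derive_seed <- function(master, cell_index, protocol_code) {
  (as.numeric(master) * 7919 + cell_index * 131 + protocol_code) %% 2147483647
}
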