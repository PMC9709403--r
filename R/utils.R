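# Seeded evaluation: every stochastic operation in the package draws its
# randomness inside with_seed(), so nothing perturbs (or depends on) the
# caller's global RNG state and all outputs are reproducible from one seed.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# sub-seed derivation: fold a stage label into a base seed, staying well
# below .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435 + offset) %% 2147480000)
}
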