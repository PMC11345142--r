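# Internal helpers: seed streams and seed-safe evaluation.

# Derive a child seed from a master seed and a stream id. Keeps every derived
# seed below 2^31 so it is always a valid R integer seed. The scheme is a fixed
# affine map modulo a Mersenne prime, so adding a stream never perturbs others.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), is.numeric(stream))
  as.integer((abs(as.numeric(master)) * 48271 + abs(as.numeric(stream)) * 30269) %%
               2147483629)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483629))
  force(code)
}

# Fixed 6-significant-digit formatting used by every text writer so that
# identical config + seed gives byte-identical output files.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.6g", x))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
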