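# Internal helpers shared across modules.

# Round half away from zero (fixed convention so grey normalisation is
# bit-exact across platforms; round() in R rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Stable per-stage seed derived from the run seed; keeps every derived seed a
# valid 32-bit integer and distinct across stage names.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

# Population standard deviation (denominator n), used for the AllDirection_SD
# texture variants.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}
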