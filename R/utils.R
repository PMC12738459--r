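# Seed plumbing: a single master seed deterministically derives independent
# per-stage, per-unit streams so that enlarging a cohort does not reshuffle
# the records already generated.

# Evaluate expr with a local RNG state seeded by `seed`; the caller's RNG
# state is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from a master seed and a stream label
# (stage name + unit indices). Multiplicative hashing on a Mersenne prime.
deriveSeed <- function(master, ...) {
  parts <- c(as.character(master), vapply(list(...), as.character, character(1)))
  h <- 0
  for (p in parts) {
    for (v in utf8ToInt(p)) h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

# Stable short hash of an R object (config fingerprinting for reports).
configHash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

# lognormal helpers: draw with a given mean and either SD or CV
rlnormMeanSd <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

rlnormMean1Cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}
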