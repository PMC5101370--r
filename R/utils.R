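# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded operations do not disturb
# the global stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Stable 31-bit string hash (polynomial rolling hash).  Used to derive
# per-image RNG substreams from (patient_id, image index) so that cohorts
# are extensible without reshuffling earlier images.
stable_hash <- function(s) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
  h
}

# Combine a master seed with a substream label into a 31-bit seed.
derive_seed <- function(master, label) {
  m <- 2147483647
  as.integer(((master %% m) * 69069 + stable_hash(label)) %% m)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (not sample) standard deviation.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# Luminance conversion used by the texture descriptors.
to_gray <- function(pixels) {
  if (length(dim(pixels)) == 2L) return(pixels)
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}
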