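# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package functions never clobber user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# One-hot encode integer labels 1..C as an N x C matrix.
one_hot <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > n_classes))
    stop("labels must lie in 1..", n_classes)
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
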