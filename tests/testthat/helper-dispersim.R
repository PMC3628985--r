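# Small-scale configuration used across tests.
tiny_cfg <- function(...) {
  defaults <- list(variant = "D_and_I", n_patches = 4L, K = 30L,
                   n_steps = 50, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

metapop_size <- function(patches) {
  sum(vapply(patches, function(p) nrow(p$residents), integer(1)))
}

all_individuals <- function(patches) {
  do.call(rbind, lapply(patches, `[[`, "residents"))
}

# Independent oracle for the exact two-sided sign test: enumerate all
# n + 1 outcomes and sum the probabilities of those no more likely than the
# observed count (tiny relative epsilon absorbs floating-point ties between
# mirror-image outcomes).
binom_two_sided_oracle <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-9)])
}

# 3-standard-error band for a Bernoulli frequency estimate.
within_3se <- function(observed_fraction, p, n) {
  abs(observed_fraction - p) <= 3 * sqrt(p * (1 - p) / n)
}
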