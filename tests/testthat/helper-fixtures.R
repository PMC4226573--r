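# Shared fixtures: all built in code at test time.

# The worked example triplet used across operation tests.
example_truth <- function(noise_sd = 0) {
  pulse_ground_truth(H = c(0.8, 0.6, 0.3), W = c(60, 90, 120),
                     C = c(150, 260, 450), noise_sd = noise_sd)
}

# Physiologic random truth, mirroring the generator's default morphology.
random_truth <- function(noise_sd = 0.01) {
  pulse_ground_truth(
    H = c(runif(1, 0.6, 0.85), runif(1, 0.55, 0.8), runif(1, 0.2, 0.4)),
    W = c(runif(1, 45, 70), runif(1, 75, 110), runif(1, 150, 210)),
    C = c(runif(1, 125, 160), runif(1, 230, 280), runif(1, 550, 680)),
    noise_sd = noise_sd)
}

# Reduced swarm configuration for tests where fit quality is not the
# point (determinism, batching, plumbing).
quick_fit_config <- function(seed = 1L) {
  fit_config(swarm_size = 15L, stage1_iters = 40L, stage2_iters = 15L,
             stage1_restarts = 1L, seed = seed)
}

# Independent brute-force objective: plain loops, no vectorization.
brute_force_objective <- function(H, W, C, S) {
  total <- 0
  for (n in seq_along(S)) {
    f <- 0
    for (k in 1:3) f <- f + H[k] * exp(-(n - C[k])^2 / (2 * W[k]^2))
    total <- total + (S[n] - f)^2
  }
  total
}

# Closed-form balanced two-way ANOVA (textbook sums of squares).
balanced_anova_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y); I <- nlevels(a); J <- nlevels(b)
  K <- n / (I * J)
  gm <- mean(y)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  cm <- tapply(y, interaction(a, b), mean)
  ssa <- J * K * sum((am - gm)^2)
  ssb <- I * K * sum((bm - gm)^2)
  sscell <- K * sum((cm - gm)^2)
  ssab <- sscell - ssa - ssb
  sse <- sum((y - ave(y, a, b))^2)
  dfa <- I - 1; dfb <- J - 1; dfab <- dfa * dfb; dfe <- n - I * J
  list(F = c(sex = (ssa / dfa) / (sse / dfe),
             sbp_category = (ssb / dfb) / (sse / dfe),
             interaction = (ssab / dfab) / (sse / dfe)),
       df = c(dfa, dfb, dfab, dfe))
}
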