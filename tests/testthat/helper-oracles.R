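# Independent oracles used across tests.

# Exact two-sided Mann-Whitney p by full enumeration of all rank
# assignments (no ties assumed).
mw_enumerate_p <- function(x, y) {
  n_x <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  sets <- utils::combn(length(pooled), n_x)
  us <- apply(sets, 2, function(idx) {
    r <- rank(pooled)[idx]
    sum(r) - n_x * (n_x + 1) / 2
  })
  mu <- n_x * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# OLS via the normal equations, independent of stats::lm.
ols_normal_equations <- function(X, y) {
  Xd <- cbind(1, X)
  drop(solve(crossprod(Xd), crossprod(Xd, y)))
}

# Small derivation-like cohort for quick tests.
quick_cohort <- function(n = 120, seed = 1, label = "derivation", ...) {
  p <- patient_derivation_preset(n = n, seed = seed)
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  simulate_cohort(bloodt1:::validate_generator_params(p), label)
}
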