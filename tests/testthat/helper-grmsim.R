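# Shared fixtures and a per-session cache for the heavier condition runs, so
# different test files can reuse the same Monte Carlo computations.

.grmsim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .grmsim_cache)) {
    assign(key, force(expr), envir = .grmsim_cache)
  }
  get(key, envir = .grmsim_cache)
}

# One condition cell run under the study's default settings.
cached_condition <- function(n, J, K, R, base_seed = 123L) {
  key <- sprintf("cond_n%d_J%d_K%d_R%d_s%d", n, J, K, R, base_seed)
  cached(key, {
    cfg <- study_config(n_values = n, J_values = J, K_values = K, R = R,
                        base_seed = base_seed)
    run_condition(grm_condition(n, J, K, R = R, base_seed = base_seed), cfg)
  })
}

# A large-sample fit against a known bank, reused by the recovery checks.
cached_largen_fit <- function() {
  cached("largen_fit", {
    set.seed(2024)
    bank <- generate_item_bank(J = 10, K = 5)
    theta <- rnorm(5000)
    resp <- simulate_responses(theta, bank)
    list(bank = bank, theta = theta, fit = fit_grm(resp, K = 5))
  })
}

# Small symmetric test bank used across files.
symmetric_bank <- function(J = 4, K = 4, a = 1.2) {
  b <- t(replicate(J, c(-1, 0, 1)[seq_len(K - 1)]))
  item_bank(a = rep(a, J), b = b)
}
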