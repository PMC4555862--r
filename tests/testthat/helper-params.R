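# Hand-assembled parameter sets for dynamics tests that do not need the
# full parameter-space machinery.
custom_params <- function(mu_a, mu_b, k_a, k_b, dilution = 0.1, inflow = 10,
                          quota_a = 1e-6, quota_b = 1e-6,
                          more_fit_id = "a", point_index = 1L,
                          inequality = 1) {
  structure(list(mu_a = mu_a, mu_b = mu_b, k_a = k_a, k_b = k_b,
                 dilution = dilution, inflow = inflow,
                 quota_a = quota_a, quota_b = quota_b,
                 more_fit_id = more_fit_id, point_index = point_index,
                 inequality = inequality),
            class = "regime_params")
}

# Independent hand evaluation of one synchronous deterministic update, kept
# free of any package function so it can serve as an oracle.
hand_step <- function(n_a, n_b, r, mu_a, mu_b, k_a, k_b, d, inflow, q) {
  g_a <- mu_a * n_a * r / (k_a + r)
  g_b <- mu_b * n_b * r / (k_b + r)
  n_a2 <- n_a + g_a - d * n_a
  n_b2 <- n_b + g_b - d * n_b
  if (n_a2 < 1) n_a2 <- 0
  if (n_b2 < 1) n_b2 <- 0
  r2 <- r + d * (inflow - r) - (q * g_a + q * g_b)
  list(n_a = n_a2, n_b = n_b2, resource = max(0, r2))
}
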