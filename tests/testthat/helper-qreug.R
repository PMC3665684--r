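# Published reference values used across tests.

# Estimates (coefficients, -lnL) of the per-group and restricted fits.
tab5 <- list(
  pooled          = c(b = 9.80, lam = 6.19, nll = 210.07),
  all_resettled   = c(b = 13.97, lam = 6.83, nll = 139.30),
  all_traditional = c(b = 4.39, lam = 5.74, nll = 64.68),
  sengezi_res     = c(b = 27.86, lam = 9.02, nll = 28.66),
  model3          = c(b_r = 14.04, b_t = 3.80, lam = 6.55, nll = 204.53)
)

# Model prediction columns (2 dp) for the all-resettled parameters and the
# Sengezi-resettled parameters: equilibrium offer probabilities and
# rejection rates over the grid 0, 0.1, ..., 1.
pred_res <- list(
  params = c(b = 13.97, lam = 6.83),
  offer_probs = c(.01, .01, .01, .06, .36, .37, .12, .02, .00, .00, .01),
  reject = c(1.00, 1.00, 0.95, 0.47, 0.09, 0.03, 0.03, 0.05, 0.24, 0.82, 0.99)
)
pred_sengezi <- list(
  params = c(b = 27.86, lam = 9.02),
  offer_probs = c(.01, .01, .01, .01, .30, .58, .07, .00, .01, .01, .01),
  reject = c(1.00, 1.00, 1.00, 0.91, 0.09, 0.01, 0.02, 0.22, 0.98, 1.00, 1.00)
)
pred_trad <- list(
  params = c(b = 4.39, lam = 5.74),
  reject = c(0.96, 0.81, 0.50, 0.23, 0.10, 0.05, 0.03, 0.03, 0.03, 0.04, 0.07)
)

# Observed per-offer counts over the full grid for the two status groups.
counts_res <- c(0, 2, 5, 3, 14, 59, 3, 0, 0, 0, 0)
counts_trad <- c(1, 1, 4, 0, 8, 17, 0, 0, 0, 0, 0)

status_groups <- function() {
  list(resettled = ug_fixture("all_resettled"),
       traditional = ug_fixture("all_traditional"))
}
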