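#!/usr/bin/env Rscript
# Maximum-likelihood fits of the logit-equilibrium model: one (b, lambda)
# per group, and the three two-group specifications (free, shared-b,
# shared-lambda) for every area where both status groups are
# reconstructible. Bootstrap SEs are computed for the single-group fits.
# Set boot_reps <- 0 to skip the bootstrap.

library(qreug)

boot_reps <- as.integer(Sys.getenv("QREUG_BOOT_REPS", "1000"))
seed <- 20130528L

dir.create("results", showWarnings = FALSE)

single <- c("pooled_all", "all_resettled", "all_traditional",
            "mupfurudzi_all", "mutanda_all", "sengezi_all",
            "mutanda_resettled", "mutanda_traditional",
            "sengezi_resettled", "sengezi_traditional")

rows <- list()
for (g in single) {
  fit <- suppressWarnings(ug_fit(ug_fixture(g)))
  if (boot_reps > 0)
    fit <- suppressWarnings(ug_bootstrap(fit, n_reps = boot_reps,
                                         seed = seed))
  rows[[g]] <- data.frame(
    model = "single", group = g,
    n = nrow(fit$spec$groups[[1]]),
    b = fit$b[[1]], se_b = if (boot_reps > 0) fit$se[["b"]] else NA,
    lam = fit$lam[[1]],
    se_lam = if (boot_reps > 0) fit$se[["lam"]] else NA,
    neg_loglik = fit$neg_loglik,
    lam_at_bound = any(fit$bound_hits[grep("^lam", names(fit$bound_hits))]))
  cat(sprintf("%-20s b = %6.2f  lam = %6.2f  -lnL = %8.2f\n",
              g, fit$b[[1]], fit$lam[[1]], fit$neg_loglik))
}

areas <- list(
  all = c("all_resettled", "all_traditional"),
  mutanda = c("mutanda_resettled", "mutanda_traditional"),
  sengezi = c("sengezi_resettled", "sengezi_traditional"))

for (a in names(areas)) {
  groups <- list(resettled = ug_fixture(areas[[a]][1]),
                 traditional = ug_fixture(areas[[a]][2]))
  for (m in c("shared_b", "shared_lam")) {
    spec <- if (m == "shared_b")
      ug_model_spec(groups, b_sharing = "all")
    else
      ug_model_spec(groups, lam_sharing = "all")
    fit <- suppressWarnings(ug_fit_spec(spec))
    rows[[paste(a, m)]] <- data.frame(
      model = m, group = a, n = sum(vapply(groups, nrow, integer(1))),
      b = paste(signif(fit$b, 4), collapse = "/"), se_b = NA,
      lam = paste(signif(fit$lam, 4), collapse = "/"), se_lam = NA,
      neg_loglik = fit$neg_loglik,
      lam_at_bound = any(fit$bound_hits[grep("^lam", names(fit$bound_hits))]))
    cat(sprintf("%-8s %-11s b = %-12s lam = %-12s -lnL = %8.2f%s\n",
                a, m, rows[[paste(a, m)]]$b, rows[[paste(a, m)]]$lam,
                fit$neg_loglik,
                if (rows[[paste(a, m)]]$lam_at_bound) "  [lam at bound]" else ""))
  }
}

est <- do.call(rbind, rows)
write.csv(est, "results/estimates.csv", row.names = FALSE)
cat("Estimates -> results/estimates.csv\n")
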