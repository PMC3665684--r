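#' Simulate ultimatum-game play from the logit equilibrium
#'
#' Generates `n_pairs` independent proposer-responder plays at the given
#' preference parameters: for each pair an offer is drawn from the
#' equilibrium offer distribution and then an acceptance from the
#' responder's equilibrium acceptance probability at that offer. A single
#' uniform random stream is consumed pair by pair (offer draw, then
#' response draw), so both margins are reproducible under one seed.
#'
#' @param b,lam Preference parameters; `lam >= 0`.
#' @param n_pairs Number of pairs to simulate (>= 1).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param game A [ug_game()].
#' @param area,status Labels stamped on the output.
#' @return A `ug_data` table of `n_pairs` observations.
#' @examples
#' sim <- ug_simulate(b = 10, lam = 7, n_pairs = 50, seed = 1)
#' table(sim$offer)
#' @export
ug_simulate <- function(b, lam, n_pairs, seed, game = ug_game(),
                        area = "simulated", status = "simulated") {
  stopifnot(n_pairs >= 1, !missing(seed))
  eq <- ug_equilibrium(b, lam, game)
  cum <- cumsum(eq$offer_prob)
  set.seed(seed)
  u <- stats::runif(2L * n_pairs)
  u_offer <- u[seq(1L, 2L * n_pairs, by = 2L)]
  u_resp <- u[seq(2L, 2L * n_pairs, by = 2L)]
  idx <- findInterval(u_offer, cum) + 1L
  idx[idx > length(cum)] <- length(cum)
  accepted <- as.integer(u_resp < eq$accept_prob[idx])
  ug_observations(game$offer_grid[idx], accepted, area = area,
                  status = status,
                  pair_id = sprintf("sim_%05d", seq_len(n_pairs)),
                  game = game)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` datasets of `n_pairs` pairs at the true
#' parameters, refits each by [ug_fit()], and summarizes bias and RMSE per
#' parameter. Optionally, for the first `coverage_reps` replicates, runs a
#' bootstrap and reports the coverage of the +/- 2 SE intervals.
#'
#' @param b,lam True parameters of the generating equilibrium.
#' @param n_pairs Pairs per simulated dataset.
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Integer seed; per-replicate seeds are drawn from it.
#' @param game A [ug_game()].
#' @param coverage_reps Replicates on which to assess bootstrap interval
#'   coverage (0 to skip).
#' @param boot_reps Bootstrap replicates for the coverage assessment.
#' @param ... Passed to [ug_fit()].
#' @return A list of class `ug_recovery`: `replicates` (per-replicate
#'   estimates), `summary` (truth, mean estimate, bias, RMSE per
#'   parameter), and `coverage` (or `NULL`).
#' @examples
#' rec <- ug_recovery(b = 10, lam = 7, n_pairs = 200, n_replicates = 3,
#'                    seed = 1)
#' rec$summary
#' @export
ug_recovery <- function(b, lam, n_pairs, n_replicates, seed,
                        game = ug_game(), coverage_reps = 0,
                        boot_reps = 200, ...) {
  stopifnot(n_replicates >= 2)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  boot_seeds <- sample.int(.Machine$integer.max, n_replicates)

  est <- matrix(NA_real_, n_replicates, 2,
                dimnames = list(NULL, c("b", "lam")))
  covered <- matrix(NA, n_replicates, 2,
                    dimnames = list(NULL, c("b", "lam")))
  for (r in seq_len(n_replicates)) {
    sim <- ug_simulate(b, lam, n_pairs, seed = rep_seeds[r], game = game)
    fit <- tryCatch(suppressWarnings(ug_fit(sim, game = game, ...)),
                    error = function(e)
                      stop("fit failed in replicate ", r, ": ",
                           conditionMessage(e)))
    est[r, ] <- fit$estimates
    if (r <= coverage_reps) {
      bf <- ug_bootstrap(fit, n_reps = boot_reps, seed = boot_seeds[r])
      lo <- bf$estimates - 2 * bf$se
      hi <- bf$estimates + 2 * bf$se
      covered[r, ] <- c(b, lam) >= lo & c(b, lam) <= hi
    }
  }
  truth <- c(b = b, lam = lam)
  summ <- data.frame(parameter = c("b", "lam"), truth = as.numeric(truth),
                     mean_estimate = colMeans(est),
                     bias = colMeans(est) - truth,
                     rmse = sqrt(colMeans((est - rep(truth, each = n_replicates))^2)),
                     row.names = NULL)
  cov <- if (coverage_reps > 0)
    colMeans(covered[seq_len(min(coverage_reps, n_replicates)), ,
                     drop = FALSE]) else NULL
  structure(list(replicates = as.data.frame(est), summary = summ,
                 coverage = cov, n_pairs = n_pairs, seed = seed),
            class = "ug_recovery")
}

#' @export
print.ug_recovery <- function(x, ...) {
  cat("Parameter recovery over", nrow(x$replicates), "replicates of",
      x$n_pairs, "pairs\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$coverage)) {
    cat("+/- 2 SE coverage:\n"); print(x$coverage)
  }
  invisible(x)
}
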