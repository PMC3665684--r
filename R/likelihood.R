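# Collapse observations to per-offer sufficient statistics:
# grid index, count, number of rejections. The likelihood depends on the
# data only through these.
ug_bin_data <- function(data, game = ug_game()) {
  stopifnot(inherits(data, "ug_data"))
  if (nrow(data) == 0)
    return(data.frame(idx = integer(0), n = integer(0), k = integer(0)))
  idx <- match_grid(data$offer, game)
  agg <- stats::aggregate(cbind(n = rep(1L, length(idx)),
                                k = as.integer(data$accepted == 0L)),
                          by = list(idx = idx), FUN = sum)
  agg
}

# Negative log-likelihood from binned sufficient statistics. Probability
# floor 1e-300 keeps the objective finite during optimizer excursions
# where a rejected offer has predicted acceptance ~1 (or vice versa).
nll_binned <- function(bins, b, lam, game) {
  pa_full <- stats::plogis(lam * ug_utility(game$offer_grid, b,
                                            surplus = game$surplus))
  eu <- pa_full * ug_utility(1 - game$offer_grid, b, surplus = game$surplus)
  pp_full <- softmax_lam(lam, eu)
  pp <- pmax(pp_full[bins$idx], 1e-300)
  pa <- pmax(pa_full[bins$idx], 1e-300)
  pr <- pmax(1 - pa_full[bins$idx], 1e-300)
  -sum(bins$n * log(pp) + (bins$n - bins$k) * log(pa) + bins$k * log(pr))
}

#' Log-likelihood of ultimatum-game data under the logit equilibrium
#'
#' For observations \eqn{(s_k, d_k)} (offer, acceptance dummy) the
#' log-likelihood at \eqn{(b, \lambda)} is
#' \deqn{\sum_k \ln p_P(s_k) + d_k \ln p_R(s_k) + (1-d_k)\ln(1-p_R(s_k)),}
#' where \eqn{p_P} and \eqn{p_R} are the equilibrium offer and acceptance
#' probabilities from [ug_equilibrium()]. Probabilities are floored at
#' 1e-300 inside the logarithms, so the value is finite over the whole
#' estimation region.
#'
#' @param data A `ug_data` table (may be empty, giving 0).
#' @param b,lam Preference parameters; `lam >= 0`.
#' @param game A [ug_game()].
#' @return The log-likelihood (a scalar; 0 for an empty dataset).
#' @examples
#' ug_loglik(ug_fixture("all_resettled"), b = 13.97, lam = 6.83)
#' @export
ug_loglik <- function(data, b, lam, game = ug_game()) {
  stopifnot(lam >= 0)
  bins <- ug_bin_data(data, game)
  if (nrow(bins) == 0) return(0)
  -nll_binned(bins, b, lam, game)
}
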