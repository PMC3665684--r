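#' Discrete ultimatum game configuration
#'
#' Defines the game over which equilibria are computed: the money at stake,
#' the proposer's offer grid as fractions of the stakes, and the surplus
#' value used inside utilities (the stakes normalized to 1 by default, so
#' that all utilities and the rationality coefficient lambda are measured
#' on the normalized scale).
#'
#' The default is the field-experiment game: stakes of 50 currency units
#' divisible in steps of 5, i.e. eleven offers 0, 0.1, ..., 1.
#'
#' @param stakes Money at stake, in currency units. Must be positive.
#'   Presentation only; utilities use `surplus`.
#' @param offer_grid Strictly increasing vector of offer fractions in
#'   \[0, 1\].
#' @param surplus Surplus value used inside utilities; defaults to 1
#'   (normalized stakes).
#' @return An object of class `ug_game`.
#' @examples
#' g <- ug_game()
#' g$offer_grid
#' @export
ug_game <- function(stakes = 50, offer_grid = seq(0, 1, by = 0.1),
                    surplus = 1) {
  stopifnot(is.numeric(stakes), length(stakes) == 1L, stakes > 0,
            is.numeric(surplus), length(surplus) == 1L, surplus > 0,
            is.numeric(offer_grid), length(offer_grid) >= 2L)
  if (any(offer_grid < 0 | offer_grid > 1))
    stop("offer_grid values must lie in [0, 1]")
  if (any(diff(offer_grid) <= 0))
    stop("offer_grid must be strictly increasing")
  structure(list(stakes = stakes, offer_grid = as.numeric(offer_grid),
                 surplus = surplus),
            class = "ug_game")
}

#' @export
print.ug_game <- function(x, ...) {
  cat("Ultimatum game: stakes", x$stakes, "| surplus (normalized)",
      x$surplus, "|", length(x$offer_grid), "offers:",
      paste(x$offer_grid, collapse = " "), "\n")
  invisible(x)
}

# Match offers to grid positions; tolerance absorbs decimal representation
# noise only, not off-grid offers.
match_grid <- function(offer, game, what = "offer") {
  idx <- vapply(offer, function(s) {
    d <- abs(game$offer_grid - s)
    i <- which.min(d)
    if (d[i] > 1e-8) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx)) {
    bad <- unique(offer[is.na(idx)])
    stop(sprintf("%s value(s) not on the offer grid: %s", what,
                 paste(bad, collapse = ", ")))
  }
  idx
}

#' Inequality-averse utility
#'
#' Utility of receiving a share of the surplus under the symmetric
#' quadratic inequality-aversion (ERC-type) motivation function
#' \deqn{u(\sigma) = c\,\sigma - \frac{b}{2}(\sigma - 1/2)^2,}
#' where \eqn{\sigma} is the player's payoff share, \eqn{c} the surplus
#' (1 on the normalized scale) and \eqn{b} the fairness coefficient. A
#' rejected play yields zero surplus; the share of a zero surplus is
#' defined as 1/2, so the loss term vanishes and the utility is exactly 0.
#'
#' @param share Payoff share(s) in \[0, 1\].
#' @param b Fairness (inequality-aversion) coefficient.
#' @param accepted Logical (recycled): was the proposal accepted?
#' @param surplus Surplus value; defaults to 1.
#' @return Numeric vector of utilities.
#' @examples
#' ug_utility(0.5, b = 13.97)          # equal split: no inequality loss
#' ug_utility(0.3, b = 13.97)          # 0.3 - 6.985 * 0.04
#' ug_utility(0.3, b = 13.97, accepted = FALSE)
#' @export
ug_utility <- function(share, b, accepted = TRUE, surplus = 1) {
  if (any(share < 0 | share > 1, na.rm = TRUE))
    stop("share must lie in [0, 1]")
  u <- surplus * share - (b / 2) * (share - 0.5)^2
  u[rep_len(!accepted, length(u))] <- 0
  u
}

#' Responder acceptance probability
#'
#' Logit quantal response of the responder between accepting an offer
#' (utility `ug_utility(s, b)`) and rejecting it (utility 0):
#' \eqn{p = 1 / (1 + e^{-\lambda u_{acc}})}. With `lam = 0` every offer is
#' accepted with probability exactly 1/2; as `lam` grows the response
#' approaches the best reply.
#'
#' @param offer Offer fraction(s); must lie on the game's grid.
#' @param b Fairness coefficient.
#' @param lam Rationality (logit precision) coefficient, `lam >= 0`.
#' @param game A [ug_game()].
#' @return Acceptance probabilities, one per offer.
#' @examples
#' 1 - ug_accept_prob(0.2, b = 13.97, lam = 6.83)  # rejection prob ~0.95
#' @export
ug_accept_prob <- function(offer, b, lam, game = ug_game()) {
  stopifnot(lam >= 0)
  idx <- match_grid(offer, game)
  s <- game$offer_grid[idx]
  stats::plogis(lam * ug_utility(s, b, surplus = game$surplus))
}

# Numerically stable softmax with precision lam (log-sum-exp with
# max-subtraction); finite for lam up to the estimation bound of 100.
softmax_lam <- function(lam, values) {
  z <- lam * values
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Proposer offer distribution
#'
#' The proposer's logit quantal response over the offer grid. The expected
#' utility of offering `s` is the acceptance probability times the utility
#' of keeping `1 - s`; rejection yields 0. Offer probabilities are a
#' softmax with precision `lam` over these expected utilities, computed
#' with max-subtraction so the result is finite for `lam` up to 100.
#'
#' @inheritParams ug_accept_prob
#' @param accept_probs Optional acceptance probabilities aligned with the
#'   grid; computed from `(b, lam)` when missing.
#' @return Probability vector over the grid (sums to 1).
#' @examples
#' ug_offer_distribution(b = 13.97, lam = 6.83)
#' @export
ug_offer_distribution <- function(b, lam, game = ug_game(),
                                  accept_probs = NULL) {
  stopifnot(lam >= 0)
  if (is.null(accept_probs))
    accept_probs <- ug_accept_prob(game$offer_grid, b, lam, game)
  stopifnot(length(accept_probs) == length(game$offer_grid))
  eu <- accept_probs *
    ug_utility(1 - game$offer_grid, b, surplus = game$surplus)
  softmax_lam(lam, eu)
}

#' Agent quantal response equilibrium of the ultimatum game
#'
#' Solves the agent QRE (logit equilibrium) of the sequential ultimatum
#' game at fairness `b` and rationality `lam`. Because the responder moves
#' after observing the offer, the responder's quantal response does not
#' depend on the proposer's mixed strategy, so the equilibrium is obtained
#' in one backward pass: acceptance probabilities per offer, then the
#' proposer's softmax over expected utilities. The result is a fixed point
#' of the two logit response maps; see [ug_fixed_point_error()].
#'
#' @inheritParams ug_accept_prob
#' @param b Fairness coefficient.
#' @param lam Rationality coefficient, `lam >= 0` (0 gives uniform offers
#'   and 1/2 acceptance everywhere).
#' @return An object of class `ug_equilibrium`: a data frame with columns
#'   `offer`, `offer_prob`, `accept_prob`, `expected_proposer_util`, with
#'   the parameters and game attached as attributes.
#' @examples
#' eq <- ug_equilibrium(b = 13.97, lam = 6.83)
#' round(eq$offer_prob, 2)
#' @export
ug_equilibrium <- function(b, lam, game = ug_game()) {
  stopifnot(is.numeric(b), length(b) == 1L,
            is.numeric(lam), length(lam) == 1L, lam >= 0)
  pa <- ug_accept_prob(game$offer_grid, b, lam, game)
  eu <- pa * ug_utility(1 - game$offer_grid, b, surplus = game$surplus)
  pp <- softmax_lam(lam, eu)
  out <- data.frame(offer = game$offer_grid, offer_prob = pp,
                    accept_prob = pa, expected_proposer_util = eu)
  structure(out, class = c("ug_equilibrium", "data.frame"),
            b = b, lam = lam, game = game)
}

#' Fixed-point residual of a solved equilibrium
#'
#' Re-applies both logit response maps (responder acceptance, proposer
#' softmax) to a solved equilibrium and returns the largest absolute change
#' in any probability. For a correct solution this is numerically zero.
#'
#' @param eq An object from [ug_equilibrium()].
#' @return Maximum absolute probability change (a scalar).
#' @export
ug_fixed_point_error <- function(eq) {
  stopifnot(inherits(eq, "ug_equilibrium"))
  game <- attr(eq, "game")
  b <- attr(eq, "b")
  lam <- attr(eq, "lam")
  pa2 <- ug_accept_prob(game$offer_grid, b, lam, game)
  pp2 <- ug_offer_distribution(b, lam, game, accept_probs = eq$accept_prob)
  max(abs(pa2 - eq$accept_prob), abs(pp2 - eq$offer_prob))
}

#' @export
print.ug_equilibrium <- function(x, digits = 4, ...) {
  cat(sprintf("Agent QRE at b = %.4g, lam = %.4g\n",
              attr(x, "b"), attr(x, "lam")))
  print.data.frame(round(as.data.frame(x), digits), row.names = FALSE)
  invisible(x)
}

#' Count-weighted Pearson correlation of observed and predicted behavior
#'
#' Weighted Pearson correlation between observed frequencies (or rates)
#' and model predictions, restricted to grid points with positive weight
#' (offers actually observed). Used to compare observed and predicted
#' offer distributions and rejection rates.
#'
#' @param observed,predicted Aligned numeric vectors.
#' @param weights Nonnegative weights (per-offer observation counts) with
#'   a positive total.
#' @return The correlation coefficient; `NA` with attribute
#'   `undefined = TRUE` when fewer than 2 support points (or zero variance)
#'   make the correlation undefined.
#' @examples
#' ug_weighted_cor(c(0.2, 0.8), c(0.1, 0.9), c(5, 5))
#' @export
ug_weighted_cor <- function(observed, predicted, weights) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(weights))
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be nonnegative")
  keep <- !is.na(weights) & weights > 0 & !is.na(observed) & !is.na(predicted)
  if (sum(weights[keep]) <= 0) stop("total weight must be positive")
  x <- observed[keep]; y <- predicted[keep]
  w <- weights[keep] / sum(weights[keep])
  if (length(x) < 2L)
    return(structure(NA_real_, undefined = TRUE))
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0)
    return(structure(NA_real_, undefined = TRUE))
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Equilibrium prediction table for presentation
#'
#' Convenience wrapper around [ug_equilibrium()] returning the offer
#' distribution and rejection rates both at full precision and rounded to
#' two decimals, the layout in which such predictions are usually
#' tabulated against observed play.
#'
#' @inheritParams ug_equilibrium
#' @return A data frame with columns `offer`, `offer_prob`, `reject_prob`,
#'   `offer_prob_2dp`, `reject_prob_2dp`.
#' @export
ug_predict_table <- function(b, lam, game = ug_game()) {
  eq <- ug_equilibrium(b, lam, game)
  data.frame(offer = eq$offer,
             offer_prob = eq$offer_prob,
             reject_prob = 1 - eq$accept_prob,
             offer_prob_2dp = round(eq$offer_prob, 2),
             reject_prob_2dp = round(1 - eq$accept_prob, 2))
}
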