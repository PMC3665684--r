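#' Construct an ultimatum-game observation table
#'
#' One row per proposer-responder pair: the offer made (as a fraction of
#' the stakes, on the game's grid) and whether the responder accepted.
#'
#' @param offer Offer fractions, each on the grid of `game`.
#' @param accepted Acceptance indicators (0/1 or logical).
#' @param area,status Group labels (recycled).
#' @param pair_id Optional identifiers; generated when missing.
#' @param game A [ug_game()] used to validate offers.
#' @return A data frame of class `ug_data` with columns
#'   `pair_id`, `area`, `status`, `offer`, `accepted`.
#' @examples
#' ug_observations(c(0.5, 0.2), c(1, 0), area = "all", status = "resettled")
#' @export
ug_observations <- function(offer, accepted, area = "all", status = "all",
                            pair_id = NULL, game = ug_game()) {
  n <- length(offer)
  stopifnot(length(accepted) == n)
  accepted <- as.integer(accepted)
  if (n > 0 && !all(accepted %in% c(0L, 1L)))
    stop("accepted must be 0/1")
  if (n > 0) {
    idx <- match_grid(offer, game)
    offer <- game$offer_grid[idx]
  }
  if (is.null(pair_id)) pair_id <- if (n > 0) sprintf("pair_%04d", seq_len(n)) else character(0)
  out <- data.frame(pair_id = as.character(pair_id),
                    area = rep_len(as.character(area), n),
                    status = rep_len(as.character(status), n),
                    offer = as.numeric(offer),
                    accepted = accepted,
                    stringsAsFactors = FALSE)
  class(out) <- c("ug_data", "data.frame")
  out
}

# round-half-up, the convention under which every printed rate x count
# resolves uniquely at these sample sizes
round_half_up <- function(x) floor(x + 0.5)

#' Expand a binned count table into individual observations
#'
#' The field data are published only as per-offer counts and rejection
#' rates. This reconstructs the individual plays: for each offer row with
#' `n` observations and rejection rate `r`, it emits `round(r * n)`
#' rejections (half-up) and `n - round(r * n)` acceptances. If `r * n` is
#' farther than 0.25 from an integer the reconstruction is ambiguous and
#' the function stops rather than guess.
#'
#' @param binned Data frame with columns `offer`, `n`, `rejection_rate`
#'   and optionally `area`, `status`.
#' @param game A [ug_game()].
#' @param expected_n If given, the reconstructed total must equal it.
#' @param expected_rejection_rate If given, the reconstructed overall
#'   rejection rate must round (2 dp) to it.
#' @return A `ug_data` table (see [ug_observations()]).
#' @examples
#' ug_expand_binned(data.frame(offer = 0.2, n = 5, rejection_rate = 0.6))
#' @export
ug_expand_binned <- function(binned, game = ug_game(), expected_n = NULL,
                             expected_rejection_rate = NULL) {
  stopifnot(is.data.frame(binned),
            all(c("offer", "n", "rejection_rate") %in% names(binned)))
  if (any(binned$n < 0) || any(binned$n != round_half_up(binned$n)))
    stop("counts n must be nonnegative integers")
  area <- if ("area" %in% names(binned)) binned$area else "all"
  status <- if ("status" %in% names(binned)) binned$status else "all"
  area <- rep_len(area, nrow(binned))
  status <- rep_len(status, nrow(binned))

  offers <- numeric(0); acc <- integer(0); ar <- character(0); st <- character(0)
  for (i in seq_len(nrow(binned))) {
    n_i <- binned$n[i]
    if (n_i == 0) next
    x <- binned$rejection_rate[i] * n_i
    k <- round_half_up(x)
    if (abs(x - k) > 0.25)
      stop(sprintf(
        "ambiguous reconstruction at offer %s: rate * n = %.3f is not within 0.25 of an integer",
        binned$offer[i], x))
    offers <- c(offers, rep(binned$offer[i], n_i))
    acc <- c(acc, rep(c(0L, 1L), c(k, n_i - k)))
    ar <- c(ar, rep(as.character(area[i]), n_i))
    st <- c(st, rep(as.character(status[i]), n_i))
  }
  out <- ug_observations(offers, acc, area = ar, status = st, game = game)
  if (!is.null(expected_n) && nrow(out) != expected_n)
    stop(sprintf("reconstructed %d pairs but expected %d", nrow(out), expected_n))
  if (!is.null(expected_rejection_rate)) {
    got <- round(mean(out$accepted == 0L), 2)
    if (abs(got - expected_rejection_rate) > 1e-9)
      stop(sprintf("reconstructed rejection rate %.2f does not match expected %.2f",
                   got, expected_rejection_rate))
  }
  out
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "qreug")
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

# derived fixtures are concatenations of shipped base groups
derived_fixtures <- list(
  pooled_all   = c("all_resettled", "all_traditional"),
  mutanda_all  = c("mutanda_resettled", "mutanda_traditional"),
  sengezi_all  = c("sengezi_resettled", "sengezi_traditional")
)

#' Names of the embedded field-experiment fixtures
#'
#' The per-offer counts and rejection rates of the Zimbabwe resettlement
#' ultimatum-game experiment, as published, reconstructible per group.
#' Derived groups (`pooled_all`, `mutanda_all`, `sengezi_all`) are
#' concatenations of the base groups. The 64-pair Mupfurudzi area is only
#' published merged across resettlement status.
#'
#' @return Character vector of group names accepted by [ug_fixture()].
#' @export
ug_fixture_names <- function() {
  base <- unique(utils::read.csv(fixture_path("ug_binned_counts.csv"))$group)
  c(base, names(derived_fixtures))
}

#' Load a reconstructed field-experiment dataset
#'
#' Expands the embedded per-offer counts and rejection rates of the named
#' group into individual observations and validates the reconstruction
#' against the published group totals (number of pairs, overall rejection
#' rate at 2 dp), failing loudly on any mismatch.
#'
#' @param group One of [ug_fixture_names()].
#' @param game A [ug_game()].
#' @return A `ug_data` table.
#' @examples
#' res <- ug_fixture("all_resettled")
#' nrow(res); sum(res$accepted == 0)
#' @export
ug_fixture <- function(group, game = ug_game()) {
  avail <- ug_fixture_names()
  if (!group %in% avail)
    stop("unknown fixture group '", group, "'; available: ",
         paste(avail, collapse = ", "))
  totals <- utils::read.csv(fixture_path("ug_group_totals.csv"))
  tot <- totals[totals$group == group, ]
  if (group %in% names(derived_fixtures)) {
    parts <- lapply(derived_fixtures[[group]], ug_fixture, game = game)
    out <- do.call(rbind, parts)
    out$pair_id <- sprintf("pair_%04d", seq_len(nrow(out)))
    class(out) <- c("ug_data", "data.frame")
    if (nrow(out) != tot$n_pairs)
      stop("derived fixture size mismatch for ", group)
    if (abs(round(mean(out$accepted == 0L), 2) - tot$rejection_rate) > 1e-9)
      stop("derived fixture rejection rate mismatch for ", group)
    return(out)
  }
  bins <- utils::read.csv(fixture_path("ug_binned_counts.csv"))
  bins <- bins[bins$group == group, ]
  ug_expand_binned(bins, game = game, expected_n = tot$n_pairs,
                   expected_rejection_rate = tot$rejection_rate)
}

#' Embedded binned count tables
#'
#' Returns the per-offer counts and published rejection rates for one
#' fixture group (or all groups), in the binned layout.
#'
#' @param group Optional group name; all groups when `NULL`.
#' @return Data frame with columns `group`, `area`, `status`, `offer`,
#'   `n`, `rejection_rate`.
#' @export
ug_binned_counts <- function(group = NULL) {
  bins <- utils::read.csv(fixture_path("ug_binned_counts.csv"))
  if (!is.null(group)) {
    if (!group %in% bins$group)
      stop("unknown group '", group, "'")
    bins <- bins[bins$group == group, ]
  }
  bins
}

#' Read ultimatum-game observations from CSV
#'
#' Expects a header `pair_id,area,status,offer,accepted`. Offers are
#' validated against the game's grid and malformed rows are reported with
#' their line numbers.
#'
#' @param path File path.
#' @param game A [ug_game()].
#' @return A `ug_data` table.
#' @export
ug_read_observations <- function(path, game = ug_game()) {
  df <- utils::read.csv(path, colClasses = c(pair_id = "character"))
  need <- c("pair_id", "area", "status", "offer", "accepted")
  if (!all(need %in% names(df)))
    stop("expected header: ", paste(need, collapse = ","))
  if (nrow(df) == 0)
    return(ug_observations(numeric(0), integer(0), game = game))
  bad <- which(is.na(df$offer) | is.na(df$accepted) |
                 !(df$accepted %in% c(0, 1)) |
                 vapply(df$offer,
                        function(s) min(abs(game$offer_grid - s)) > 1e-8,
                        logical(1)))
  if (length(bad) > 0)
    stop("malformed rows (offer off grid or bad acceptance) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  ug_observations(df$offer, df$accepted, area = df$area, status = df$status,
                  pair_id = df$pair_id, game = game)
}

#' Write ultimatum-game observations to CSV
#'
#' @param data A `ug_data` table.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
ug_write_observations <- function(data, path) {
  stopifnot(inherits(data, "ug_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Descriptive summary of ultimatum-game play
#'
#' Mean and sample standard deviation of offers, overall rejection rate,
#' rejection rates conditional on offers below one half and below 0.3
#' (with the number of such offers), and the modal offer (ties broken
#' toward the lowest offer).
#'
#' @param data A non-empty `ug_data` table.
#' @return One-row data frame of class `ug_descriptives`.
#' @examples
#' ug_descriptives(ug_fixture("all_resettled"))
#' @export
ug_descriptives <- function(data) {
  stopifnot(inherits(data, "ug_data"))
  if (nrow(data) == 0) stop("empty dataset")
  rej <- data$accepted == 0L
  lo5 <- data$offer < 0.5
  lo3 <- data$offer < 0.3
  tab <- table(data$offer)
  modal <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = lowest
  out <- data.frame(
    n_pairs = nrow(data),
    mean_offer = mean(data$offer),
    sd_offer = if (nrow(data) > 1) stats::sd(data$offer) else 0,
    rejection_rate = mean(rej),
    n_below_half = sum(lo5),
    rejection_rate_below_half = if (any(lo5)) mean(rej[lo5]) else NA_real_,
    n_below_03 = sum(lo3),
    rejection_rate_below_03 = if (any(lo3)) mean(rej[lo3]) else NA_real_,
    modal_offer = modal)
  class(out) <- c("ug_descriptives", "data.frame")
  out
}
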