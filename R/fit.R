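#' Specify a (possibly restricted) multi-group model
#'
#' Groups are named datasets (e.g. resettled and traditional villagers).
#' `b_sharing` and `lam_sharing` partition the group names into blocks
#' that share one fairness coefficient b, respectively one rationality
#' coefficient lambda. The default gives every group its own pair of
#' parameters (the unrestricted model). `b_fixed_zero` imposes the pure
#' self-interest restriction b = 0 for all groups.
#'
#' @param groups Named list of `ug_data` tables.
#' @param b_sharing,lam_sharing Partitions of `names(groups)` given as
#'   lists of character vectors; each name must appear exactly once.
#'   `NULL` means one block per group; `"all"` shares one parameter
#'   across every group.
#' @param b_fixed_zero If `TRUE`, b is fixed at 0 (no free b blocks).
#' @return An object of class `ug_model_spec`.
#' @examples
#' groups <- list(resettled = ug_fixture("all_resettled"),
#'                traditional = ug_fixture("all_traditional"))
#' ug_model_spec(groups, b_sharing = NULL, lam_sharing = "all")
#' @export
ug_model_spec <- function(groups, b_sharing = NULL, lam_sharing = NULL,
                          b_fixed_zero = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  for (g in groups) stopifnot(inherits(g, "ug_data"))
  gn <- names(groups)
  norm_part <- function(part) {
    if (is.null(part)) part <- as.list(gn)
    if (identical(part, "all")) part <- list(gn)
    stopifnot(is.list(part))
    flat <- unlist(part)
    if (!setequal(flat, gn) || anyDuplicated(flat) > 0)
      stop("sharing partition must cover each group name exactly once")
    part
  }
  b_sharing <- norm_part(b_sharing)
  lam_sharing <- norm_part(lam_sharing)
  n_free <- (if (b_fixed_zero) 0L else length(b_sharing)) +
    length(lam_sharing)
  structure(list(groups = groups, b_sharing = b_sharing,
                 lam_sharing = lam_sharing, b_fixed_zero = b_fixed_zero,
                 n_free = n_free),
            class = "ug_model_spec")
}

block_labels <- function(prefix, part) {
  if (length(part) == 1L) prefix
  else paste0(prefix, "_", vapply(part, paste, "", collapse = "+"))
}

# Map each group to its b-block and lam-block index.
block_index <- function(part, gn) {
  vapply(gn, function(g) which(vapply(part, function(bl) g %in% bl,
                                      logical(1))), integer(1))
}

#' Fit a multi-group model by maximum likelihood
#'
#' Maximizes the joint log-likelihood (sum over groups) over the free
#' parameters of a [ug_model_spec()], subject to the sharing constraints,
#' with bounds b in \[0, 500\] and lambda in (0, 100\] and a multistart
#' bounded quasi-Newton search (`L-BFGS-B`). Estimates within 1e-3 of a
#' bound are flagged. A group whose plays are a single offer, all
#' accepted, leaves (b, lambda) unidentified along a ridge; such groups
#' are flagged and a warning is issued rather than failing silently.
#'
#' @param spec A [ug_model_spec()].
#' @param game A [ug_game()].
#' @param b_bounds,lam_bounds Parameter bounds.
#' @param b_starts,lam_starts Multistart values per free parameter (their
#'   Cartesian product seeds the local searches).
#' @param factr `optim` L-BFGS-B convergence tolerance factor.
#' @return An object of class `ug_fit` with named `estimates`, per-group
#'   `b` and `lam`, total `neg_loglik` and per-group `components`,
#'   convergence and bound-hit flags, and the spec itself.
#' @examples
#' fit <- ug_fit_spec(ug_model_spec(list(res = ug_fixture("all_resettled"))))
#' coef(fit)
#' @export
ug_fit_spec <- function(spec, game = ug_game(),
                        b_bounds = c(0, 500), lam_bounds = c(1e-6, 100),
                        b_starts = c(1, 5, 10, 25, 50),
                        lam_starts = c(2, 5, 10, 50),
                        factr = 1e4) {
  stopifnot(inherits(spec, "ug_model_spec"))
  gn <- names(spec$groups)
  for (g in gn) if (nrow(spec$groups[[g]]) == 0)
    stop("empty dataset in group '", g, "'")
  bins <- lapply(spec$groups, ug_bin_data, game = game)

  flat <- vapply(gn, function(g) {
    b <- bins[[g]]
    nrow(b) == 1L && b$k == 0L
  }, logical(1))
  if (any(flat))
    warning("non-identifiable group(s) (single offer, all accepted): ",
            paste(gn[flat], collapse = ", "))

  b_idx <- block_index(spec$b_sharing, gn)
  l_idx <- block_index(spec$lam_sharing, gn)
  nb <- if (spec$b_fixed_zero) 0L else length(spec$b_sharing)
  nl <- length(spec$lam_sharing)

  nll_joint <- function(theta) {
    bs <- if (nb > 0) theta[seq_len(nb)] else numeric(0)
    ls <- theta[nb + seq_len(nl)]
    tot <- 0
    for (i in seq_along(gn)) {
      b_g <- if (spec$b_fixed_zero) 0 else bs[b_idx[i]]
      tot <- tot + nll_binned(bins[[i]], b_g, ls[l_idx[i]], game)
    }
    tot
  }

  start_grid <- do.call(expand.grid, c(rep(list(b_starts), nb),
                                       rep(list(lam_starts), nl)))
  lower <- c(rep(b_bounds[1], nb), rep(lam_bounds[1], nl))
  upper <- c(rep(b_bounds[2], nb), rep(lam_bounds[2], nl))

  best <- NULL
  n_conv <- 0L
  msgs <- character(0)
  for (j in seq_len(nrow(start_grid))) {
    o <- tryCatch(
      stats::optim(as.numeric(start_grid[j, ]), nll_joint,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = factr, maxit = 500)),
      error = function(e) e)
    if (inherits(o, "error")) { msgs <- c(msgs, conditionMessage(o)); next }
    if (o$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all optimizer starts failed: ",
         paste(unique(msgs), collapse = "; "))

  theta <- best$par
  bs <- if (nb > 0) theta[seq_len(nb)] else numeric(0)
  ls <- theta[nb + seq_len(nl)]
  est <- c(bs, ls)
  names(est) <- c(if (nb > 0) block_labels("b", spec$b_sharing),
                  block_labels("lam", spec$lam_sharing))
  b_by_group <- stats::setNames(
    if (spec$b_fixed_zero) rep(0, length(gn)) else bs[b_idx], gn)
  lam_by_group <- stats::setNames(ls[l_idx], gn)
  components <- stats::setNames(vapply(seq_along(gn), function(i)
    nll_binned(bins[[i]], b_by_group[i], lam_by_group[i], game),
    numeric(1)), gn)

  tol <- 1e-3
  bound_hits <- c(
    if (nb > 0) abs(bs - b_bounds[1]) < tol | abs(bs - b_bounds[2]) < tol,
    abs(ls - lam_bounds[1]) < tol | abs(ls - lam_bounds[2]) < tol)
  names(bound_hits) <- names(est)

  structure(list(estimates = est,
                 b = b_by_group, lam = lam_by_group,
                 neg_loglik = best$value, components = components,
                 convergence = best$convergence,
                 n_starts = nrow(start_grid), n_converged = n_conv,
                 bound_hits = bound_hits,
                 non_identifiable = stats::setNames(flat, gn),
                 n_free = spec$n_free, spec = spec, game = game,
                 b_bounds = b_bounds, lam_bounds = lam_bounds,
                 factr = factr),
            class = "ug_fit")
}

#' Fit one group by maximum likelihood
#'
#' Convenience wrapper around [ug_fit_spec()] for a single dataset:
#' estimates one fairness coefficient b and one rationality coefficient
#' lambda.
#'
#' @param data A non-empty `ug_data` table.
#' @param ... Passed to [ug_fit_spec()] (bounds, starts, `game`, ...).
#' @return A `ug_fit` object; `coef()` gives `c(b = ..., lam = ...)`.
#' @examples
#' fit <- ug_fit(ug_fixture("sengezi_resettled"))
#' coef(fit); fit$neg_loglik
#' @export
ug_fit <- function(data, ...) {
  ug_fit_spec(ug_model_spec(list(group = data)), ...)
}

#' @export
coef.ug_fit <- function(object, ...) object$estimates

#' @export
logLik.ug_fit <- function(object, ...) {
  structure(-object$neg_loglik, df = object$n_free, class = "logLik")
}

#' @export
print.ug_fit <- function(x, digits = 4, ...) {
  cat("Logit-equilibrium ML fit (", x$n_free, " free parameter(s), ",
      length(x$spec$groups), " group(s))\n", sep = "")
  print(round(x$estimates, digits))
  cat("-lnL:", format(x$neg_loglik, digits = 8), "\n")
  if (any(x$bound_hits))
    cat("at bound:", paste(names(x$bound_hits)[x$bound_hits],
                           collapse = ", "), "\n")
  if (!is.null(x$se)) {
    cat("bootstrap SE:\n"); print(round(x$se, digits))
  }
  invisible(x)
}

#' Likelihood-ratio test of nested model specifications
#'
#' Compares two fits of the same grouped data: the statistic is twice the
#' log-likelihood difference, referred to a chi-squared distribution with
#' degrees of freedom equal to the difference in free-parameter counts.
#'
#' @param null_fit,alt_fit `ug_fit` objects; the null must be nested in
#'   the alternative (same groups, fewer free parameters).
#' @return An object of class `ug_lr_test` with `lr`, `df`, `p_value`.
#' @examples
#' groups <- list(r = ug_fixture("all_resettled"),
#'                t = ug_fixture("all_traditional"))
#' f0 <- ug_fit_spec(ug_model_spec(groups, "all", "all"))
#' f1 <- ug_fit_spec(ug_model_spec(groups))
#' ug_lr_test(f0, f1)
#' @export
ug_lr_test <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "ug_fit"), inherits(alt_fit, "ug_fit"))
  gn0 <- names(null_fit$spec$groups); gn1 <- names(alt_fit$spec$groups)
  n0 <- sum(vapply(null_fit$spec$groups, nrow, integer(1)))
  n1 <- sum(vapply(alt_fit$spec$groups, nrow, integer(1)))
  if (!setequal(gn0, gn1) || n0 != n1)
    stop("fits are not on the same grouped data")
  df <- alt_fit$n_free - null_fit$n_free
  if (df < 1) stop("null model is not nested in the alternative (df < 1)")
  lr <- 2 * (null_fit$neg_loglik - alt_fit$neg_loglik)
  if (lr < -1e-6)
    stop("negative LR statistic (", format(lr),
         "): optimizer failure in one of the fits")
  lr <- max(lr, 0)
  structure(list(lr = lr, df = df,
                 p_value = stats::pchisq(lr, df, lower.tail = FALSE),
                 null_neg_loglik = null_fit$neg_loglik,
                 alt_neg_loglik = alt_fit$neg_loglik,
                 null_n_free = null_fit$n_free,
                 alt_n_free = alt_fit$n_free),
            class = "ug_lr_test")
}

#' @export
print.ug_lr_test <- function(x, ...) {
  cat(sprintf("LR = %.4f, df = %d, p = %.4f\n", x$lr, x$df, x$p_value))
  invisible(x)
}

#' Bootstrap standard errors for a fitted model
#'
#' Resamples proposer-responder pairs with replacement within each group
#' (pairs are the independent observations of the likelihood), refits the
#' model specification on every resample, and reports the standard
#' deviation of the bootstrap estimates as the standard error, with
#' p-values from the normal approximation `2 * pnorm(-|estimate| / SE)`.
#' Refits start from the original estimate plus one central fallback
#' start. Non-converged replicates are dropped and counted; more than 10%
#' failures is an error.
#'
#' @param fit A `ug_fit` from [ug_fit()] or [ug_fit_spec()].
#' @param n_reps Number of bootstrap replicates (>= 2).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return `fit` with elements `se`, `p_values`, `boot_estimates`
#'   (replicate x parameter matrix), `n_failed` and `boot_seed` added.
#' @examples
#' fit <- ug_fit(ug_fixture("all_resettled"))
#' fit <- ug_bootstrap(fit, n_reps = 25, seed = 1)
#' fit$se
#' @export
ug_bootstrap <- function(fit, n_reps = 1000, seed = 1L) {
  stopifnot(inherits(fit, "ug_fit"), n_reps >= 2)
  spec <- fit$spec
  if (any(vapply(spec$groups, nrow, integer(1)) == 1L))
    warning("group with a single pair: bootstrap resamples are degenerate")
  set.seed(seed)
  gn <- names(spec$groups)
  starts_b <- unique(c(fit$estimates[grep("^b", names(fit$estimates))], 5))
  starts_l <- unique(c(fit$estimates[grep("^lam", names(fit$estimates))], 5))
  # two starts: the full-data optimum and a central fallback
  nb <- if (spec$b_fixed_zero) 0L else length(spec$b_sharing)
  start1 <- fit$estimates
  start2 <- c(rep(5, nb), rep(5, length(spec$lam_sharing)))

  est <- matrix(NA_real_, nrow = n_reps, ncol = length(fit$estimates),
                dimnames = list(NULL, names(fit$estimates)))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    groups_r <- lapply(spec$groups, function(g) {
      idx <- sample.int(nrow(g), nrow(g), replace = TRUE)
      out <- g[idx, , drop = FALSE]
      class(out) <- c("ug_data", "data.frame")
      out
    })
    spec_r <- ug_model_spec(groups_r, spec$b_sharing, spec$lam_sharing,
                            spec$b_fixed_zero)
    f_r <- tryCatch(
      suppressWarnings(refit_from_starts(spec_r, fit, start1, start2)),
      error = function(e) NULL)
    if (is.null(f_r) || f_r$convergence != 0) { n_failed <- n_failed + 1L; next }
    est[r, ] <- f_r$par
  }
  if (n_failed > 0.10 * n_reps)
    stop("bootstrap failed in ", n_failed, " of ", n_reps, " replicates")
  if (n_failed > 0)
    message(n_failed, " non-converged bootstrap replicate(s) dropped")
  ok <- stats::complete.cases(est)
  se <- apply(est[ok, , drop = FALSE], 2, stats::sd)
  fit$se <- se
  fit$p_values <- 2 * stats::pnorm(-abs(fit$estimates) / se)
  fit$boot_estimates <- est[ok, , drop = FALSE]
  fit$n_failed <- n_failed
  fit$n_reps <- n_reps
  fit$boot_seed <- seed
  fit
}

# One cheap refit used inside the bootstrap: L-BFGS-B from two starts.
refit_from_starts <- function(spec, fit, start1, start2) {
  game <- fit$game
  bins <- lapply(spec$groups, ug_bin_data, game = game)
  gn <- names(spec$groups)
  b_idx <- block_index(spec$b_sharing, gn)
  l_idx <- block_index(spec$lam_sharing, gn)
  nb <- if (spec$b_fixed_zero) 0L else length(spec$b_sharing)
  nl <- length(spec$lam_sharing)
  nll_joint <- function(theta) {
    bs <- if (nb > 0) theta[seq_len(nb)] else numeric(0)
    ls <- theta[nb + seq_len(nl)]
    tot <- 0
    for (i in seq_along(gn)) {
      b_g <- if (spec$b_fixed_zero) 0 else bs[b_idx[i]]
      tot <- tot + nll_binned(bins[[i]], b_g, ls[l_idx[i]], game)
    }
    tot
  }
  lower <- c(rep(fit$b_bounds[1], nb), rep(fit$lam_bounds[1], nl))
  upper <- c(rep(fit$b_bounds[2], nb), rep(fit$lam_bounds[2], nl))
  # a start exactly on a bound stalls the line search; pull it inside
  margin <- 0.005 * (upper - lower)
  clamp <- function(st) pmin(pmax(as.numeric(st), lower + margin),
                             upper - margin)
  best <- NULL
  for (st in list(clamp(start1), clamp(start2))) {
    o <- tryCatch(
      stats::optim(as.numeric(st), nll_joint, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = fit$factr, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("refit failed from all starts")
  best
}
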