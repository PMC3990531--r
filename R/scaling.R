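gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

fit_refused <- function(msg) abort(msg, class = "socnet_fit_refused")

#' Discrete truncated power-law fit
#'
#' Maximum-likelihood fit of the discrete power law `P(x) ~ x^-tau` truncated
#' to `[x_min, x_max]`. The normalisation runs over the arithmetic lattice the
#' sample actually lives on (detected from the gcd of offsets from `x_min`):
#' some generating processes put all their mass on a sub-lattice — a binary
#' branching process, for instance, only ever produces odd total progeny — and
#' normalising over all integers would bias the exponent. The standard error
#' comes from the observed Fisher information. A least-squares fit to the
#' complementary cumulative distribution (slope of `log P(X >= x)` against
#' `log x`) is reported alongside for figure parity; its density exponent is
#' the cumulative exponent plus one, exactly.
#'
#' @param x positive integer samples (sizes or durations).
#' @param x_min,x_max fit range (inclusive). `x_min = NULL` selects the lower
#'   cutoff from the data by minimising the Kolmogorov-Smirnov distance
#'   between the empirical and fitted distributions over the candidates in
#'   `x_min_scan` — the standard remedy when the head of the distribution is
#'   shaped by non-universal effects (trigger neighbourhoods, offspring-law
#'   head) rather than the scaling regime.
#' @param x_min_scan candidate lower cutoffs examined when `x_min = NULL`.
#' @param min_samples refuse the fit when fewer samples fall in range.
#' @return A `powerlaw_fit` object: list with `tau` (ML density exponent),
#'   `se`, `estimates` (tibble with both estimators, each as density and
#'   cumulative exponent), `n`, `x_min`, `x_max`, `lattice`.
#' @export
#' @examples
#' x <- rzipf(2000, tau = 1.5, x_max = 1000, seed = 1)
#' fit_powerlaw_tail(x, 1, 1000)
fit_powerlaw_tail <- function(x, x_min = 1, x_max = max(x),
                              x_min_scan = 1:8, min_samples = 100) {
  x <- as.numeric(x)
  if (is.null(x_min)) {
    cand <- x_min_scan[x_min_scan < x_max]
    ks <- vapply(cand, function(m) {
      tryCatch(
        powerlaw_ks(x, m, x_max, min_samples),
        socnet_fit_refused = function(e) NA_real_
      )
    }, numeric(1))
    if (all(is.na(ks))) fit_refused("no candidate x_min admits a fit.")
    x_min <- cand[which.min(ks)]
  }
  x <- x[x >= x_min & x <= x_max]
  n <- length(x)
  if (n < min_samples) {
    fit_refused(sprintf("only %d samples in [%s, %s]; need >= %d.", n, x_min, x_max, min_samples))
  }
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    fit_refused("degenerate sample: all values identical in the fit range.")
  }
  lattice <- Reduce(gcd2, as.integer(ux - min(ux)))
  support <- seq(min(ux), x_max, by = lattice)
  logsup <- log(support)
  mean_logx <- mean(log(x))
  nll <- function(tau) {
    tau * mean_logx + log(sum(exp(-tau * logsup)))
  }
  opt <- optimize(nll, interval = c(0.05, 8))
  tau <- opt$minimum
  # observed information: n * Var_fit(log k) over the truncated support
  wts <- exp(-tau * logsup)
  wts <- wts / sum(wts)
  v <- sum(wts * logsup^2) - sum(wts * logsup)^2
  se <- 1 / sqrt(n * v)

  # complementary-cumulative least squares (figure parity)
  counts <- tabulate(match(x, ux), nbins = length(ux))
  ccdf <- (n - c(0, cumsum(counts)[-length(counts)])) / n
  cc_fit <- lm(log(ccdf) ~ log(ux))
  tau_cc_cum <- -unname(coef(cc_fit)[2L])
  cc_se <- summary(cc_fit)$coefficients[2L, 2L]

  estimates <- tibble::tibble(
    method = c("mle", "ccdf_ls"),
    exponent = c(tau, tau_cc_cum + 1),
    cumulative_exponent = c(tau - 1, tau_cc_cum),
    se = c(se, cc_se)
  )
  structure(
    list(
      tau = tau, se = se, estimates = estimates, n = n,
      x_min = x_min, x_max = x_max, lattice = lattice
    ),
    class = "powerlaw_fit"
  )
}

# KS distance between the empirical distribution on [x_min, x_max] and the
# fitted truncated discrete power law (used for x_min selection)
powerlaw_ks <- function(x, x_min, x_max, min_samples = 100) {
  fit <- fit_powerlaw_tail(x, x_min, x_max, min_samples = min_samples)
  xs <- x[x >= x_min & x <= x_max]
  support <- seq(fit$x_min, x_max, by = fit$lattice)
  p <- support^(-fit$tau)
  p <- p / sum(p)
  cdf_fit <- cumsum(p)
  idx <- pmin(length(support), ((xs - fit$x_min) %/% fit$lattice) + 1L)
  cdf_emp <- cumsum(tabulate(idx, nbins = length(support))) / length(xs)
  max(abs(cdf_emp - cdf_fit))
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> tau = %.3f (se %.3f, MLE), ccdf-LS density exponent %.3f; n = %d on [%g, %g]\n",
    x$tau, x$se, x$estimates$exponent[2L], x$n, x$x_min, x$x_max
  ))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(
    term = paste0("tau_", x$estimates$method),
    estimate = x$estimates$exponent,
    std.error = x$estimates$se
  )
}

#' Mean avalanche size versus duration scaling
#'
#' Least-squares slope `gamma` of `log <S>(T)` against `log T` over durations
#' populated by at least `min_count` avalanches. At criticality
#' `<S>(T) ~ T^gamma`, and `gamma` must match `(alpha - 1) / (tau - 1)` — the
#' crackling-noise exponent relation.
#'
#' @param summaries an `avalanche_ensemble` or any data frame with columns
#'   `S` and `T`.
#' @param t_min,t_max duration fit range.
#' @param min_count minimum avalanches per duration.
#' @param min_durations refuse the fit below this many populated durations.
#' @return A list with `gamma`, `se`, `data` (per-duration means), `t_min`,
#'   `t_max`.
#' @export
fit_size_vs_duration <- function(summaries, t_min = 1, t_max = max(summaries$T),
                                 min_count = 20, min_durations = 10) {
  df <- dplyr::filter(
    tibble::as_tibble(summaries[c("S", "T")]),
    .data$T >= t_min, .data$T <= t_max
  )
  by_t <- dplyr::summarise(dplyr::group_by(df, .data$T),
    mean_S = mean(.data$S), n = dplyr::n(), .groups = "drop"
  )
  by_t <- dplyr::filter(by_t, .data$n >= min_count)
  if (nrow(by_t) < min_durations) {
    fit_refused(sprintf(
      "only %d durations with >= %d avalanches in [%s, %s]; need >= %d.",
      nrow(by_t), min_count, t_min, t_max, min_durations
    ))
  }
  fit <- lm(log(mean_S) ~ log(T), data = by_t)
  # suppressWarnings: an exactly linear log-log relation triggers the
  # "essentially perfect fit" note and a zero standard error, both fine here
  list(
    gamma = unname(coef(fit)[2L]),
    se = suppressWarnings(summary(fit)$coefficients[2L, 2L]),
    data = by_t, t_min = t_min, t_max = t_max
  )
}

#' Fitted avalanche scaling exponents
#'
#' Fits the three critical exponents of an avalanche ensemble: `tau` for the
#' size density `P(S) ~ S^-tau`, `alpha` for the duration density
#' `P(T) ~ T^-alpha`, and `gamma` for the mean-size scaling
#' `<S>(T) ~ T^gamma`, and evaluates the crackling-noise relation
#' `gamma = (alpha - 1) / (tau - 1)`. Default fit ranges mirror the cutoff
#' structure of finite critical networks: upper cutoffs are `N/2` for sizes
#' (the power law extends almost up to network size, where system-spanning
#' avalanches accumulate) and the saturation knee for durations (the first
#' duration whose mean size exceeds `N/2`, beyond which avalanches span most
#' of the system); lower cutoffs are selected by Kolmogorov-Smirnov distance
#' (see [fit_powerlaw_tail()]), since the first few sizes and durations
#' reflect the trigger node's immediate neighbourhood rather than universal
#' scaling. Avalanches truncated by the step cap are excluded from all fits
#' and counted in `n_capped`.
#'
#' @param ensemble an `avalanche_ensemble` (or data frame with `S`, `T`).
#' @param n_nodes network size `N`; defaults to `attr(ensemble, "n_nodes")`.
#' @param s_range,t_range optional explicit fit ranges (length-2 vectors)
#'   overriding the defaults.
#' @param min_count minimum avalanches per duration for the `<S>(T)` fit.
#' @return A `scaling_fit` object; see [tidy.scaling_fit()] and
#'   [glance.scaling_fit()] for tabular views, and
#'   [exponent_relation_check()] for the relation residual.
#' @export
scaling_fit <- function(ensemble, n_nodes = attr(ensemble, "n_nodes"),
                        s_range = NULL, t_range = NULL, min_count = 20) {
  df <- tibble::as_tibble(ensemble[c("S", "T", "terminated_by")])
  n_capped <- sum(df$terminated_by == "cap")
  df <- dplyr::filter(df, .data$terminated_by != "cap")
  if (n_capped > 0.001 * nrow(df)) {
    warn(sprintf(
      "%d avalanches (> 0.1%%) hit the step cap and were excluded; fits may be biased.",
      n_capped
    ), class = "socnet_cap_warning")
  }
  s_min <- s_max <- t_min <- t_max <- NULL
  if (is.null(s_range)) {
    if (is.null(n_nodes)) {
      stop_invalid("supply `n_nodes` or an explicit `s_range`.")
    }
    s_max <- max(2, floor(n_nodes / 2))
  } else {
    s_min <- s_range[1L]
    s_max <- s_range[2L]
  }
  if (is.null(t_range)) {
    by_t <- dplyr::summarise(dplyr::group_by(df, .data$T),
      mean_S = mean(.data$S), .groups = "drop"
    )
    by_t <- dplyr::arrange(by_t, .data$T)
    if (!is.null(n_nodes)) {
      knee <- by_t$T[which(by_t$mean_S > 0.5 * n_nodes)[1L]]
      t_max <- if (is.na(knee)) max(df$T) else max(2, knee - 1)
    } else {
      t_max <- max(df$T)
    }
  } else {
    t_min <- t_range[1L]
    t_max <- t_range[2L]
  }
  size_fit <- fit_powerlaw_tail(df$S, s_min, s_max)
  dur_fit <- fit_powerlaw_tail(df$T, t_min, t_max)
  s_range <- c(size_fit$x_min, s_max)
  t_range <- c(dur_fit$x_min, t_max)
  st_fit <- fit_size_vs_duration(df,
    t_min = t_range[1L], t_max = t_range[2L],
    min_count = min_count, min_durations = min(10, max(3, t_max - t_range[1L]))
  )
  out <- structure(
    list(
      tau = size_fit$tau, tau_se = size_fit$se,
      alpha = dur_fit$tau, alpha_se = dur_fit$se,
      gamma = st_fit$gamma, gamma_se = st_fit$se,
      tau_cumulative = size_fit$tau - 1,
      alpha_cumulative = dur_fit$tau - 1,
      size_fit = size_fit, duration_fit = dur_fit, st_fit = st_fit,
      s_range = s_range, t_range = t_range,
      n_avalanches = nrow(df), n_capped = n_capped
    ),
    class = "scaling_fit"
  )
  rel <- exponent_relation_check(out)
  out$relation_residual <- rel$residual
  out$relation_se <- rel$se
  out$relation_consistent <- rel$consistent
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<scaling_fit> tau = %.3f (%.3f), alpha = %.3f (%.3f), gamma = %.3f (%.3f)\n",
      "  relation residual gamma - (alpha-1)/(tau-1) = %+.3f (se %.3f) -> %s\n",
      "  %d avalanches; S in [%g, %g], T in [%g, %g]\n"
    ),
    x$tau, x$tau_se, x$alpha, x$alpha_se, x$gamma, x$gamma_se,
    x$relation_residual, x$relation_se,
    if (x$relation_consistent) "consistent with criticality" else "NOT consistent",
    x$n_avalanches, x$s_range[1L], x$s_range[2L], x$t_range[1L], x$t_range[2L]
  ))
  invisible(x)
}

#' Tidy and glance methods for scaling fits
#'
#' @param x a `scaling_fit` object.
#' @param ... unused.
#' @return `tidy()` returns one row per exponent (`term`, `estimate`,
#'   `std.error`, `cumulative`); `glance()` a one-row model summary.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "alpha", "gamma"),
    estimate = c(x$tau, x$alpha, x$gamma),
    std.error = c(x$tau_se, x$alpha_se, x$gamma_se),
    cumulative = c(x$tau_cumulative, x$alpha_cumulative, NA_real_)
  )
}

#' @rdname tidy.scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(
    tau = x$tau, alpha = x$alpha, gamma = x$gamma,
    relation_residual = x$relation_residual,
    relation_se = x$relation_se,
    relation_consistent = x$relation_consistent,
    n_avalanches = x$n_avalanches, n_capped = x$n_capped
  )
}

#' Crackling-noise exponent relation
#'
#' Residual of the scaling relation `gamma = (alpha - 1) / (tau - 1)` that
#' links the size, duration, and mean-size exponents of a critical system,
#' with first-order error propagation; the fit is flagged consistent when the
#' residual is within two propagated standard errors of zero.
#'
#' @param fit a `scaling_fit`, or any list with `tau`, `alpha`, `gamma` and
#'   their `_se` standard errors.
#' @return A one-row tibble with `residual`, `se`, `consistent`.
#' @export
exponent_relation_check <- function(fit) {
  tau <- fit$tau
  alpha <- fit$alpha
  gamma <- fit$gamma
  residual <- gamma - (alpha - 1) / (tau - 1)
  se <- sqrt(
    fit$gamma_se^2 +
      (fit$alpha_se / (tau - 1))^2 +
      (fit$tau_se * (alpha - 1) / (tau - 1)^2)^2
  )
  tibble::tibble(residual = residual, se = se, consistent = abs(residual) <= 2 * se)
}

#' Avalanche-shape collapse
#'
#' Searches for the exponent `gamma` under which the mean temporal profiles
#' of avalanches of different durations — time rescaled to the unit interval,
#' amplitude divided by `T^(gamma - 1)` — collapse onto one universal shape.
#' The collapse error is the across-duration variance of the rescaled
#' profiles on a common grid, normalised by the squared grand mean; it is
#' reported alongside the baseline error of the unrescaled profiles
#' (`gamma = 1`), so a successful collapse shows up as a large error
#' reduction. The quoted `gamma_se` is the half-width over which the collapse
#' error doubles — the scale of the collapse valley, not a sampling error.
#'
#' @param ensemble an `avalanche_ensemble` with profiles.
#' @param durations duration classes to collapse (each needs `min_count`
#'   avalanches).
#' @param gammas either `NULL` (continuous search over (1, 3.5)) or a vector
#'   of candidate exponents to evaluate.
#' @param n_bins common rescaled-time grid size.
#' @param min_count minimum avalanches per duration class.
#' @return A `collapse_result`: list with `gamma_shape`, `gamma_se`,
#'   `collapse_error`, `baseline_error`, `durations`, `profiles` (long tibble
#'   of rescaled mean profiles at `gamma_shape`).
#' @export
shape_collapse <- function(ensemble, durations = c(8, 16, 32), gammas = NULL,
                           n_bins = 20, min_count = 50) {
  if (!"profile" %in% names(ensemble)) {
    stop_invalid("ensemble was generated with keep_profiles = FALSE.")
  }
  counts <- vapply(durations, function(d) sum(ensemble$T == d), integer(1))
  if (length(durations) < 3L || any(counts < min_count)) {
    fit_refused(sprintf(
      "need >= 3 duration classes with >= %d avalanches each; counts: %s.",
      min_count, paste(counts, collapse = ", ")
    ))
  }
  base_profiles <- lapply(durations, function(d) {
    mean_profile(ensemble, d, n_bins = n_bins, gamma = 1)
  })
  values <- vapply(base_profiles, function(p) p$value, numeric(n_bins))
  collapse_error <- function(gamma) {
    y <- sweep(values, 2L, durations^(gamma - 1), `/`)
    mean(apply(y, 1L, var)) / mean(y)^2
  }
  if (is.null(gammas)) {
    opt <- optimize(collapse_error, interval = c(1, 3.5))
    gamma_shape <- opt$minimum
    err <- opt$objective
  } else {
    errs <- vapply(gammas, collapse_error, numeric(1))
    gamma_shape <- gammas[which.min(errs)]
    err <- min(errs)
  }
  # width of the collapse valley: |dg| where the error doubles (quadratic approx)
  h <- 0.05
  curv <- (collapse_error(gamma_shape + h) + collapse_error(gamma_shape - h) - 2 * err) / h^2
  gamma_se <- if (curv > 0) sqrt(2 * err / curv) else NA_real_
  profiles <- dplyr::bind_rows(lapply(durations, function(d) {
    mean_profile(ensemble, d, n_bins = n_bins, gamma = gamma_shape)
  }))
  structure(
    list(
      gamma_shape = gamma_shape, gamma_se = gamma_se,
      collapse_error = err, baseline_error = collapse_error(1),
      durations = durations, n_bins = n_bins, profiles = profiles
    ),
    class = "collapse_result"
  )
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf(
    "<collapse_result> gamma = %.3f (valley width %.3f); error %.4g vs baseline %.4g (T = %s)\n",
    x$gamma_shape, x$gamma_se, x$collapse_error, x$baseline_error,
    paste(x$durations, collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.collapse_result <- function(x, ...) {
  tibble::tibble(
    term = "gamma_shape", estimate = x$gamma_shape, std.error = x$gamma_se,
    collapse_error = x$collapse_error, baseline_error = x$baseline_error
  )
}
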