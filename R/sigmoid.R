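#' @include AllClasses.R
NULL

# Canonical melting-curve parameterization used throughout CETSA/TPP work:
# f(T) = (1 - p) / (1 + exp(b - a/T)) + p, with lower plateau p and shape
# constants a, b; the half-denaturation point Tm solves b - a/Tm = 0.
.sigmoid_eval <- function(temp, p, a, b) {
  (1 - p) / (1 + exp(b - a / temp)) + p
}

#' Fit a sigmoid melting curve by bounded nonlinear least squares
#'
#' Fits \eqn{f(T) = (1 - p)/(1 + exp(b - a/T)) + p} to relative-abundance
#' observations by Levenberg-Marquardt least squares with the plateau bounded
#' to `[0, 1.5]`, multi-started from five deterministic initializations (a
#' grid of plausible melting points spanning the observed temperature range);
#' the best-RSS converged attempt wins, ties going to the earliest start.
#'
#' @param temperature Celsius values (>= 4 distinct).
#' @param value relative (ratio-scale) abundances.
#' @return a [SigmoidFit-class]. When no start converges, the best attempt is
#'   retained with `converged = FALSE`.
#' @examples
#' tm <- seq(37, 67, length.out = 10)
#' y <- (1 - 0.1) / (1 + exp(25 - 1300 / tm)) + 0.1
#' fitSigmoid(tm, y)
#' @export
fitSigmoid <- function(temperature, value) {
  ok <- is.finite(temperature) & is.finite(value)
  temperature <- temperature[ok]
  value <- value[ok]
  n <- length(value)
  if (length(unique(temperature)) < 4)
    stop("fitSigmoid needs at least 4 distinct temperatures")
  tss <- sum((value - mean(value))^2)
  tm_grid <- seq(min(temperature), max(temperature), length.out = 5)
  best <- NULL
  best_rss <- Inf
  best_conv <- FALSE
  for (tm0 in tm_grid) {
    # slope-at-midpoint heuristic: b = a/tm0, a from a moderate steepness
    a0 <- 550 * tm0 / 10          # gives ~10 degC transition width near tm0
    start <- list(p = max(min(min(value), 1), 0), a = a0, b = a0 / tm0)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        value ~ (1 - p) / (1 + exp(b - a / temperature)) + p,
        start = start,
        lower = c(p = 0, a = 1e-6, b = 1e-6),
        upper = c(p = 1.5, a = 1e6, b = 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    conv <- fit$convInfo$isConv
    better <- (conv && !best_conv) ||
      (conv == best_conv && rss < best_rss - 1e-14)
    if (better) {
      best <- stats::coef(fit)
      best_rss <- rss
      best_conv <- conv
    }
  }
  if (is.null(best)) {
    return(new("SigmoidFit", p = NA_real_, a = NA_real_, b = NA_real_,
               tm = NA_real_, r2 = NA_real_, rss = NA_real_,
               converged = FALSE, n_obs = as.integer(n)))
  }
  # polish from the winning start so exact data is reproduced tightly
  polish <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      value ~ (1 - p) / (1 + exp(b - a / temperature)) + p,
      start = as.list(best),
      lower = c(p = 0, a = 1e-6, b = 1e-6),
      upper = c(p = 1.5, a = 1e6, b = 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))),
    error = function(e) NULL)
  if (!is.null(polish)) {
    rss_p <- sum(stats::resid(polish)^2)
    if (rss_p <= best_rss) {
      best <- stats::coef(polish)
      best_rss <- rss_p
      best_conv <- best_conv || polish$convInfo$isConv
    }
  }
  tm <- unname(best["a"] / best["b"])
  if (!is.finite(tm) || tm < min(temperature) - 50 ||
      tm > max(temperature) + 50) tm <- NA_real_
  r2 <- if (tss > 0) 1 - best_rss / tss else NA_real_
  flat <- tss > 0 && (!is.finite(r2) || r2 <= 0)
  new("SigmoidFit", p = unname(best["p"]), a = unname(best["a"]),
      b = unname(best["b"]), tm = tm, r2 = r2, rss = best_rss,
      converged = best_conv && !is.na(r2) && tss > 0 && !flat,
      n_obs = as.integer(n))
}

#' Fit full and reduced sigmoid models to a two-condition profile
#'
#' The full model fits one sigmoid per condition; the reduced (null) model
#' fits a single shared sigmoid to all conditions jointly. Replicates are fit
#' jointly within each condition.
#'
#' @param data data.frame with columns `temperature`, `value`, `condition`.
#' @return list with elements `full` (named list of per-condition
#'   [SigmoidFit-class]), `reduced` ([SigmoidFit-class]), `rss0`, `rss1`,
#'   `df1`, `df2`, `n_obs`.
#' @export
fitSigmoidPair <- function(data) {
  stopifnot(all(c("temperature", "value", "condition") %in% names(data)))
  conds <- sort(unique(data$condition))
  full <- lapply(conds, function(cc) {
    sub <- data[data$condition == cc, ]
    fitSigmoid(sub$temperature, sub$value)
  })
  names(full) <- conds
  reduced <- fitSigmoid(data$temperature, data$value)
  rss1 <- sum(vapply(full, function(f) f@rss, numeric(1)))
  n <- nrow(data)
  p_full <- 3 * length(conds)
  list(full = full, reduced = reduced, rss0 = reduced@rss, rss1 = rss1,
       df1 = p_full - 3, df2 = n - p_full, n_obs = n)
}
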