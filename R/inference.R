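#' @include AllClasses.R study_io.R
NULL

#' Nested-model F statistic
#'
#' \eqn{F = ((RSS_0 - RSS_1)/d_1) / (RSS_1/d_2)}, compared to the F
#' distribution with \eqn{(d_1, d_2)} degrees of freedom. Tiny negative
#' numerators from numerical noise are clipped to zero (p = 1); a zero
#' denominator yields an infinite statistic with p = 0, flagged.
#'
#' @param rss0,rss1 reduced- and full-model residual sums of squares.
#' @param df1,df2 numerator and denominator degrees of freedom (> 0).
#' @return list with `statistic`, `pvalue`, `flagged`.
#' @export
fStatistic <- function(rss0, rss1, df1, df2) {
  if (df1 <= 0 || df2 <= 0) stop("degrees of freedom must be positive")
  num <- max(rss0 - rss1, 0)
  if (rss1 <= 0) {
    if (num == 0) return(list(statistic = 0, pvalue = 1, flagged = TRUE))
    return(list(statistic = Inf, pvalue = 0, flagged = TRUE))
  }
  f <- (num / df1) / (rss1 / df2)
  list(statistic = f, pvalue = stats::pf(f, df1, df2, lower.tail = FALSE),
       flagged = FALSE)
}

#' Estimate empirical-Bayes moderation parameters
#'
#' Pools per-protein residual variances by moment-matching the distribution
#' of log variances against a scaled F prior (the limma `fitFDist`
#' approach), returning the prior degrees of freedom `d0` and prior variance
#' `s0_sq`. `d0` is infinite when the spread of the observed variances does
#' not exceed their sampling variability; estimates above 1e6 are treated as
#' infinite.
#'
#' @param s_sq per-protein residual variances (>= 10 finite positive values).
#' @param df2 residual degrees of freedom of each variance.
#' @return list with `d0`, `s0_sq`.
#' @export
estimateModeration <- function(s_sq, df2) {
  ok <- is.finite(s_sq) & s_sq > 0
  if (sum(ok) < 10)
    stop("need >= 10 proteins with positive residual variance; ",
         "use the plain F test instead")
  fd <- limma::fitFDist(s_sq[ok], df1 = df2)
  d0 <- fd$df2
  if (is.na(d0) || d0 > 1e6) d0 <- Inf
  list(d0 = d0, s0_sq = fd$scale)
}

#' Moderated F test
#'
#' Replaces the residual variance in the F denominator with the shrunken
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_2 s^2) / (d_0 + d_2)} and compares to
#' the F distribution with \eqn{(d_1, d_0 + d_2)} degrees of freedom. With
#' `d0 = 0` this is exactly the plain F test; with `d0 = Inf` the
#' denominator is `s0_sq` and the reference has infinite denominator df.
#'
#' @param rss0,rss1,df1,df2 as in [fStatistic()].
#' @param params moderation parameters from [estimateModeration()].
#' @param s_sq this protein's residual variance (default `rss1/df2`).
#' @return list with `statistic`, `pvalue`, `s_tilde_sq`, `flagged`.
#' @export
moderatedF <- function(rss0, rss1, df1, df2, params, s_sq = rss1 / df2) {
  d0 <- params$d0
  s0 <- params$s0_sq
  s_tilde <- if (is.infinite(d0)) s0 else (d0 * s0 + df2 * s_sq) / (d0 + df2)
  num <- max(rss0 - rss1, 0)
  if (s_tilde <= 0) {
    if (num == 0) return(list(statistic = 0, pvalue = 1,
                              s_tilde_sq = s_tilde, flagged = TRUE))
    return(list(statistic = Inf, pvalue = 0, s_tilde_sq = s_tilde,
                flagged = TRUE))
  }
  f <- (num / df1) / s_tilde
  list(statistic = f,
       pvalue = stats::pf(f, df1, d0 + df2, lower.tail = FALSE),
       s_tilde_sq = s_tilde, flagged = FALSE)
}

#' Empirical-Bayes rescaled F inference over sigmoid fits
#'
#' Approximates the across-protein distributions of the numerator
#' \eqn{RSS_0 - RSS_1} and denominator \eqn{RSS_1} separately as scaled
#' chi-squares sharing one scale \eqn{\sigma_0^2}:
#' \eqn{RSS_0 - RSS_1 \sim \sigma_0^2 \chi^2(d_1)} and
#' \eqn{RSS_1 \sim \sigma_0^2 \chi^2(d_2)}, with effective degrees of
#' freedom and scale estimated by joint maximum likelihood
#' (method-of-moments initialization). Each protein's
#' \eqn{F = ((RSS_0 - RSS_1)/d_1)/(RSS_1/d_2)} is then compared to
#' \eqn{F(d_1, d_2)}. Non-positive numerators get p = 1.
#'
#' @param delta_rss per-protein \eqn{RSS_0 - RSS_1}.
#' @param rss1 per-protein full-model residual sums of squares.
#' @return list with `params` (`d1`, `d2`, `sigma0_sq`, `converged`),
#'   `statistic`, and `pvalue` vectors aligned with the input.
#' @export
nparcEbInference <- function(delta_rss, rss1) {
  stopifnot(length(delta_rss) == length(rss1))
  if (length(delta_rss) < 50)
    warning("fewer than 50 proteins; empirical degrees of freedom may be unstable")
  x1 <- delta_rss[is.finite(delta_rss) & delta_rss > 0]
  x2 <- rss1[is.finite(rss1) & rss1 > 0]
  mom <- function(x) {
    m <- mean(x); v <- stats::var(x)
    c(d = 2 * m^2 / v, s = v / (2 * m))
  }
  m1 <- mom(x1); m2 <- mom(x2)
  init <- log(c(d1 = unname(m1["d"]), d2 = unname(m2["d"]),
                s = unname((m1["s"] + m2["s"]) / 2)))
  nll <- function(par) {
    d1 <- exp(par[1]); d2 <- exp(par[2]); s <- exp(par[3])
    -sum(stats::dgamma(x1, shape = d1 / 2, scale = 2 * s, log = TRUE)) -
      sum(stats::dgamma(x2, shape = d2 / 2, scale = 2 * s, log = TRUE))
  }
  opt <- tryCatch(stats::optim(init, nll, method = "BFGS",
                               control = list(maxit = 500)),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    warning("empirical-Bayes fit diverged; falling back to moment estimates")
    d1 <- unname(m1["d"]); d2 <- unname(m2["d"])
    s0 <- unname((m1["s"] + m2["s"]) / 2)
    converged <- FALSE
  } else {
    d1 <- exp(opt$par[[1]]); d2 <- exp(opt$par[[2]]); s0 <- exp(opt$par[[3]])
    converged <- opt$convergence == 0
  }
  f <- ifelse(delta_rss <= 0 | rss1 <= 0, 0,
              (delta_rss / d1) / (rss1 / d2))
  p <- ifelse(f <= 0, 1, stats::pf(f, d1, d2, lower.tail = FALSE))
  list(params = list(d1 = d1, d2 = d2, sigma0_sq = s0,
                     converged = converged),
       statistic = f, pvalue = p)
}

#' Wald test on the SCAM difference in means
#'
#' @param fit a [ScamFit-class].
#' @param protein_id id for the result row.
#' @return a [testResult()] row (model `"scam"`); z statistic against the
#'   standard normal, two-sided.
#' @export
scamDimTest <- function(fit, protein_id = NA_character_) {
  stopifnot(is(fit, "ScamFit"))
  if (!fit@converged || !is.finite(fit@dim_se) || fit@dim_se == 0)
    return(testResult(protein_id, "scam", decision = "failed",
                      n_obs = fit@n_obs))
  z <- fit@dim / fit@dim_se
  testResult(protein_id, "scam", statistic = z, estimate = fit@dim,
             se = fit@dim_se, pvalue = 2 * stats::pnorm(-abs(z)),
             n_obs = fit@n_obs)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; ties and input order preserved.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Quality filter preceding sigmoid-based inference
#'
#' Keeps a protein for inference only when the sigmoid fit quality criteria
#' hold: R-squared strictly above `r2_min` and lower plateau strictly below
#' `plateau_max`. By default both conditions must pass (`rule = "both"`);
#' `rule = "any"` requires one. Boundary values are excluded (strict
#' inequalities). Dropped proteins are to be reported with decision
#' `"filtered"`, not tested.
#'
#' @param fits named list, one element per protein, each a list of
#'   per-condition [SigmoidFit-class] objects.
#' @param r2_min,plateau_max thresholds (defaults 0.8 and 0.3).
#' @param rule `"both"` or `"any"`: how many conditions must pass.
#' @return named logical vector, `TRUE` = keep.
#' @export
nparcPostfilter <- function(fits, r2_min = 0.8, plateau_max = 0.3,
                            rule = c("both", "any")) {
  rule <- match.arg(rule)
  vapply(fits, function(fl) {
    ok <- vapply(fl, function(f)
      isTRUE(is.finite(f@r2) && f@r2 > r2_min &&
               is.finite(f@p) && f@p < plateau_max), logical(1))
    if (rule == "both") all(ok) else any(ok)
  }, logical(1))
}

#' Replicate-level decision rule for the sigmoid TPP model
#'
#' A protein is called an interactor only if all four criteria hold across
#' the replicate-level fits: the melting-point shifts share one sign; every
#' replicate's p-value is below 0.05; at least one replicate has R-squared
#' above 0.8; and every lower plateau is below 0.3 (strict inequalities
#' throughout). Any undefined melting point yields `"failed"`.
#'
#' @param delta_tm per-replicate treated-minus-vehicle Tm shifts.
#' @param pvalue per-replicate p-values.
#' @param r2 per-replicate R-squared values (best of the two conditions).
#' @param plateaus all lower-plateau values across replicates and conditions.
#' @return `"interactor"`, `"non-interactor"`, or `"failed"`.
#' @export
tppSigmoidDecision <- function(delta_tm, pvalue, r2, plateaus) {
  if (length(delta_tm) < 2) stop("need >= 2 replicate-level results")
  if (any(!is.finite(delta_tm))) return("failed")
  same_sign <- all(delta_tm > 0) || all(delta_tm < 0)
  ok <- same_sign && all(pvalue < 0.05) && any(r2 > 0.8) &&
    all(plateaus < 0.3)
  if (ok) "interactor" else "non-interactor"
}
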