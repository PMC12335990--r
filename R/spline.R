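#' @include AllClasses.R
NULL

#' Fit a natural cubic spline model to a two-condition profile
#'
#' Least-squares fit of a natural cubic spline basis with `d` degrees of
#' freedom on temperature. `scope = "full"` fits separate coefficients (and
#' intercepts) per condition; `scope = "reduced"` fits one shared curve for
#' all conditions. The two scopes are nested, so
#' RSS(reduced) >= RSS(full) on identical data.
#'
#' @param data data.frame with columns `temperature`, `value`, `condition`.
#' @param d basis degrees of freedom (default 5; 4 is the economical choice).
#' @param scope `"full"` or `"reduced"`.
#' @return a [SplineFit-class].
#' @export
fitSpline <- function(data, d = 5, scope = c("full", "reduced")) {
  scope <- match.arg(scope)
  stopifnot(all(c("temperature", "value", "condition") %in% names(data)))
  d <- as.integer(d)
  conds <- sort(unique(data$condition))
  if (length(unique(data$temperature)) < d + 1)
    stop("need at least d + 1 distinct temperatures")
  basis <- splines::ns(data$temperature, df = d)
  if (scope == "full" && length(conds) > 1) {
    cf <- factor(data$condition, levels = conds)
    X <- stats::model.matrix(~ cf + cf:basis - 1)
  } else {
    X <- cbind(1, basis)
  }
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    # identify which condition's block is deficient
    if (scope == "full") {
      for (cc in conds) {
        sub <- data[data$condition == cc, ]
        if (length(unique(sub$temperature)) < d + 1)
          stop("rank-deficient spline basis for condition ", cc)
      }
    }
    stop("rank-deficient spline basis")
  }
  fit <- qr.coef(qr_, data$value)
  fitted <- drop(X %*% fit)
  rss <- sum((data$value - fitted)^2)
  new("SplineFit", d = d, scope = scope, rss = rss,
      n_params = ncol(X), fitted = fitted, n_obs = nrow(data))
}

#' Full-versus-reduced spline comparison for one protein
#'
#' Fits both scopes with a shared basis and returns the residual sums of
#' squares and degrees of freedom feeding the F-statistic: `df1` is the
#' difference in parameter counts, `df2` the residual degrees of freedom of
#' the full model.
#'
#' @param data data.frame with columns `temperature`, `value`, `condition`.
#' @param d basis degrees of freedom.
#' @return list with `full`, `reduced` ([SplineFit-class]), `rss0`, `rss1`,
#'   `df1`, `df2`, `n_obs`.
#' @export
fitSplinePair <- function(data, d = 5) {
  full <- fitSpline(data, d = d, scope = "full")
  reduced <- fitSpline(data, d = d, scope = "reduced")
  list(full = full, reduced = reduced,
       rss0 = reduced@rss, rss1 = full@rss,
       df1 = full@n_params - reduced@n_params,
       df2 = full@n_obs - full@n_params,
       n_obs = full@n_obs)
}
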