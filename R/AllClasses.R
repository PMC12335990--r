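#' @import methods
NULL

#' Study design for a multi-plex TMT thermal-profiling experiment
#'
#' A `StudyDesign` records, for every TMT channel of every plex, the condition,
#' biological replicate, temperature index and temperature it carries, plus its
#' role (`measurement`, `reference`, `carrier`, or `empty`). Temperature index
#' 0 denotes the reference channel when one is present, otherwise the lowest
#' temperature. Carrier and empty channels carry no temperature.
#'
#' Construction does not error on an inconsistent design; use
#' [validateDesign()] to obtain one diagnostic per violated invariant.
#'
#' @slot channels data.frame with columns `plex`, `channel`, `condition`,
#'   `replicate`, `temperature_index` (integer, `NA` for carrier/empty),
#'   `temperature` (Celsius, `NA` for carrier/empty), `role`.
#' @export
setClass("StudyDesign", representation(channels = "data.frame"))

#' Protein-level reporter abundance table
#'
#' Long-format protein-level abundances keyed by
#' (protein, condition, replicate, temperature index). The `scale` slot tracks
#' whether values are raw reporter intensities, log2-transformed, or ratios to
#' the reference channel.
#'
#' @slot data data.frame with columns `protein`, `condition`, `replicate`,
#'   `temperature_index`, `temperature`, `abundance`.
#' @slot scale one of `"raw"`, `"log2"`, `"ratio"`.
#' @export
setClass("ProteinProfileTable",
         representation(data = "data.frame", scale = "character"))

#' Feature (PSM) level intensity table
#'
#' Long-format feature intensities keyed by
#' (protein, feature, condition, replicate, temperature index). Missing
#' intensities are explicit `NA` records, never silent absence within an
#' observed feature-plex block. `shared` flags features mapping to more than
#' one protein group; `imputed` flags values filled in by [aftImpute()].
#'
#' @slot data data.frame with columns `protein`, `feature`, `plex`,
#'   `condition`, `replicate`, `temperature_index`, `temperature`,
#'   `intensity`, `shared`, `imputed`.
#' @slot scale one of `"raw"`, `"log2"`.
#' @export
setClass("FeatureTable",
         representation(data = "data.frame", scale = "character"))

#' Per-temperature normalization factors for the TPP/NPARC protocol
#'
#' @slot Q named numeric vector of multiplicative factors, one per temperature
#'   index; the factor at index 0 is forced to 1 so the reference column is
#'   never rescaled.
#' @slot condition,replicate the (condition, replicate) profile whose sigmoid
#'   fit maximized R-squared and from which the factors were derived.
#' @slot normset character vector of protein ids in the normalization set.
#' @slot fit_r2 R-squared of the winning sigmoid fit.
#' @export
setClass("NormFactors",
         representation(Q = "numeric", condition = "character",
                        replicate = "character", normset = "character",
                        fit_r2 = "numeric"))

#' Processing configuration
#'
#' Tunable knobs for both processing protocols. The NormSet ratio bounds at
#' temperature indices 6, 8 and 9 encode the removal of thermostable proteins
#' from the normalization set; they are deliberately user-tunable because no
#' canonical values exist.
#'
#' @slot normset_bounds data.frame with columns `temperature_index`, `lower`,
#'   `upper` (ratio bounds applied in every condition x replicate group).
#' @slot msstats_min_features proteins with fewer features are dropped
#'   (default 2, i.e. single-feature proteins are removed).
#' @slot msstats_max_missing_per_plex a feature-plex block with more missing
#'   channel intensities than this is dropped (default 3).
#' @slot remove_shared_features drop features shared across protein groups.
#' @slot global_median_normalization equalize channel medians (OnePot designs
#'   only; inappropriate for thermal profiles, which decay across channels).
#' @slot imputation_enabled run AFT imputation before median polish.
#' @export
setClass("ProcessingConfig",
         representation(normset_bounds = "data.frame",
                        msstats_min_features = "numeric",
                        msstats_max_missing_per_plex = "numeric",
                        remove_shared_features = "logical",
                        global_median_normalization = "logical",
                        imputation_enabled = "logical"))

setValidity("ProcessingConfig", function(object) {
  b <- object@normset_bounds
  if (!all(c("temperature_index", "lower", "upper") %in% names(b)))
    return("normset_bounds needs columns temperature_index, lower, upper")
  if (any(!is.finite(b$lower)) || any(!is.finite(b$upper)))
    return("normset bounds must be finite")
  if (any(b$lower > b$upper))
    return("normset bounds must satisfy lower <= upper")
  TRUE
})

# ---- model fits -------------------------------------------------------------

#' Sigmoid melting-curve fit
#'
#' Parameterization \eqn{f(T) = (1 - p) / (1 + exp(b - a/T)) + p}: `p` is the
#' lower plateau, `a` and `b` shape constants, and the melting point
#' \eqn{Tm = a/b} is where the curve crosses midway between 1 and `p`.
#'
#' @slot p,a,b fitted parameters.
#' @slot tm melting temperature (Celsius), `NA` when undefined.
#' @slot r2 1 - RSS/TSS of the fit.
#' @slot rss residual sum of squares.
#' @slot converged honest convergence flag.
#' @slot n_obs number of observations fitted.
#' @export
setClass("SigmoidFit",
         representation(p = "numeric", a = "numeric", b = "numeric",
                        tm = "numeric", r2 = "numeric", rss = "numeric",
                        converged = "logical", n_obs = "integer"))

#' Natural-spline fit (full or reduced scope)
#'
#' @slot d basis degrees of freedom.
#' @slot scope `"full"` (one curve per condition) or `"reduced"` (shared).
#' @slot rss residual sum of squares.
#' @slot n_params number of estimated mean parameters.
#' @slot fitted fitted values in input row order.
#' @slot n_obs number of observations.
#' @export
setClass("SplineFit",
         representation(d = "integer", scope = "character", rss = "numeric",
                        n_params = "integer", fitted = "numeric",
                        n_obs = "integer"))

#' Monotone shape-constrained additive fit
#'
#' Per-condition monotone-decreasing smooths (cumulative non-positive
#' increments on a B-spline basis, ridge-stabilized), a biological replicate
#' intercept, and the difference in means (DIM) between treated and vehicle
#' averaged over the observed temperatures.
#'
#' @slot k number of basis functions per condition.
#' @slot dim difference in means, treated minus vehicle, log2 scale.
#' @slot dim_se standard error of `dim`, incorporating both variance
#'   components.
#' @slot sigma_bio_sq,sigma_error_sq variance component estimates.
#' @slot smooths list with per-condition functions evaluating the fitted
#'   smooth at arbitrary temperatures.
#' @slot converged logical.
#' @export
setClass("ScamFit",
         representation(k = "integer", dim = "numeric", dim_se = "numeric",
                        sigma_bio_sq = "numeric", sigma_error_sq = "numeric",
                        smooths = "list", converged = "logical",
                        n_obs = "integer"))

#' Mixed-effects cell-means fit
#'
#' Cell means for every condition x temperature, a biological-replicate random
#' intercept variance, and a residual variance, estimated by REML. For
#' balanced complete data the fit is closed-form (the ANOVA decomposition,
#' which coincides with REML under balance); otherwise lme4 is used and the
#' merMod object is retained in `fit`.
#'
#' @slot cell_means named numeric vector, names `condition.t<index>`.
#' @slot sigma_bio_sq,sigma_error_sq variance components (bio truncated at 0).
#' @slot ms_rep,df_rep,ms_err,df_err balanced-case mean squares and df
#'   retained for untruncated contrast variance estimation (`NA` when the
#'   lme4 route was used).
#' @slot n_replicates,n_temperatures design shape.
#' @slot singular TRUE when the biological variance hit the zero boundary.
#' @slot balanced TRUE when the closed-form route applied.
#' @slot fit the underlying lmerTest fit for unbalanced data, else NULL.
#' @export
setClass("MixedFit",
         representation(cell_means = "numeric", sigma_bio_sq = "numeric",
                        sigma_error_sq = "numeric", ms_rep = "numeric",
                        df_rep = "numeric", ms_err = "numeric",
                        df_err = "numeric", n_replicates = "integer",
                        n_temperatures = "integer", singular = "logical",
                        balanced = "logical", fit = "ANY", n_obs = "integer"))

# ---- simulation -------------------------------------------------------------

#' Ground-truth interaction template
#'
#' Condition-by-temperature matrix of log2 mean abundances representing a
#' strong, weak, or absent protein-drug interaction. Null templates have
#' identical vehicle and treated rows; all rows are non-increasing beyond the
#' first index (melting).
#'
#' @slot temperatures ordered Celsius values.
#' @slot mu 2 x T matrix, rows `vehicle` and `treated`.
#' @slot kind `"strong"`, `"weak"`, or `"null"`.
#' @export
setClass("Template",
         representation(temperatures = "numeric", mu = "matrix",
                        kind = "character"))

setValidity("Template", function(object) {
  mu <- object@mu
  if (!identical(rownames(mu), c("vehicle", "treated")))
    return("mu must have rows vehicle, treated")
  if (ncol(mu) != length(object@temperatures))
    return("mu columns must match temperatures")
  if (is.unsorted(object@temperatures, strictly = TRUE))
    return("temperatures must be strictly increasing")
  dif <- t(apply(mu, 1, diff))
  if (any(dif > 1e-8))
    return("template rows must be non-increasing in temperature")
  if (object@kind == "null" && any(mu["vehicle", ] != mu["treated", ]))
    return("null templates must have identical condition rows")
  TRUE
})

#' Experimental design specification for simulation
#'
#' @slot mode `"thermal"` or `"onepot"`.
#' @slot n_replicates biological replicates per condition.
#' @slot temperatures_fit temperature indices entering the model fit.
#' @slot temperatures_test indices of the null-hypothesis subset (thermal).
#' @slot pooled_indices indices physically pooled per channel (onepot).
#' @slot n_plexes number of TMT plexes replicates are allocated to.
#' @export
setClass("DesignSpec",
         representation(mode = "character", n_replicates = "integer",
                        temperatures_fit = "integer",
                        temperatures_test = "integer",
                        pooled_indices = "integer", n_plexes = "integer"))

setValidity("DesignSpec", function(object) {
  if (!object@mode %in% c("thermal", "onepot"))
    return("mode must be 'thermal' or 'onepot'")
  if (object@mode == "thermal" &&
      !all(object@temperatures_test %in% object@temperatures_fit))
    return("temperatures_test must be a subset of temperatures_fit")
  if (object@mode == "onepot" && length(object@pooled_indices) == 0)
    return("onepot designs need non-empty pooled_indices")
  TRUE
})

#' Simulation configuration
#'
#' @slot sigma_bio_sq biological between-replicate variance (log2 scale).
#' @slot sigma_error_sq technological within-replicate variance (log2 scale).
#' @slot n_instances number of protein instances to simulate.
#' @slot seed mandatory integer seed.
#' @slot design a [DesignSpec-class].
#' @export
setClass("SimConfig",
         representation(sigma_bio_sq = "numeric", sigma_error_sq = "numeric",
                        n_instances = "integer", seed = "integer",
                        design = "DesignSpec"))

setValidity("SimConfig", function(object) {
  if (object@sigma_bio_sq < 0 || object@sigma_error_sq < 0)
    return("variances must be >= 0")
  if (object@design@n_replicates < 2)
    return("need at least 2 replicates per condition")
  if (length(object@seed) != 1 || is.na(object@seed))
    return("seed is mandatory")
  TRUE
})
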