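#' @include AllClasses.R study_io.R
NULL

#' Default processing configuration
#'
#' The NormSet ratio bounds restrict reference ratios at temperature indices
#' 6, 8 and 9 (the 7th, 9th and 10th temperatures) so that only proteins
#' showing canonical melting — strong decay at high temperatures — enter the
#' normalization set. No canonical numeric bounds exist; the defaults below
#' (index 6: ratio in [0, 0.6]; index 8: [0, 0.3]; index 9: [0, 0.2]) encode
#' the removal of thermostable proteins and are user-tunable.
#'
#' @param normset_bounds data.frame(`temperature_index`, `lower`, `upper`).
#' @param msstats_min_features minimum features per protein (default 2).
#' @param msstats_max_missing_per_plex maximum missing channels tolerated in a
#'   feature-plex block (default 3; blocks with more are dropped).
#' @param remove_shared_features drop features shared across protein groups.
#' @param global_median_normalization equalize channel medians (OnePot only).
#' @param imputation_enabled impute missing channels before median polish.
#' @return a [ProcessingConfig-class].
#' @export
processingConfig <- function(
    normset_bounds = data.frame(temperature_index = c(6L, 8L, 9L),
                                lower = 0, upper = c(0.6, 0.3, 0.2)),
    msstats_min_features = 2,
    msstats_max_missing_per_plex = 3,
    remove_shared_features = TRUE,
    global_median_normalization = FALSE,
    imputation_enabled = TRUE) {
  new("ProcessingConfig", normset_bounds = normset_bounds,
      msstats_min_features = msstats_min_features,
      msstats_max_missing_per_plex = msstats_max_missing_per_plex,
      remove_shared_features = remove_shared_features,
      global_median_normalization = global_median_normalization,
      imputation_enabled = imputation_enabled)
}

# ---- TPP/NPARC protocol -----------------------------------------------------

#' Normalize each profile to its reference-channel abundance
#'
#' Divides every abundance by the abundance of the same
#' (protein, condition, replicate) group at temperature index 0, placing all
#' thermal profiles on a common relative scale. Groups whose reference value
#' is missing or non-positive cannot be ratioed; they are excluded and
#' reported in the `dropped` attribute.
#'
#' @param table raw-scale [ProteinProfileTable-class].
#' @return ratio-scale [ProteinProfileTable-class] with attribute `dropped`
#'   (data.frame of excluded groups).
#' @export
ratioToReference <- function(table) {
  stopifnot(is(table, "ProteinProfileTable"))
  if (tableScale(table) != "raw")
    stop("ratioToReference expects a raw-scale table")
  d <- profileData(table)
  grp <- paste(d$protein, d$condition, d$replicate, sep = "\r")
  ref <- d$abundance[d$temperature_index == 0L]
  names(ref) <- grp[d$temperature_index == 0L]
  refv <- ref[grp]
  ok <- !is.na(refv) & refv > 0
  dropped <- unique(d[!ok, c("protein", "condition", "replicate")])
  d <- d[ok, , drop = FALSE]
  d$abundance <- d$abundance / refv[ok]
  d$abundance[d$temperature_index == 0L] <- 1
  out <- proteinProfileTable(d, scale = "ratio")
  attr(out, "dropped") <- dropped
  out
}

#' Select the normalization set of canonically melting proteins
#'
#' Keeps proteins whose reference ratios at the configured temperature
#' indices fall within the configured bounds in every
#' (condition, replicate) group, and which are present (all configured
#' indices observed) in all groups. The result is used for deriving
#' normalization factors only, never as a permanent protein filter.
#'
#' @param ratios ratio-scale [ProteinProfileTable-class].
#' @param config a [ProcessingConfig-class].
#' @return character vector of protein ids.
#' @export
buildNormSet <- function(ratios, config = processingConfig()) {
  stopifnot(is(ratios, "ProteinProfileTable"))
  if (tableScale(ratios) != "ratio")
    stop("buildNormSet expects a ratio-scale table")
  b <- config@normset_bounds
  d <- profileData(ratios)
  groups <- unique(d[, c("condition", "replicate")])
  n_groups <- nrow(groups)
  sub <- d[d$temperature_index %in% b$temperature_index, , drop = FALSE]
  lo <- b$lower[match(sub$temperature_index, b$temperature_index)]
  hi <- b$upper[match(sub$temperature_index, b$temperature_index)]
  sub$pass <- !is.na(sub$abundance) & sub$abundance >= lo & sub$abundance <= hi
  cnt <- stats::aggregate(list(n_rows = sub$temperature_index),
                          by = list(protein = sub$protein), FUN = length)
  passed <- stats::aggregate(list(n_pass = as.integer(sub$pass)),
                             by = list(protein = sub$protein), FUN = sum)
  need <- n_groups * nrow(b)
  tab <- merge(cnt, passed, by = "protein")
  keep <- tab$protein[tab$n_rows == need & tab$n_pass == need]
  if (!length(keep))
    stop("empty NormSet: no protein satisfies the ratio bounds in every ",
         "group; relax the bounds in processingConfig()")
  sort(keep)
}

#' Derive per-temperature normalization factors from the NormSet
#'
#' Computes, per (condition, replicate), the median ratio profile over the
#' NormSet proteins; fits a sigmoid to each median profile; picks the profile
#' with maximal R-squared (ties broken by condition then replicate order);
#' and returns factors \eqn{Q_t} = fitted/median for that profile, with the
#' factor at index 0 forced to 1.
#'
#' @param ratios ratio-scale [ProteinProfileTable-class].
#' @param normset protein ids from [buildNormSet()].
#' @return a [NormFactors-class].
#' @export
computeNormFactors <- function(ratios, normset) {
  stopifnot(is(ratios, "ProteinProfileTable"))
  d <- profileData(ratios)
  d <- d[d$protein %in% normset, , drop = FALSE]
  if (!nrow(d)) stop("normset proteins not found in the table")
  med <- stats::aggregate(
    list(med = d$abundance),
    by = list(condition = d$condition, replicate = d$replicate,
              temperature_index = d$temperature_index,
              temperature = d$temperature),
    FUN = stats::median)
  groups <- unique(med[, c("condition", "replicate")])
  groups <- groups[order(groups$condition, groups$replicate), , drop = FALSE]
  fits <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- med[med$condition == groups$condition[i] &
               med$replicate == groups$replicate[i], , drop = FALSE]
    if (length(unique(g$temperature_index)) < 5) {
      fits[[i]] <- NULL
      next
    }
    fits[[i]] <- fitSigmoid(g$temperature, g$med)
  }
  r2 <- vapply(fits, function(f)
    if (is.null(f) || !f@converged) -Inf else f@r2, numeric(1))
  if (all(!is.finite(r2)))
    stop("normalization factors unavailable: no sigmoid fit converged")
  best <- which.max(r2)   # first max wins: condition then replicate order
  g <- med[med$condition == groups$condition[best] &
             med$replicate == groups$replicate[best], , drop = FALSE]
  g <- g[order(g$temperature_index), ]
  fv <- .sigmoid_eval(g$temperature, fits[[best]]@p, fits[[best]]@a,
                      fits[[best]]@b)
  Q <- fv / g$med
  names(Q) <- g$temperature_index
  Q["0"] <- 1
  if (any(!is.finite(Q)) || any(Q <= 0))
    stop("normalization factors unavailable: non-positive or non-finite Q_t")
  new("NormFactors", Q = Q, condition = groups$condition[best],
      replicate = groups$replicate[best], normset = as.character(normset),
      fit_r2 = fits[[best]]@r2)
}

#' Apply per-temperature normalization factors
#'
#' Multiplies every ratio by the factor for its temperature index. Reference
#' entries stay exactly 1 because the factor at index 0 is 1.
#'
#' @param ratios ratio-scale [ProteinProfileTable-class].
#' @param factors a [NormFactors-class].
#' @return normalized ratio-scale [ProteinProfileTable-class].
#' @export
applyNormFactors <- function(ratios, factors) {
  stopifnot(is(ratios, "ProteinProfileTable"), is(factors, "NormFactors"))
  d <- profileData(ratios)
  q <- factors@Q[as.character(d$temperature_index)]
  if (any(is.na(q)))
    stop("missing Q_t for temperature index(es): ",
         paste(unique(d$temperature_index[is.na(q)]), collapse = ", "))
  d$abundance <- d$abundance * unname(q)
  proteinProfileTable(d, scale = tableScale(ratios))
}

#' Run the full TPP/NPARC processing protocol
#'
#' Reference ratios, NormSet selection, sigmoid-derived factors, and factor
#' application, in that order.
#'
#' @param table raw-scale [ProteinProfileTable-class].
#' @param config a [ProcessingConfig-class].
#' @return normalized ratio-scale [ProteinProfileTable-class]; attributes
#'   `norm_factors` (the [NormFactors-class]) and `dropped`.
#' @export
tppProcess <- function(table, config = processingConfig()) {
  ratios <- ratioToReference(table)
  normset <- buildNormSet(ratios, config)
  factors <- computeNormFactors(ratios, normset)
  out <- applyNormFactors(ratios, factors)
  attr(out, "norm_factors") <- factors
  attr(out, "dropped") <- attr(ratios, "dropped")
  out
}

# ---- shared helpers ---------------------------------------------------------

#' Log2-transform a table
#'
#' Elementwise log2; missing values stay missing; non-positive values are an
#' error naming the offending keys.
#'
#' @param table raw-scale [ProteinProfileTable-class] or [FeatureTable-class].
#' @return the same class of table on log2 scale.
#' @export
log2Transform <- function(table) {
  if (is(table, "ProteinProfileTable")) {
    if (tableScale(table) != "raw") stop("log2Transform expects a raw-scale table")
    d <- profileData(table)
    bad <- !is.na(d$abundance) & d$abundance <= 0
    if (any(bad))
      stop("non-positive abundance for key(s): ",
           paste(utils::head(paste(d$protein, d$condition, d$replicate,
                                   d$temperature_index)[bad], 5),
                 collapse = "; "))
    d$abundance <- log2(d$abundance)
    proteinProfileTable(d, scale = "log2")
  } else if (is(table, "FeatureTable")) {
    if (tableScale(table) != "raw") stop("log2Transform expects a raw-scale table")
    d <- featureData(table)
    bad <- !is.na(d$intensity) & d$intensity <= 0
    if (any(bad))
      stop("non-positive intensity for key(s): ",
           paste(utils::head(paste(d$protein, d$feature, d$condition,
                                   d$replicate, d$temperature_index)[bad], 5),
                 collapse = "; "))
    d$intensity <- log2(d$intensity)
    featureTable(d, scale = "log2")
  } else stop("unsupported table class")
}

#' Global median normalization across channels
#'
#' Shifts each channel (plex x condition x replicate x temperature column) so
#' that its median equals the grand median of all channel medians. Appropriate
#' for OnePot group-comparison designs only: thermal profiles decay across
#' channels by design, so equalizing their medians distorts melting curves.
#'
#' @param table log2-scale [ProteinProfileTable-class] or
#'   [FeatureTable-class].
#' @return normalized log2-scale table of the same class.
#' @export
globalMedianNormalize <- function(table) {
  if (tableScale(table) != "log2")
    stop("globalMedianNormalize expects a log2-scale table")
  if (is(table, "ProteinProfileTable")) {
    d <- profileData(table)
    ch <- paste(d$condition, d$replicate, d$temperature_index, sep = "\r")
    meds <- tapply(d$abundance, ch, stats::median, na.rm = TRUE)
    d$abundance <- d$abundance - unname(meds[ch]) + stats::median(meds)
    proteinProfileTable(d, scale = "log2")
  } else if (is(table, "FeatureTable")) {
    d <- featureData(table)
    ch <- paste(d$plex, d$condition, d$replicate, d$temperature_index,
                sep = "\r")
    meds <- tapply(d$intensity, ch, stats::median, na.rm = TRUE)
    d$intensity <- d$intensity - unname(meds[ch]) + stats::median(meds)
    featureTable(d, scale = "log2")
  } else stop("unsupported table class")
}
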