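#' @include AllClasses.R study_io.R processing.R
NULL

#' Feature-level filtering for protein summarization
#'
#' Applies, in order: (a) removal of features shared across protein groups;
#' (b) removal of feature-plex blocks with more than
#' `msstats_max_missing_per_plex` missing channel intensities (the default 3
#' keeps a block with exactly 3 missing channels); (c) removal of proteins
#' left with fewer than `msstats_min_features` distinct features. An empty
#' result is allowed and reported.
#'
#' @param features a [FeatureTable-class].
#' @param config a [ProcessingConfig-class].
#' @return the filtered [FeatureTable-class] with attribute `filter_report`,
#'   a data.frame(step, entity, count_removed).
#' @export
msstatsFilter <- function(features, config = processingConfig()) {
  stopifnot(is(features, "FeatureTable"))
  d <- featureData(features)
  report <- data.frame(step = character(), entity = character(),
                       count_removed = integer())
  # (a) shared features
  if (config@remove_shared_features) {
    shared_keys <- unique(d[d$shared, c("protein", "feature")])
    d <- d[!d$shared, , drop = FALSE]
    report <- rbind(report, data.frame(step = "shared_features",
                                       entity = "feature",
                                       count_removed = nrow(shared_keys)))
  }
  # (b) feature-plex blocks with too many missing channels
  blk <- paste(d$protein, d$feature, d$plex, sep = "\r")
  n_missing <- tapply(is.na(d$intensity), blk, sum)
  bad_blocks <- names(n_missing)[n_missing > config@msstats_max_missing_per_plex]
  d <- d[!blk %in% bad_blocks, , drop = FALSE]
  report <- rbind(report, data.frame(step = "missing_channels",
                                     entity = "feature_plex_block",
                                     count_removed = length(bad_blocks)))
  # (c) proteins with too few features
  nfeat <- tapply(d$feature, d$protein, function(f) length(unique(f)))
  bad_prot <- names(nfeat)[nfeat < config@msstats_min_features]
  d <- d[!d$protein %in% bad_prot, , drop = FALSE]
  report <- rbind(report, data.frame(step = "single_feature_proteins",
                                     entity = "protein",
                                     count_removed = length(bad_prot)))
  out <- featureTable(d, scale = tableScale(features))
  attr(out, "filter_report") <- report
  out
}

#' Impute missing channel intensities with a censored regression
#'
#' Within each protein-plex block, missing channel intensities are treated as
#' left-censored at the block's minimum observed log2 intensity and modeled
#' with an accelerated-failure-time regression (Gaussian location-scale on
#' the log2 scale) with additive feature and channel effects. Missing cells
#' are replaced by the model predictions and flagged `imputed`; observed
#' entries are never modified. Features with fewer than 2 observed values are
#' left unimputed; all-missing features are skipped and reported.
#'
#' @param features filtered log2-scale [FeatureTable-class].
#' @return a [FeatureTable-class] with imputed values flagged; attribute
#'   `impute_report` lists skipped features.
#' @export
aftImpute <- function(features) {
  stopifnot(is(features, "FeatureTable"))
  if (tableScale(features) != "log2")
    stop("aftImpute expects a log2-scale feature table")
  d <- featureData(features)
  d$.row <- seq_len(nrow(d))
  skipped <- data.frame(protein = character(), plex = character(),
                        feature = character(), reason = character())
  for (key in unique(paste(d$protein, d$plex, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    blk <- d[d$protein == parts[1] & d$plex == parts[2], , drop = FALSE]
    if (!anyNA(blk$intensity)) next
    n_obs_feat <- tapply(!is.na(blk$intensity), blk$feature, sum)
    dead <- names(n_obs_feat)[n_obs_feat == 0]
    thin <- names(n_obs_feat)[n_obs_feat > 0 & n_obs_feat < 2]
    if (length(dead))
      skipped <- rbind(skipped, data.frame(protein = parts[1], plex = parts[2],
                                           feature = dead,
                                           reason = "all_missing"))
    if (length(thin))
      skipped <- rbind(skipped, data.frame(protein = parts[1], plex = parts[2],
                                           feature = thin,
                                           reason = "too_few_observed"))
    blk <- blk[!blk$feature %in% c(dead, thin), , drop = FALSE]
    if (!nrow(blk) || !anyNA(blk$intensity)) next
    thr <- min(blk$intensity, na.rm = TRUE)
    mf <- data.frame(
      feature = factor(blk$feature),
      channel = factor(paste(blk$condition, blk$replicate,
                             blk$temperature_index, sep = "\r")),
      y = blk$intensity)
    obs <- !is.na(mf$y)
    pred <- .aft_predict(mf, obs, thr)
    fill <- which(!obs & !is.na(pred))
    d$intensity[blk$.row[fill]] <- pred[fill]
    d$imputed[blk$.row[fill]] <- TRUE
  }
  d$.row <- NULL
  out <- featureTable(d, scale = "log2")
  attr(out, "impute_report") <- skipped
  out
}

# Censored Gaussian AFT fit with additive feature + channel effects; falls
# back to an OLS additive fit capped at the censoring threshold when the
# censored fit degenerates (e.g. residual scale collapsing to zero).
.aft_predict <- function(mf, obs, thr) {
  mf$time <- ifelse(obs, mf$y, thr)
  mf$status <- as.integer(obs)
  converged <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      survival::survreg(
        survival::Surv(time, status, type = "left") ~ feature + channel,
        data = mf, dist = "gaussian"),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  pred <- if (!is.null(fit) && converged && all(is.finite(stats::coef(fit))))
    tryCatch(suppressWarnings(stats::predict(fit, newdata = mf)),
             error = function(e) rep(NA_real_, nrow(mf)))
  else rep(NA_real_, nrow(mf))
  if (anyNA(pred[!obs])) {
    ols <- tryCatch(stats::lm(y ~ feature + channel, data = mf[obs, ]),
                    error = function(e) NULL)
    if (!is.null(ols)) {
      alt <- tryCatch(suppressWarnings(stats::predict(ols, newdata = mf)),
                      error = function(e) rep(NA_real_, nrow(mf)))
      pred[is.na(pred)] <- pmin(alt[is.na(pred)], thr)
    }
  }
  pred
}

# Tukey median polish, rows-first, convergence on the change in total
# absolute residual (< tol), capped at maxiter sweeps. NA cells are excluded
# from each median.
.median_polish <- function(x, tol = 1e-6, maxiter = 100) {
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  z <- x
  oldsum <- 0
  for (iter in seq_len(maxiter)) {
    rd <- apply(z, 1, stats::median, na.rm = TRUE)
    rd[is.na(rd)] <- 0
    z <- z - rd
    row_eff <- row_eff + rd
    delta <- stats::median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cd <- apply(z, 2, stats::median, na.rm = TRUE)
    cd[is.na(cd)] <- 0
    z <- sweep(z, 2, cd)
    col_eff <- col_eff + cd
    delta <- stats::median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(z), na.rm = TRUE)
    if (newsum == 0 || abs(newsum - oldsum) < tol) break
    oldsum <- newsum
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = z)
}

#' Summarize features into protein-level abundances by median polish
#'
#' Per protein and plex, fits an additive Tukey median polish (rows first,
#' tolerance 1e-6 on the change in total absolute residual, at most 100
#' sweeps) to the feature x channel matrix of log2 intensities (observed and
#' imputed). The protein abundance for a channel is the overall effect plus
#' that channel's column effect. Cells still missing are excluded from each
#' median. Empty matrices are skipped and reported.
#'
#' @param features log2-scale [FeatureTable-class] (after [msstatsFilter()]
#'   and, typically, [aftImpute()]).
#' @return a log2-scale [ProteinProfileTable-class]; attribute `skipped`
#'   names protein-plex blocks with no usable data.
#' @export
medianPolishSummarize <- function(features) {
  stopifnot(is(features, "FeatureTable"))
  if (tableScale(features) != "log2")
    stop("medianPolishSummarize expects a log2-scale feature table")
  d <- featureData(features)
  out <- list()
  skipped <- character()
  for (key in unique(paste(d$protein, d$plex, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    blk <- d[d$protein == parts[1] & d$plex == parts[2], , drop = FALSE]
    ch <- unique(blk[, c("condition", "replicate", "temperature_index",
                         "temperature")])
    ch <- ch[order(ch$condition, ch$replicate, ch$temperature_index), ,
             drop = FALSE]
    ch_key <- paste(ch$condition, ch$replicate, ch$temperature_index,
                    sep = "\r")
    feats <- unique(blk$feature)
    m <- matrix(NA_real_, length(feats), length(ch_key),
                dimnames = list(feats, ch_key))
    m[cbind(match(blk$feature, feats),
            match(paste(blk$condition, blk$replicate, blk$temperature_index,
                        sep = "\r"), ch_key))] <- blk$intensity
    if (all(is.na(m))) {
      skipped <- c(skipped, key)
      next
    }
    mp <- .median_polish(m)
    out[[key]] <- data.frame(
      protein = parts[1], condition = ch$condition, replicate = ch$replicate,
      temperature_index = ch$temperature_index, temperature = ch$temperature,
      abundance = mp$overall + mp$col, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no protein-plex block could be summarized")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tab <- proteinProfileTable(res, scale = "log2")
  attr(tab, "skipped") <- skipped
  tab
}

#' Align plexes on their reference-channel abundance
#'
#' Per protein, additively shifts each plex profile so its reference
#' (temperature index 0) value equals the cross-plex median of reference
#' values. Single-plex profiles are returned unchanged; plexes lacking a
#' reference value for a protein are left unshifted and reported. The
#' operation is idempotent.
#'
#' @param proteins log2-scale [ProteinProfileTable-class]. Plex membership is
#'   taken from `design` when supplied, else each (condition, replicate)
#'   group is treated as one plex (the one-plex-per-replicate layout).
#' @param design optional [StudyDesign-class].
#' @return shifted log2-scale table; attribute `unshifted` lists
#'   (protein, plex) groups without a reference value.
#' @export
referenceChannelNormalize <- function(proteins, design = NULL) {
  stopifnot(is(proteins, "ProteinProfileTable"))
  if (tableScale(proteins) != "log2")
    stop("referenceChannelNormalize expects a log2-scale table")
  d <- profileData(proteins)
  if (!is.null(design)) {
    ch <- designChannels(design)
    key <- paste(ch$condition, ch$replicate, ch$temperature_index)
    d$.plex <- ch$plex[match(paste(d$condition, d$replicate,
                                   d$temperature_index), key)]
  } else {
    d$.plex <- paste(d$condition, d$replicate, sep = "\r")
  }
  unshifted <- data.frame(protein = character(), plex = character())
  for (p in unique(d$protein)) {
    rows <- which(d$protein == p)
    sub <- d[rows, , drop = FALSE]
    refs <- tapply(sub$abundance[sub$temperature_index == 0L],
                   sub$.plex[sub$temperature_index == 0L], function(x) x[1])
    plexes <- unique(sub$.plex)
    have <- plexes %in% names(refs) & !is.na(refs[plexes])
    if (any(!have))
      unshifted <- rbind(unshifted,
                         data.frame(protein = p, plex = plexes[!have]))
    if (sum(have) < 2) next
    target <- stats::median(refs[plexes[have]])
    shift <- target - refs[sub$.plex]
    shift[is.na(shift)] <- 0
    d$abundance[rows] <- sub$abundance + unname(shift)
  }
  d$.plex <- NULL
  out <- proteinProfileTable(d, scale = "log2")
  attr(out, "unshifted") <- unshifted
  out
}

#' Run the full feature-to-protein processing protocol
#'
#' Log2 transform (when raw), optional global median normalization (OnePot
#' only), feature filtering, censored-regression imputation, median-polish
#' summarization, and reference-channel alignment across plexes.
#'
#' @param features a [FeatureTable-class] (raw or log2 scale).
#' @param design optional [StudyDesign-class] for plex mapping.
#' @param config a [ProcessingConfig-class].
#' @return log2-scale [ProteinProfileTable-class]; attributes carry the
#'   filter and imputation reports.
#' @export
msstatsProcess <- function(features, design = NULL,
                           config = processingConfig()) {
  if (tableScale(features) == "raw") features <- log2Transform(features)
  if (config@global_median_normalization)
    features <- globalMedianNormalize(features)
  features <- msstatsFilter(features, config)
  freport <- attr(features, "filter_report")
  ireport <- NULL
  if (config@imputation_enabled) {
    features <- aftImpute(features)
    ireport <- attr(features, "impute_report")
  }
  out <- medianPolishSummarize(features)
  has_ref <- any(profileData(out)$temperature_index == 0L)
  if (has_ref) out <- referenceChannelNormalize(out, design)
  attr(out, "filter_report") <- freport
  attr(out, "impute_report") <- ireport
  out
}
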