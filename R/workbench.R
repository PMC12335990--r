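#' @include AllClasses.R study_io.R processing.R msstats_processing.R
#' @include sigmoid.R spline.R scam.R mixed.R inference.R simulator.R
#' @include evaluation.R
NULL

ALL_MODELS <- c("tpp_spline", "tpp_sigmoid", "nparc", "scam",
                "msstats_mixed", "onepot_anova")

# scale bridges: curve models assume relative (ratio) abundances; the mixed
# and SCAM models work on the log2 scale.
.toRatioScale <- function(table) {
  if (tableScale(table) == "ratio") return(table)
  if (tableScale(table) == "log2") {
    d <- profileData(table)
    d$abundance <- 2^d$abundance
    table <- proteinProfileTable(d, scale = "raw")
  }
  ratioToReference(table)
}

.toLog2Scale <- function(table) {
  if (tableScale(table) == "log2") return(table)
  d <- profileData(table)
  if (any(d$abundance <= 0, na.rm = TRUE))
    stop("cannot log2-transform non-positive abundances")
  d$abundance <- log2(d$abundance)
  proteinProfileTable(d, scale = "log2")
}

#' Run the selected per-protein models on a processed table
#'
#' Dispatches each protein profile to the selected statistical models,
#' applying the scale each model assumes (curve models are fed relative
#' abundances, the mixed and SCAM models log2 values; conversions are
#' recorded in the returned provenance), pools the across-protein
#' empirical-Bayes steps (spline moderation, sigmoid degrees-of-freedom
#' rescaling), applies BH adjustment per model, and thresholds decisions at
#' the FDR cutoff.
#'
#' @param table a processed [ProteinProfileTable-class].
#' @param models subset of `tpp_spline`, `tpp_sigmoid`, `nparc`, `scam`,
#'   `msstats_mixed`, `onepot_anova`.
#' @param subset temperature-index subset for the mixed-model contrast
#'   (default `c(6, 7, 8)`).
#' @param spline_df spline degrees of freedom (default 5).
#' @param scam_k SCAM basis size (default 5).
#' @param fdr FDR cutoff for decisions (default 0.05).
#' @param drop_reference discard temperature index 0 in the mixed model
#'   (TRUE for experimental tables with a reference channel; FALSE for
#'   simulated tables where index 0 is a real measurement).
#' @return data.frame of [testResult()] rows; attribute `provenance` lists
#'   scale conversions and pooled moderation parameters.
#' @export
analyzeProfiles <- function(table, models = c("msstats_mixed"),
                            subset = c(6L, 7L, 8L), spline_df = 5,
                            scam_k = 5, fdr = 0.05, drop_reference = TRUE) {
  models <- match.arg(models, ALL_MODELS, several.ok = TRUE)
  prov <- list(models = models, fdr = fdr, subset = as.integer(subset))
  rows <- list()
  ratio_tab <- NULL
  log2_tab <- NULL
  if (any(models %in% c("tpp_spline", "tpp_sigmoid", "nparc"))) {
    ratio_tab <- .toRatioScale(table)
    prov$ratio_conversion <- tableScale(table) != "ratio"
  }
  if (any(models %in% c("scam", "msstats_mixed"))) {
    log2_tab <- .toLog2Scale(table)
    prov$log2_conversion <- tableScale(table) != "log2"
  }
  split_by_protein <- function(tab) split(profileData(tab),
                                          profileData(tab)$protein)
  if ("msstats_mixed" %in% models) {
    for (sub in split_by_protein(log2_tab)) {
      pid <- sub$protein[1]
      res <- tryCatch({
        fit <- fitMixed(sub, drop_reference = drop_reference)
        mixedContrastTest(fit, subset, protein_id = pid)
      }, error = function(e) testResult(pid, "msstats_mixed",
                                        decision = "failed"))
      rows[[length(rows) + 1]] <- res
    }
  }
  if ("scam" %in% models) {
    for (sub in split_by_protein(log2_tab)) {
      pid <- sub$protein[1]
      sub$value <- sub$abundance
      res <- tryCatch(scamDimTest(fitScam(sub, k = scam_k), protein_id = pid),
                      error = function(e) testResult(pid, "scam",
                                                     decision = "failed"))
      rows[[length(rows) + 1]] <- res
    }
  }
  if ("tpp_spline" %in% models) {
    fits <- list()
    for (sub in split_by_protein(ratio_tab)) {
      sub$value <- sub$abundance
      fits[[sub$protein[1]]] <- tryCatch(fitSplinePair(sub, d = spline_df),
                                         error = function(e) NULL)
    }
    ok <- !vapply(fits, is.null, logical(1))
    s_sq <- vapply(fits[ok], function(f) f$rss1 / f$df2, numeric(1))
    df2s <- vapply(fits[ok], function(f) f$df2, numeric(1))
    params <- if (sum(ok) >= 10)
      tryCatch(estimateModeration(s_sq, df2 = stats::median(df2s)),
               error = function(e) list(d0 = 0, s0_sq = NA_real_))
    else list(d0 = 0, s0_sq = NA_real_)
    prov$spline_moderation <- params
    for (pid in names(fits)) {
      f <- fits[[pid]]
      if (is.null(f)) {
        rows[[length(rows) + 1]] <- testResult(pid, "tpp_spline",
                                               decision = "failed")
        next
      }
      mf <- moderatedF(f$rss0, f$rss1, f$df1, f$df2, params)
      rows[[length(rows) + 1]] <- testResult(
        pid, "tpp_spline", statistic = mf$statistic, df1 = f$df1,
        df2 = params$d0 + f$df2, pvalue = mf$pvalue, n_obs = f$n_obs)
    }
  }
  if ("nparc" %in% models) {
    fits <- list()
    for (sub in split_by_protein(ratio_tab)) {
      sub$value <- sub$abundance
      fits[[sub$protein[1]]] <- tryCatch(fitSigmoidPair(sub),
                                         error = function(e) NULL)
    }
    ok <- !vapply(fits, is.null, logical(1))
    keep <- nparcPostfilter(lapply(fits[ok], `[[`, "full"))
    kept_ids <- names(keep)[keep]
    if (length(kept_ids) >= 2) {
      delta <- vapply(fits[kept_ids], function(f) f$rss0 - f$rss1, numeric(1))
      rss1 <- vapply(fits[kept_ids], function(f) f$rss1, numeric(1))
      eb <- suppressWarnings(nparcEbInference(delta, rss1))
      prov$nparc_eb <- eb$params
      for (i in seq_along(kept_ids)) {
        f <- fits[[kept_ids[i]]]
        rows[[length(rows) + 1]] <- testResult(
          kept_ids[i], "nparc", statistic = eb$statistic[i],
          df1 = eb$params$d1, df2 = eb$params$d2, pvalue = eb$pvalue[i],
          n_obs = f$n_obs)
      }
    }
    for (pid in setdiff(names(fits)[ok], kept_ids))
      rows[[length(rows) + 1]] <- testResult(pid, "nparc",
                                             decision = "filtered",
                                             n_obs = fits[[pid]]$n_obs)
    for (pid in names(fits)[!ok])
      rows[[length(rows) + 1]] <- testResult(pid, "nparc",
                                             decision = "failed")
  }
  if ("tpp_sigmoid" %in% models) {
    for (sub in split_by_protein(ratio_tab)) {
      pid <- sub$protein[1]
      reps <- intersect(unique(sub$replicate[sub$condition == "vehicle"]),
                        unique(sub$replicate[sub$condition == "treated"]))
      rep_p <- rep_dtm <- rep_r2 <- plateaus <- numeric(0)
      for (r in reps) {
        rsub <- sub[sub$replicate == r, ]
        rsub$value <- rsub$abundance
        pr <- tryCatch(fitSigmoidPair(rsub), error = function(e) NULL)
        if (is.null(pr)) next
        ft <- fStatistic(pr$rss0, pr$rss1, pr$df1, pr$df2)
        tms <- vapply(pr$full, function(f) f@tm, numeric(1))
        rep_p <- c(rep_p, ft$pvalue)
        rep_dtm <- c(rep_dtm, tms["treated"] - tms["vehicle"])
        rep_r2 <- c(rep_r2, max(vapply(pr$full, function(f) f@r2,
                                       numeric(1))))
        plateaus <- c(plateaus, vapply(pr$full, function(f) f@p, numeric(1)))
      }
      decision <- if (length(rep_p) >= 2)
        tppSigmoidDecision(rep_dtm, rep_p, rep_r2, plateaus)
      else "failed"
      rows[[length(rows) + 1]] <- testResult(
        pid, "tpp_sigmoid",
        pvalue = if (length(rep_p)) max(rep_p) else NA_real_,
        estimate = if (length(rep_dtm)) mean(rep_dtm) else NA_real_,
        decision = decision, n_obs = nrow(sub))
    }
  }
  if ("onepot_anova" %in% models)
    rows[[length(rows) + 1]] <- anovaGroupComparison(.toLog2Scale(table))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # BH within model; FDR decisions where not already decided
  for (mdl in unique(out$model)) {
    sel <- out$model == mdl & !is.na(out$pvalue)
    if (any(sel)) out$qvalue[sel] <- bhAdjust(out$pvalue[sel])
    open <- sel & is.na(out$decision)
    out$decision[open] <- ifelse(out$qvalue[open] < fdr, "interactor",
                                 "non-interactor")
  }
  attr(out, "provenance") <- prov
  out
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys `input`, `design`, `level`,
#'   `processing` (`tpp` or `msstats`), `models`, `subset`, `fdr`,
#'   `output_dir`, `seed`, and optional `columns` remapping.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$models) || !length(cfg$models))
    stop("config must select at least one model")
  cfg$models <- unlist(cfg$models)
  if (is.null(cfg$fdr)) cfg$fdr <- 0.05
  if (is.null(cfg$subset)) cfg$subset <- c(6L, 7L, 8L)
  cfg$subset <- as.integer(unlist(cfg$subset))
  cfg
}

#' Run a full processing + inference analysis
#'
#' Reads the quantification and design files, runs the selected processing
#' protocol, analyzes with the selected models, writes the results CSV and a
#' provenance JSON (configuration, seed, moderation parameters, filter
#' report) that suffices to reproduce the run.
#'
#' @param config list as returned by [readRunConfig()], or a path to a YAML
#'   file.
#' @return the results data.frame, invisibly; files are written to
#'   `config$output_dir`.
#' @export
runAnalysis <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  design <- readDesign(config$design)
  level <- if (is.null(config$level)) "feature" else config$level
  columns <- if (is.null(config$columns)) character()
  else unlist(config$columns)
  tab <- readQuantTable(config$input, level = level, design = design,
                        columns = columns)
  pconf <- processingConfig(
    global_median_normalization = isTRUE(config$global_median_normalization))
  processed <- if (identical(config$processing, "tpp")) {
    if (level == "feature")
      stop("tpp processing expects a protein-level input table")
    tppProcess(tab, pconf)
  } else {
    if (level == "feature") msstatsProcess(tab, design, pconf)
    else stop("msstats processing expects a feature-level input table")
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  results <- analyzeProfiles(processed, models = config$models,
                             subset = config$subset, fdr = config$fdr)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    writeResults(results, file.path(config$output_dir, "results.csv"))
    prov <- attr(results, "provenance")
    prov$config <- config
    freport <- attr(processed, "filter_report")
    if (!is.null(freport)) {
      utils::write.csv(freport,
                       file.path(config$output_dir, "filter_report.csv"),
                       row.names = FALSE)
      prov$filter_report <- freport
    }
    jsonlite::write_json(prov, file.path(config$output_dir,
                                         "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(results)
}

# deterministic per-cell seed; primes keep instance substreams of different
# cells disjoint for any n_instances <= 100003
.cell_seed <- function(seed, cell_index) {
  as.integer((seed + cell_index * 100003) %% .Machine$integer.max)
}

#' Simulate and analyze a grid of templates, designs, and ICC levels
#'
#' For every combination of template kind, named design, and biological
#' variance, simulates `n_instances` protein instances and analyzes them
#' with the design-appropriate model: the mixed-effects subset contrast for
#' thermal designs (fitting the design's temperature subset, testing its
#' null subset), or the OnePot group-comparison ANOVA. Returns the long
#' table of per-instance p-values plus power and calibration summaries.
#'
#' @param templates character subset of `c("strong", "weak", "null")`.
#' @param designs character vector of [designCatalog()] names.
#' @param sigma_bio_sq biological variances to scan (default
#'   `c(0.014, 0.178)`, i.e. ICC 5% and 40%).
#' @param sigma_error_sq technological variance (default 0.267).
#' @param n_instances instances per cell (default 1000).
#' @param seed integer seed; each cell derives a deterministic subseed.
#' @param cutoffs significance cutoffs for the summaries.
#' @return list with `results` (template, design, icc, instance, pvalue),
#'   `power` ([powerTable()]), and `calibration` (per null-template cell,
#'   [summarizePvalues()]).
#' @export
runSimulationStudy <- function(templates = c("strong", "weak", "null"),
                               designs = c("T-D", "T-F", "T-G"),
                               sigma_bio_sq = c(0.014, 0.178),
                               sigma_error_sq = 0.267, n_instances = 1000,
                               seed, cutoffs = c(0.001, 0.05)) {
  catalog <- designCatalog()
  if (!all(designs %in% names(catalog)))
    stop("unknown design name(s): ",
         paste(setdiff(designs, names(catalog)), collapse = ", "))
  grid <- expand.grid(template = templates, design = designs,
                      sb = sigma_bio_sq, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    des <- catalog[[grid$design[i]]]
    tmpl <- makeTemplate(grid$template[i])
    cfg <- simConfig(grid$sb[i], sigma_error_sq, n_instances,
                     seed = .cell_seed(seed, i), design = des)
    pv <- if (des@mode == "thermal")
      .simulate_and_test_thermal(tmpl, cfg)
    else .simulate_and_test_onepot(tmpl, cfg)
    out[[i]] <- data.frame(
      template = grid$template[i], design = grid$design[i],
      icc = icc(grid$sb[i], sigma_error_sq),
      instance = seq_along(pv), pvalue = pv, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, out)
  calib <- list()
  nulls <- results[results$template == "null", , drop = FALSE]
  for (key in unique(paste(nulls$design, nulls$icc))) {
    sel <- paste(nulls$design, nulls$icc) == key
    calib[[key]] <- summarizePvalues(nulls$pvalue[sel], cutoffs)
  }
  list(results = results, power = powerTable(results, cutoffs),
       calibration = calib)
}

.simulate_and_test_thermal <- function(template, config) {
  des <- config@design
  vapply(seq_len(config@n_instances), function(i) {
    d <- .simulate_instance(template, config, i)
    d <- d[d$temperature_index %in% des@temperatures_fit, , drop = FALSE]
    fit <- fitMixed(d, drop_reference = FALSE)
    res <- mixedContrastTest(fit, des@temperatures_test)
    res$pvalue
  }, numeric(1))
}

.simulate_and_test_onepot <- function(template, config) {
  tabs <- simulateOnepot(template, config)
  all <- do.call(rbind, lapply(tabs, profileData))
  tab <- proteinProfileTable(all, scale = "log2")
  res <- anovaGroupComparison(tab,
                              comparisons = list(c("treated", "vehicle")))
  res <- res[order(res$protein_id), ]
  res$pvalue
}
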