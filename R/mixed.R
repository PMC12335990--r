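#' @include AllClasses.R study_io.R
NULL

# order conditions vehicle-first when the canonical labels are used
.cond_levels <- function(conds) {
  if (all(c("vehicle", "treated") %in% conds))
    c("vehicle", "treated")
  else sort(conds)
}

#' Fit the mixed-effects cell-means model for one protein
#'
#' Models log2 abundances as \eqn{Y_{crt} = \mu_{ct} + b_{cr} +
#' \varepsilon_{crt}} with a fixed mean per condition x temperature cell, a
#' biological-replicate random intercept \eqn{b \sim N(0, \sigma^2_{bio})},
#' and residual \eqn{\varepsilon \sim N(0, \sigma^2_{error})}. The reference
#' channel (temperature index 0) is discarded before fitting. For balanced
#' complete data the REML solution is closed-form via the ANOVA
#' decomposition (between-replicate and residual mean squares, which the
#' fit retains untruncated for contrast-variance estimation); otherwise the
#' model is fit with lme4/lmerTest and the merMod object is retained.
#'
#' @param data data.frame with columns `condition`, `replicate`,
#'   `temperature_index`, `abundance` (log2 scale).
#' @param drop_reference drop temperature index 0 first (default TRUE).
#' @return a [MixedFit-class].
#' @export
fitMixed <- function(data, drop_reference = TRUE) {
  stopifnot(all(c("condition", "replicate", "temperature_index",
                  "abundance") %in% names(data)))
  if (drop_reference)
    data <- data[data$temperature_index != 0L, , drop = FALSE]
  data <- data[!is.na(data$abundance), , drop = FALSE]
  conds <- .cond_levels(unique(data$condition))
  temps <- sort(unique(data$temperature_index))
  reps <- sort(unique(data$replicate))
  for (cc in conds)
    if (length(unique(data$replicate[data$condition == cc])) < 2)
      stop("need >= 2 replicates per condition")
  C <- length(conds); Tn <- length(temps)
  n <- nrow(data)
  balanced <- n == C * length(reps) * Tn &&
    all(table(data$condition, data$temperature_index) == length(reps)) &&
    all(table(data$condition, data$replicate) == Tn)
  cm_names <- as.vector(t(outer(conds, temps, function(a, b)
    paste0(a, ".t", b))))
  if (balanced) {
    R <- length(reps)
    cell <- tapply(data$abundance, list(factor(data$condition, conds),
                                        factor(data$temperature_index, temps)),
                   mean)
    subj <- tapply(data$abundance, list(factor(data$condition, conds),
                                        factor(data$replicate, reps)), mean)
    condm <- rowMeans(subj)
    ms_rep <- Tn * sum((subj - condm)^2) / (C * (R - 1))
    df_rep <- C * (R - 1)
    ci <- match(data$condition, conds)
    fitted <- cell[cbind(ci, match(data$temperature_index, temps))] +
      subj[cbind(ci, match(data$replicate, reps))] - condm[ci]
    df_err <- C * (R - 1) * (Tn - 1)
    sing <- FALSE
    if (df_err > 0) {
      ms_err <- sum((data$abundance - fitted)^2) / df_err
      sigma_b <- (ms_rep - ms_err) / Tn
      sing <- sigma_b < 0
      sigma_b <- max(sigma_b, 0)
    } else {
      # one temperature: replicate and residual variation are confounded
      ms_err <- ms_rep
      sigma_b <- 0
      sing <- TRUE
    }
    cms <- as.vector(t(cell))
    names(cms) <- cm_names
    new("MixedFit", cell_means = cms, sigma_bio_sq = sigma_b,
        sigma_error_sq = ms_err, ms_rep = ms_rep, df_rep = df_rep,
        ms_err = ms_err, df_err = max(df_err, 0), n_replicates = as.integer(R),
        n_temperatures = as.integer(Tn), singular = sing, balanced = TRUE,
        fit = NULL, n_obs = as.integer(n))
  } else {
    df <- data.frame(
      y = data$abundance,
      ct = factor(paste0(data$condition, ".t", data$temperature_index),
                  levels = cm_names),
      biorep = factor(paste(data$condition, data$replicate, sep = "\r")))
    fm <- suppressMessages(lmerTest::lmer(
      y ~ 0 + ct + (1 | biorep), data = df,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    vc <- as.data.frame(lme4::VarCorr(fm))
    sigma_b <- vc$vcov[vc$grp == "biorep"][1]
    sigma_e <- vc$vcov[vc$grp == "Residual"][1]
    cms <- lme4::fixef(fm)
    names(cms) <- sub("^ct", "", names(cms))
    new("MixedFit", cell_means = cms, sigma_bio_sq = sigma_b,
        sigma_error_sq = sigma_e, ms_rep = NA_real_, df_rep = NA_real_,
        ms_err = NA_real_, df_err = NA_real_,
        n_replicates = as.integer(length(reps)),
        n_temperatures = as.integer(Tn),
        singular = lme4::isSingular(fm), balanced = FALSE, fit = fm,
        n_obs = as.integer(n))
  }
}

#' Test a temperature-subset contrast on a mixed-model fit
#'
#' Tests the null hypothesis that the treated-minus-vehicle difference in
#' cell means, averaged over the temperature subset `subset`, is zero. The
#' contrast variance uses both variance components estimated from all fitted
#' temperatures. For balanced fits it is assembled from the untruncated
#' between-replicate and residual mean squares,
#' \deqn{\hat V = \frac{2}{RT} MS_{rep} + \frac{2}{R}\left(\frac{1}{|S|} -
#' \frac{1}{T}\right) MS_{err},}
#' with Satterthwaite degrees of freedom over the two independent mean
#' squares (exact Student t when the subset equals all fitted temperatures);
#' unbalanced fits use the lmerTest Satterthwaite machinery. Degrees of
#' freedom are floored at 1.
#'
#' @param fit a [MixedFit-class].
#' @param subset integer temperature indices; must be contained in the
#'   fitted indices (index 0 is an error when the reference channel was
#'   discarded at fit time).
#' @param protein_id id for the result row.
#' @return a [testResult()] data.frame row (model `"msstats_mixed"`).
#' @export
mixedContrastTest <- function(fit, subset, protein_id = NA_character_) {
  stopifnot(is(fit, "MixedFit"))
  subset <- as.integer(subset)
  if (!length(subset)) stop("subset must be non-empty")
  cm <- fit@cell_means
  conds <- unique(sub("\\.t.*", "", names(cm)))
  conds <- .cond_levels(conds)
  if (length(conds) != 2) stop("contrast needs exactly two conditions")
  want <- lapply(conds, function(cc) paste0(cc, ".t", subset))
  if (!all(unlist(want) %in% names(cm))) {
    if (0L %in% subset && !paste0(conds[1], ".t0") %in% names(cm))
      stop("subset contains the reference index 0, which was discarded ",
           "before fitting")
    stop("subset contains temperature indices outside the fitted set")
  }
  m <- length(subset)
  est <- mean(cm[want[[2]]]) - mean(cm[want[[1]]])
  if (fit@balanced) {
    R <- fit@n_replicates; Tn <- fit@n_temperatures
    a1 <- 2 / (R * Tn)
    a2 <- (2 / R) * (1 / m - 1 / Tn)
    V <- a1 * fit@ms_rep + a2 * fit@ms_err
    if (!is.finite(V) || V <= 0)
      return(testResult(protein_id, "msstats_mixed", decision = "failed",
                        n_obs = fit@n_obs))
    den <- (a1 * fit@ms_rep)^2 / fit@df_rep
    if (a2 > 0 && fit@df_err > 0)
      den <- den + (a2 * fit@ms_err)^2 / fit@df_err
    df <- max(V^2 / den, 1)
    tstat <- est / sqrt(V)
    p <- 2 * stats::pt(-abs(tstat), df)
    testResult(protein_id, "msstats_mixed", statistic = tstat, df1 = 1,
               df2 = df, estimate = est, se = sqrt(V), pvalue = p,
               n_obs = fit@n_obs)
  } else {
    fm <- fit@fit
    cn <- names(lme4::fixef(fm))
    L <- numeric(length(cn))
    L[match(paste0("ct", want[[2]]), cn)] <- 1 / m
    L[match(paste0("ct", want[[1]]), cn)] <- -1 / m
    ct <- lmerTest::contest1D(fm, L, ddf = "Satterthwaite")
    df <- max(ct$df, 1)
    testResult(protein_id, "msstats_mixed", statistic = ct$`t value`,
               df1 = 1, df2 = df, estimate = ct$Estimate,
               se = ct$`Std. Error`,
               pvalue = 2 * stats::pt(-abs(ct$`t value`), df),
               n_obs = fit@n_obs)
  }
}

#' One-way ANOVA group comparisons for OnePot designs
#'
#' For a single-plex OnePot experiment (one pooled value per condition and
#' biological replicate), fits a per-protein one-way fixed-effects model
#' across conditions and tests each requested dose-versus-vehicle contrast
#' with the pooled residual variance. BH adjustment is applied across
#' proteins within each comparison.
#'
#' @param table log2-scale [ProteinProfileTable-class] of pooled values.
#' @param comparisons list of `c(dose, vehicle)` label pairs; default every
#'   non-vehicle condition versus `"vehicle"`.
#' @return data.frame of [testResult()] rows, one per protein x comparison;
#'   the model column is `"onepot_anova:<dose>_vs_<vehicle>"`.
#' @export
anovaGroupComparison <- function(table, comparisons = NULL) {
  stopifnot(is(table, "ProteinProfileTable"))
  d <- profileData(table)
  conds <- unique(d$condition)
  if (is.null(comparisons)) {
    if (!"vehicle" %in% conds)
      stop("no 'vehicle' condition; supply comparisons explicitly")
    comparisons <- lapply(setdiff(conds, "vehicle"),
                          function(cc) c(cc, "vehicle"))
  }
  rows <- list()
  for (p in unique(d$protein)) {
    sub <- d[d$protein == p & !is.na(d$abundance), ]
    ns <- table(sub$condition)
    means <- tapply(sub$abundance, sub$condition, mean)
    k <- sum(ns >= 1)
    ss <- sum((sub$abundance - means[sub$condition])^2)
    df_res <- nrow(sub) - k
    mse <- if (df_res > 0) ss / df_res else NA_real_
    for (cmp in comparisons) {
      label <- paste0("onepot_anova:", cmp[1], "_vs_", cmp[2])
      if (any(!cmp %in% names(ns)) || any(ns[cmp] < 2) || df_res <= 0) {
        rows[[length(rows) + 1]] <-
          testResult(p, label, decision = "failed", n_obs = nrow(sub))
        next
      }
      est <- unname(means[cmp[1]] - means[cmp[2]])
      se <- sqrt(mse * (1 / ns[[cmp[1]]] + 1 / ns[[cmp[2]]]))
      tstat <- est / se
      rows[[length(rows) + 1]] <- testResult(
        p, label, statistic = tstat, df1 = 1, df2 = df_res, estimate = est,
        se = se, pvalue = 2 * stats::pt(-abs(tstat), df_res),
        n_obs = nrow(sub))
    }
  }
  out <- do.call(rbind, rows)
  for (label in unique(out$model)) {
    sel <- out$model == label & !is.na(out$pvalue)
    out$qvalue[sel] <- bhAdjust(out$pvalue[sel])
  }
  out
}
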