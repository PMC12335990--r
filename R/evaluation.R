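#' @include AllClasses.R
NULL

#' Summarize a batch of p-values against the uniform reference
#'
#' Computes a 20-bin histogram on `[0, 1]`, the proportion of p-values below
#' each cutoff with its 99% binomial band around the nominal level
#' (`nominal +/- 2.576 sqrt(nominal (1 - nominal) / n)`), and the
#' Kolmogorov-Smirnov distance to Uniform(0, 1) together with the 1%
#' critical value `1.63 / sqrt(n)`.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param cutoffs significance cutoffs (default `c(0.001, 0.05)`).
#' @return list with `n`, `histogram` (20 counts), `prop_below` (named),
#'   `binomial_band` (matrix, rows = cutoffs), `ks_stat`, `ks_crit_1pct`.
#' @export
summarizePvalues <- function(pvalues, cutoffs = c(0.001, 0.05)) {
  pvalues <- pvalues[!is.na(pvalues)]
  n <- length(pvalues)
  if (!n) stop("no p-values to summarize")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  hist_counts <- tabulate(pmin(floor(pvalues * 20) + 1, 20), nbins = 20)
  prop <- vapply(cutoffs, function(ct) mean(pvalues < ct), numeric(1))
  names(prop) <- cutoffs
  band <- t(vapply(cutoffs, function(ct) {
    half <- 2.576 * sqrt(ct * (1 - ct) / n)
    c(low = ct - half, high = ct + half)
  }, numeric(2)))
  rownames(band) <- cutoffs
  ks <- max(abs(sort(pvalues) - (seq_len(n) - 0.5) / n)) + 0.5 / n
  list(n = n, histogram = hist_counts, prop_below = prop,
       binomial_band = band, ks_stat = ks, ks_crit_1pct = 1.63 / sqrt(n))
}

#' Tabulate significance proportions across simulation cells
#'
#' One row per (template, design, ICC, cutoff) with the proportion of
#' p-values below the cutoff. For null templates the proportion is the
#' empirical type-I error; for interacting templates it is the power.
#'
#' @param results data.frame with columns `template`, `design`, `icc`,
#'   `pvalue` (one row per simulated instance).
#' @param cutoffs significance cutoffs (default `c(0.001, 0.05)`).
#' @return data.frame with columns `template`, `design`, `icc`, `cutoff`,
#'   `n`, `proportion`.
#' @export
powerTable <- function(results, cutoffs = c(0.001, 0.05)) {
  stopifnot(all(c("template", "design", "icc", "pvalue") %in% names(results)))
  cells <- unique(results[, c("template", "design", "icc")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$template == cells$template[i] &
      results$design == cells$design[i] & results$icc == cells$icc[i]
    p <- results$pvalue[sel]
    data.frame(template = cells$template[i], design = cells$design[i],
               icc = cells$icc[i], cutoff = cutoffs,
               n = sum(!is.na(p)),
               proportion = vapply(cutoffs, function(ct)
                 mean(p < ct, na.rm = TRUE), numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Exact intersection-region counts across detection sets
#'
#' For k >= 2 named sets of protein ids, counts every one of the 2^k - 1
#' non-empty membership regions (as in an UpSet or Venn summary), plus
#' per-set totals and, optionally, hits against a reference set per region.
#'
#' @param detections named list (length >= 2) of character vectors.
#' @param reference optional character vector of reference protein ids.
#' @return list with `regions` (data.frame: one indicator column per set,
#'   `count`, and `reference_hits` when a reference is given) and `totals`
#'   (named per-set sizes).
#' @export
overlapCounts <- function(detections, reference = NULL) {
  if (length(detections) < 2) stop("need at least two sets")
  if (is.null(names(detections)) || any(names(detections) == ""))
    stop("detections must be a named list")
  sets <- lapply(detections, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  pattern <- apply(member, 1, paste, collapse = "")
  idx <- split(seq_along(universe), pattern)
  reg_list <- lapply(names(idx), function(pt) {
    rows <- idx[[pt]]
    flag <- member[rows[1], , drop = TRUE]
    out <- as.data.frame(as.list(as.integer(flag)))
    names(out) <- names(sets)
    out$count <- length(rows)
    if (!is.null(reference))
      out$reference_hits <- sum(universe[rows] %in% reference)
    out
  })
  regions <- do.call(rbind, reg_list)
  ord <- order(-rowSums(regions[names(sets)]),
               apply(regions[names(sets)], 1, paste, collapse = ""))
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  list(regions = regions,
       totals = vapply(sets, length, integer(1)))
}
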