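#' @include AllClasses.R
NULL

CONDITION_LEVELS <- c("vehicle", "treated")
CHANNEL_ROLES <- c("measurement", "reference", "carrier", "empty")

#' Construct a study design from a channel annotation table
#'
#' @param channels data.frame with columns `plex`, `channel`, `condition`,
#'   `replicate`, `temperature_index`, `temperature`, `role`. `role` defaults
#'   to `"measurement"` (index 0 is promoted to `"reference"` only if marked
#'   so explicitly); carrier/empty rows may leave index and temperature `NA`.
#' @return a [StudyDesign-class]. Construction is permissive; run
#'   [validateDesign()] for diagnostics.
#' @examples
#' ch <- data.frame(plex = "p1", channel = as.character(126:129),
#'                  condition = "vehicle", replicate = "r1",
#'                  temperature_index = 0:3,
#'                  temperature = c(37, 44, 52, 60), role = "measurement")
#' studyDesign(ch)
#' @export
studyDesign <- function(channels) {
  required <- c("plex", "channel", "condition", "replicate",
                "temperature_index", "temperature")
  miss <- setdiff(required, names(channels))
  if (length(miss))
    stop("design table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(channels$role)) channels$role <- "measurement"
  bad <- setdiff(unique(channels$role), CHANNEL_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  channels$plex <- as.character(channels$plex)
  channels$channel <- as.character(channels$channel)
  channels$condition <- as.character(channels$condition)
  channels$replicate <- as.character(channels$replicate)
  channels$temperature_index <- as.integer(channels$temperature_index)
  channels$temperature <- as.numeric(channels$temperature)
  off <- channels$role %in% c("carrier", "empty")
  channels$temperature_index[off] <- NA_integer_
  channels$temperature[off] <- NA_real_
  new("StudyDesign", channels = channels)
}

#' Read a study design from a delimited file
#'
#' Expects columns `plex`, `channel`, `condition`, `replicate`,
#' `temperature_index`, `temperature_c` (or `temperature`), `role`.
#' Comma- or tab-delimited, auto-detected from the file extension.
#'
#' @param path file path.
#' @return a [StudyDesign-class].
#' @export
readDesign <- function(path) {
  tab <- .read_delim_auto(path)
  if (!is.null(tab$temperature_c) && is.null(tab$temperature))
    names(tab)[names(tab) == "temperature_c"] <- "temperature"
  studyDesign(tab)
}

#' Check a study design against its invariants
#'
#' Returns diagnostics rather than throwing: an empty character vector means
#' the design is internally consistent. Checked invariants: at most one
#' reference channel per plex; unique temperature index within
#' (plex, condition) for measurement/reference channels; carrier and empty
#' channels carry no temperature; each (condition, replicate, temperature)
#' cell maps to at most one (plex, channel); temperatures strictly increasing
#' with temperature index.
#'
#' @param design a [StudyDesign-class].
#' @return character vector of diagnostics (empty when valid).
#' @export
validateDesign <- function(design) {
  ch <- designChannels(design)
  out <- character()
  for (p in unique(ch$plex)) {
    nref <- sum(ch$role == "reference" & ch$plex == p)
    if (nref > 1)
      out <- c(out, sprintf("plex %s has %d reference channels (max 1)", p, nref))
  }
  meas <- ch[ch$role %in% c("measurement", "reference"), , drop = FALSE]
  if (any(is.na(meas$temperature_index)))
    out <- c(out, "measurement/reference channels with missing temperature_index")
  key <- paste(meas$plex, meas$condition, meas$temperature_index)
  if (anyDuplicated(key))
    out <- c(out, sprintf(
      "duplicated temperature_index within (plex, condition): %s",
      paste(unique(key[duplicated(key)]), collapse = "; ")))
  crt <- paste(meas$condition, meas$replicate, meas$temperature_index)
  if (anyDuplicated(crt))
    out <- c(out, sprintf(
      "cell (condition, replicate, temperature) mapped to several channels: %s",
      paste(unique(crt[duplicated(crt)]), collapse = "; ")))
  tt <- unique(meas[!is.na(meas$temperature),
                    c("temperature_index", "temperature")])
  tt <- tt[order(tt$temperature_index), , drop = FALSE]
  if (anyDuplicated(tt$temperature_index))
    out <- c(out, "a temperature_index maps to several Celsius values")
  else if (nrow(tt) > 1 && any(diff(tt$temperature) <= 0))
    out <- c(out, "temperatures are not strictly increasing with temperature_index")
  out
}

# ---- tables -----------------------------------------------------------------

.assert_scale <- function(scale, allowed) {
  if (!scale %in% allowed)
    stop("scale must be one of: ", paste(allowed, collapse = ", "))
  scale
}

#' Construct a protein-level profile table
#'
#' @param data data.frame with columns `protein`, `condition`, `replicate`,
#'   `temperature_index`, `temperature`, `abundance`.
#' @param scale `"raw"`, `"log2"`, or `"ratio"`.
#' @return a [ProteinProfileTable-class].
#' @export
proteinProfileTable <- function(data, scale = c("raw", "log2", "ratio")) {
  scale <- match.arg(scale)
  required <- c("protein", "condition", "replicate", "temperature_index",
                "temperature", "abundance")
  miss <- setdiff(required, names(data))
  if (length(miss))
    stop("profile table is missing column(s): ", paste(miss, collapse = ", "))
  data <- data[required]
  data$protein <- as.character(data$protein)
  data$condition <- as.character(data$condition)
  data$replicate <- as.character(data$replicate)
  data$temperature_index <- as.integer(data$temperature_index)
  key <- paste(data$protein, data$condition, data$replicate,
               data$temperature_index)
  if (anyDuplicated(key))
    stop("duplicate (protein, condition, replicate, temperature) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  if (scale %in% c("raw", "ratio") &&
      any(data$abundance < 0, na.rm = TRUE))
    stop(scale, "-scale abundances must be non-negative")
  if (scale == "ratio") {
    ref <- data$abundance[data$temperature_index == 0L]
    if (length(ref) && any(abs(ref - 1) > 1e-12, na.rm = TRUE))
      stop("ratio-scale abundances must equal 1 at the reference index")
  }
  new("ProteinProfileTable", data = data, scale = scale)
}

#' Construct a feature-level intensity table
#'
#' @param data data.frame with columns `protein`, `feature`, `plex`,
#'   `condition`, `replicate`, `temperature_index`, `temperature`,
#'   `intensity`; optional `shared` (default FALSE) and `imputed`
#'   (default FALSE).
#' @param scale `"raw"` or `"log2"`.
#' @return a [FeatureTable-class].
#' @export
featureTable <- function(data, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  required <- c("protein", "feature", "plex", "condition", "replicate",
                "temperature_index", "temperature", "intensity")
  miss <- setdiff(required, names(data))
  if (length(miss))
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(data$shared)) data$shared <- FALSE
  if (is.null(data$imputed)) data$imputed <- FALSE
  data <- data[c(required, "shared", "imputed")]
  for (col in c("protein", "feature", "plex", "condition", "replicate"))
    data[[col]] <- as.character(data[[col]])
  data$temperature_index <- as.integer(data$temperature_index)
  key <- paste(data$protein, data$feature, data$condition, data$replicate,
               data$temperature_index)
  if (anyDuplicated(key))
    stop("duplicate (protein, feature, condition, replicate, temperature) key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  if (scale == "raw" && any(data$intensity < 0, na.rm = TRUE))
    stop("raw-scale intensities must be non-negative")
  new("FeatureTable", data = data, scale = scale)
}

.read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a quantification table and validate it against a design
#'
#' Reads delimited text (comma or tab, auto-detected from extension) holding
#' either feature-level intensities (`protein_id`, `feature_id`, `plex`,
#' `channel`, `intensity`, optional `shared`) or protein-level abundances
#' (`protein_id`, `plex`, `channel`, `abundance`), joins the channel
#' annotations from `design`, drops carrier/empty channels, and returns a
#' validated table. Rows referencing channels absent from the design raise a
#' design-mismatch error. Column names can be remapped via `columns`.
#'
#' @param path file path.
#' @param level `"feature"` or `"protein"`.
#' @param design a [StudyDesign-class].
#' @param scale scale flag of the values in the file (default `"raw"`).
#' @param columns named character vector remapping default column names, e.g.
#'   `c(protein_id = "Protein.Accession")`.
#' @return a [FeatureTable-class] or [ProteinProfileTable-class].
#' @export
readQuantTable <- function(path, level = c("feature", "protein"), design,
                           scale = "raw", columns = character()) {
  level <- match.arg(level)
  tab <- .read_delim_auto(path)
  defaults <- if (level == "feature")
    c(protein_id = "protein_id", feature_id = "feature_id", plex = "plex",
      channel = "channel", intensity = "intensity", shared = "shared")
  else
    c(protein_id = "protein_id", plex = "plex", channel = "channel",
      abundance = "abundance")
  mapping <- defaults
  mapping[names(columns)] <- columns
  req <- mapping[setdiff(names(mapping), "shared")]
  miss <- setdiff(unname(req), names(tab))
  if (length(miss))
    stop("quantification file is missing required column(s): ",
         paste(miss, collapse = ", "))
  ch <- designChannels(design)
  ch_key <- paste(ch$plex, ch$channel)
  row_key <- paste(tab[[mapping["plex"]]], tab[[mapping["channel"]]])
  unknown <- setdiff(unique(row_key), ch_key)
  if (length(unknown))
    stop("design mismatch: file references channel(s) not in the design: ",
         paste(utils::head(unknown, 5), collapse = "; "))
  idx <- match(row_key, ch_key)
  ann <- ch[idx, c("condition", "replicate", "temperature_index",
                   "temperature", "role")]
  keep <- ann$role %in% c("measurement", "reference")
  tab <- tab[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  if (level == "protein") {
    proteinProfileTable(data.frame(
      protein = tab[[mapping["protein_id"]]],
      condition = ann$condition, replicate = ann$replicate,
      temperature_index = ann$temperature_index,
      temperature = ann$temperature,
      abundance = tab[[mapping["abundance"]]],
      stringsAsFactors = FALSE), scale = scale)
  } else {
    shared <- if (mapping["shared"] %in% names(tab))
      as.logical(tab[[mapping["shared"]]]) else FALSE
    featureTable(data.frame(
      protein = tab[[mapping["protein_id"]]],
      feature = tab[[mapping["feature_id"]]],
      plex = tab[[mapping["plex"]]],
      condition = ann$condition, replicate = ann$replicate,
      temperature_index = ann$temperature_index,
      temperature = ann$temperature,
      intensity = tab[[mapping["intensity"]]],
      shared = shared, stringsAsFactors = FALSE), scale = scale)
  }
}

# ---- results ----------------------------------------------------------------

RESULT_COLUMNS <- c("protein_id", "model", "statistic", "df1", "df2",
                    "estimate", "se", "pvalue", "qvalue", "decision", "n_obs")

#' Assemble one per-protein test result row
#'
#' @param protein_id,model identifiers.
#' @param statistic F, t, or z statistic.
#' @param df1,df2 degrees of freedom (possibly fractional; `NA` where not
#'   applicable).
#' @param estimate,se contrast estimate and standard error (contrast-type
#'   tests only).
#' @param pvalue,qvalue raw and BH-adjusted p-values.
#' @param decision one of `"interactor"`, `"non-interactor"`, `"filtered"`,
#'   `"failed"`, or `NA` before thresholding.
#' @param n_obs observations used.
#' @return one-row data.frame with the standard result columns.
#' @export
testResult <- function(protein_id, model, statistic = NA_real_,
                       df1 = NA_real_, df2 = NA_real_, estimate = NA_real_,
                       se = NA_real_, pvalue = NA_real_, qvalue = NA_real_,
                       decision = NA_character_, n_obs = NA_integer_) {
  data.frame(protein_id = as.character(protein_id), model = as.character(model),
             statistic = statistic, df1 = df1, df2 = df2,
             estimate = estimate, se = se, pvalue = pvalue, qvalue = qvalue,
             decision = as.character(decision), n_obs = as.integer(n_obs),
             stringsAsFactors = FALSE)
}

#' Write per-protein test results to delimited text
#'
#' Rows are ordered deterministically by (protein_id, model) and columns by
#' the standard result schema, so repeated writes of the same results are
#' byte-identical.
#'
#' @param results data.frame of [testResult()] rows.
#' @param path output file (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("results must be a non-empty data.frame")
  miss <- setdiff(RESULT_COLUMNS, names(results))
  if (length(miss))
    stop("results are missing column(s): ", paste(miss, collapse = ", "))
  results <- results[order(results$protein_id, results$model), RESULT_COLUMNS]
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(results, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back a results file written by [writeResults()]
#'
#' @param path file path.
#' @return data.frame with the standard result columns.
#' @export
readResults <- function(path) {
  tab <- .read_delim_auto(path)
  miss <- setdiff(RESULT_COLUMNS, names(tab))
  if (length(miss))
    stop("results file is missing column(s): ", paste(miss, collapse = ", "))
  tab$protein_id <- as.character(tab$protein_id)
  tab$model <- as.character(tab$model)
  tab$decision <- as.character(tab$decision)
  tab$n_obs <- as.integer(tab$n_obs)
  tab[RESULT_COLUMNS]
}
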