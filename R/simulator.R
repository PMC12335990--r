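#' @include AllClasses.R study_io.R
NULL

#' Default temperature ladder (Celsius)
#' @export
DEFAULT_TEMPERATURES <- c(37.3, 40.2, 44.9, 47.6, 51, 54, 57, 61.8, 64, 67)

.template_curve <- function(temp, tm, plateau, steepness, baseline) {
  baseline + log2(plateau + (1 - plateau) / (1 + exp((temp - tm) / steepness)))
}

#' Build a surrogate ground-truth interaction template
#'
#' Condition-by-temperature log2 mean surfaces built from a parametric
#' melting sigmoid: soluble fraction
#' \eqn{f(T) = p + (1 - p)/(1 + e^{(T - T_m)/s})} on top of a log2 baseline.
#' The treated curve shifts the midpoint by `shift` degrees (+3 for strong,
#' +1 for weak interactions by default). Null templates average the vehicle
#' and treated curves and duplicate the average, mirroring how a
#' non-interactor's fitted conditions are pooled.
#'
#' @param kind `"strong"`, `"weak"`, or `"null"`.
#' @param temperatures Celsius ladder (default [DEFAULT_TEMPERATURES]).
#' @param plateau lower plateau of the soluble fraction (default 0.05).
#' @param midpoint vehicle melting midpoint, Celsius (default 52).
#' @param steepness transition scale in Celsius (default 2; the 10-90%
#'   transition then spans about 9 degrees).
#' @param shift treated-minus-vehicle midpoint shift; defaults 3 (strong),
#'   1 (weak and null).
#' @param baseline additive log2 abundance offset (default 15).
#' @return a [Template-class].
#' @examples
#' makeTemplate("strong")
#' @export
makeTemplate <- function(kind = c("strong", "weak", "null"),
                         temperatures = DEFAULT_TEMPERATURES,
                         plateau = 0.05, midpoint = 52, steepness = 2,
                         shift = NULL, baseline = 15) {
  kind <- match.arg(kind)
  if (is.null(shift)) shift <- switch(kind, strong = 3, weak = 1, null = 1)
  if (steepness <= 0 || plateau < 0 || plateau >= 1)
    stop("shape parameters produce a non-monotone or degenerate curve")
  veh <- .template_curve(temperatures, midpoint, plateau, steepness, baseline)
  trt <- .template_curve(temperatures, midpoint + shift, plateau, steepness,
                         baseline)
  mu <- rbind(vehicle = veh, treated = trt)
  if (kind == "null") {
    avg <- colMeans(mu)
    mu <- rbind(vehicle = avg, treated = avg)
  }
  new("Template", temperatures = temperatures, mu = mu, kind = kind)
}

#' Intra-class correlation of the two variance components
#'
#' Proportion of the total variation attributed to the biological
#' between-replicate variation:
#' \eqn{\sigma^2_{bio} / (\sigma^2_{bio} + \sigma^2_{error})}.
#'
#' @param sigma_bio_sq biological variance (>= 0).
#' @param sigma_error_sq technological variance (> 0 unless bio > 0).
#' @return proportion in `[0, 1)`.
#' @examples
#' icc(0.014, 0.267)   # ~5%
#' icc(0.178, 0.267)   # 40%
#' @export
icc <- function(sigma_bio_sq, sigma_error_sq) {
  if (sigma_bio_sq < 0 || sigma_error_sq < 0)
    stop("variances must be non-negative")
  if (sigma_bio_sq + sigma_error_sq == 0)
    stop("at least one variance must be positive")
  sigma_bio_sq / (sigma_bio_sq + sigma_error_sq)
}

#' Construct a design specification
#'
#' @param mode `"thermal"` or `"onepot"`.
#' @param n_replicates biological replicates per condition.
#' @param temperatures_fit indices entering the model fit (thermal).
#' @param temperatures_test null-hypothesis subset (thermal).
#' @param pooled_indices indices pooled per channel (onepot).
#' @param n_plexes number of plexes.
#' @return a [DesignSpec-class].
#' @export
designSpec <- function(mode, n_replicates, temperatures_fit = integer(),
                       temperatures_test = integer(),
                       pooled_indices = integer(), n_plexes = 1L) {
  new("DesignSpec", mode = mode, n_replicates = as.integer(n_replicates),
      temperatures_fit = as.integer(temperatures_fit),
      temperatures_test = as.integer(temperatures_test),
      pooled_indices = as.integer(pooled_indices),
      n_plexes = as.integer(n_plexes))
}

#' Catalog of the studied experimental designs
#'
#' Thermal designs: `T-D` (2 replicates, all 10 temperatures fit and
#' tested), `T-E` (2 replicates, only temperatures {6,7} measured), `T-F`
#' (2 replicates, all temperatures fit, subset {6,7,8} tested — the mode
#' used for experimental analyses), `T-G` (10 replicates, temperatures
#' {6,7}, four plexes with seeded random allocation). OnePot designs:
#' `OP-D` (10 replicates, pool of temperatures {6,7}, two plexes), `OP-E`
#' (5 replicates, one plex), `OP-F` (2 replicates, one incomplete plex).
#'
#' @return named list of [DesignSpec-class] objects.
#' @export
designCatalog <- function() {
  list(
    "T-D" = designSpec("thermal", 2, 0:9, 0:9, n_plexes = 4L),
    "T-E" = designSpec("thermal", 2, c(6L, 7L), c(6L, 7L), n_plexes = 4L),
    "T-F" = designSpec("thermal", 2, 0:9, c(6L, 7L, 8L), n_plexes = 4L),
    "T-G" = designSpec("thermal", 10, c(6L, 7L), c(6L, 7L), n_plexes = 4L),
    "OP-D" = designSpec("onepot", 10, pooled_indices = c(6L, 7L),
                        n_plexes = 2L),
    "OP-E" = designSpec("onepot", 5, pooled_indices = c(6L, 7L),
                        n_plexes = 1L),
    "OP-F" = designSpec("onepot", 2, pooled_indices = c(6L, 7L),
                        n_plexes = 1L))
}

#' Construct a simulation configuration
#'
#' @param sigma_bio_sq biological between-replicate variance (log2 scale).
#' @param sigma_error_sq technological within-replicate variance (default
#'   0.267).
#' @param n_instances protein instances to simulate (default 1000).
#' @param seed mandatory integer seed.
#' @param design a [DesignSpec-class] (default thermal `T-F`).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(sigma_bio_sq, sigma_error_sq = 0.267,
                      n_instances = 1000, seed,
                      design = designCatalog()[["T-F"]]) {
  new("SimConfig", sigma_bio_sq = sigma_bio_sq,
      sigma_error_sq = sigma_error_sq, n_instances = as.integer(n_instances),
      seed = as.integer(seed), design = design)
}

# deterministic per-instance substream: distinct user seeds map to disjoint
# instance seeds (multiplicative spreading, kept below 2^31)
.instance_seed <- function(seed, instance) {
  as.integer((as.double(seed) * 69069 + as.double(instance)) %% 2147483647)
}

# one simulated instance as a plain long data.frame (fast path)
.simulate_instance <- function(template, config, instance) {
  des <- config@design
  R <- des@n_replicates
  mu <- template@mu
  Tn <- ncol(mu)
  set.seed(.instance_seed(config@seed, instance))
  conds <- rownames(mu)
  g <- expand.grid(replicate = paste0("r", seq_len(R)),
                   condition = conds, stringsAsFactors = FALSE)
  b <- stats::rnorm(nrow(g), 0, sqrt(config@sigma_bio_sq))
  out <- data.frame(
    protein = sprintf("instance_%05d", instance),
    condition = rep(g$condition, each = Tn),
    replicate = rep(g$replicate, each = Tn),
    temperature_index = rep(0:(Tn - 1), nrow(g)),
    temperature = rep(template@temperatures, nrow(g)),
    abundance = rep(as.vector(t(mu[g$condition, , drop = FALSE])),
                    1) + rep(b, each = Tn) +
      stats::rnorm(nrow(g) * Tn, 0, sqrt(config@sigma_error_sq)),
    stringsAsFactors = FALSE)
  out
}

# seeded allocation of (condition, replicate) samples to plexes
.allocate_plexes <- function(config) {
  des <- config@design
  R <- des@n_replicates
  samples <- expand.grid(replicate = paste0("r", seq_len(R)),
                         condition = c("vehicle", "treated"),
                         stringsAsFactors = FALSE)
  set.seed(.instance_seed(config@seed, 0L))
  plex <- sample(rep(seq_len(des@n_plexes), length.out = nrow(samples)))
  samples$plex <- paste0("plex", plex)
  samples
}

#' Simulate thermal-profiling instances from a template
#'
#' Each instance is \eqn{Y_{crt} = \mu_{ct} + b_{cr} + \varepsilon_{crt}}
#' with one biological effect \eqn{b_{cr} \sim N(0, \sigma^2_{bio})} per
#' condition x replicate (vehicle and treated replicates are distinct
#' biological samples) and i.i.d. technological noise
#' \eqn{\varepsilon \sim N(0, \sigma^2_{error})}; between-plex variation is
#' taken as negligible and no plex effect is added. Instance `k` uses the
#' deterministic substream `seed + k`, so it is identical regardless of
#' batch size.
#'
#' @param template a [Template-class].
#' @param config a [SimConfig-class] with a thermal design.
#' @return list of log2-scale [ProteinProfileTable-class] objects, one per
#'   instance; attribute `allocation` records the seeded replicate-to-plex
#'   assignment.
#' @export
simulateThermal <- function(template, config) {
  stopifnot(is(template, "Template"), is(config, "SimConfig"))
  out <- lapply(seq_len(config@n_instances), function(i)
    proteinProfileTable(.simulate_instance(template, config, i),
                        scale = "log2"))
  attr(out, "allocation") <- .allocate_plexes(config)
  out
}

#' Pool log2 abundances the OnePot way
#'
#' Unlog, average over the pooled values, and log2-transform the average
#' back: `log2(mean(2^values))`. By concavity of log2 the result is at
#' least the arithmetic mean of the inputs and lies within their range.
#'
#' @param values log2 abundances over the pooled temperature treatments.
#' @return one pooled log2 value.
#' @examples
#' poolOnepot(c(1, 3))   # log2(5) ~ 2.3219
#' @export
poolOnepot <- function(values) {
  if (!length(values)) stop("pooled index set must be non-empty")
  log2(mean(2^values))
}

#' Simulate OnePot instances from a template
#'
#' Simulates the full thermal matrix exactly as [simulateThermal()], then
#' pools the configured temperature indices per condition and replicate with
#' [poolOnepot()], reflecting physical pooling of heated aliquots before
#' labeling. Each instance yields one pooled value per condition x
#' replicate (temperature fields are `NA`).
#'
#' @param template a [Template-class].
#' @param config a [SimConfig-class] with an onepot design.
#' @return list of log2-scale [ProteinProfileTable-class] objects; attribute
#'   `allocation` as in [simulateThermal()].
#' @export
simulateOnepot <- function(template, config) {
  stopifnot(is(template, "Template"), is(config, "SimConfig"))
  pool_idx <- config@design@pooled_indices
  out <- lapply(seq_len(config@n_instances), function(i) {
    full <- .simulate_instance(template, config, i)
    sub <- full[full$temperature_index %in% pool_idx, , drop = FALSE]
    grp <- paste(sub$condition, sub$replicate, sep = "\r")
    pooled <- tapply(sub$abundance, grp, poolOnepot)
    keys <- do.call(rbind, strsplit(names(pooled), "\r", fixed = TRUE))
    proteinProfileTable(data.frame(
      protein = full$protein[1], condition = keys[, 1],
      replicate = keys[, 2], temperature_index = NA_integer_,
      temperature = NA_real_, abundance = unname(pooled),
      stringsAsFactors = FALSE), scale = "log2")
  })
  attr(out, "allocation") <- .allocate_plexes(config)
  out
}
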