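# Shared fixture builders and independently coded oracles. The oracles are
# deliberately naive (loops, brute force) and never call package internals.

fix_temps <- c(37.3, 40.2, 44.9, 47.6, 51, 54, 57, 61.8, 64, 67)

# a raw-scale protein table with sigmoid-ish decay and lognormal noise
random_protein_table <- function(n_prot = 12, n_rep = 2, seed = 1,
                                 noise = 0.05) {
  set.seed(seed)
  g <- expand.grid(protein = sprintf("P%03d", seq_len(n_prot)),
                   condition = c("vehicle", "treated"),
                   replicate = paste0("r", seq_len(n_rep)),
                   temperature_index = 0:9, stringsAsFactors = FALSE)
  g$temperature <- fix_temps[g$temperature_index + 1]
  frac <- (1 - 0.05) / (1 + exp((g$temperature - 52) / 2)) + 0.05
  scale <- stats::runif(n_prot, 0.5, 2)[match(g$protein, unique(g$protein))]
  g$abundance <- 1e6 * scale * frac * exp(stats::rnorm(nrow(g), 0, noise))
  proteinProfileTable(g, scale = "raw")
}

random_feature_table <- function(n_prot = 6, n_feat = 3, seed = 1,
                                 miss_frac = 0.05, shared_prot = character()) {
  set.seed(seed)
  g <- expand.grid(protein = sprintf("P%d", seq_len(n_prot)),
                   feature = paste0("f", seq_len(n_feat)),
                   condition = c("vehicle", "treated"),
                   replicate = c("r1", "r2"),
                   temperature_index = 0:9, stringsAsFactors = FALSE)
  g$feature <- paste(g$protein, g$feature, sep = "_")
  g$plex <- paste0("plex_", g$condition, "_", g$replicate)
  g$temperature <- fix_temps[g$temperature_index + 1]
  g$intensity <- 15 + stats::rnorm(nrow(g), 0, 0.4)
  g$intensity[sample(nrow(g), round(miss_frac * nrow(g)))] <- NA
  g$shared <- g$protein %in% shared_prot
  featureTable(g, scale = "log2")
}

# a clean 4-plex, 11-channel design (reference + 9 measurements + carrier)
make_design <- function() {
  rows <- list()
  combos <- expand.grid(condition = c("vehicle", "treated"),
                        replicate = c("r1", "r2"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    rows[[i]] <- data.frame(
      plex = paste0("plex", i), channel = as.character(126:136),
      condition = combos$condition[i], replicate = combos$replicate[i],
      temperature_index = c(0:9, NA), temperature = c(fix_temps, NA),
      role = c("reference", rep("measurement", 9), "carrier"),
      stringsAsFactors = FALSE)
  }
  studyDesign(do.call(rbind, rows))
}

# ---- oracles ----------------------------------------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

oracle_median_polish_summary <- function(m, tol = 1e-6, maxit = 100) {
  overall <- 0
  re <- rep(0, nrow(m)); ce <- rep(0, ncol(m))
  z <- m; old <- 0
  for (i in seq_len(maxit)) {
    rd <- apply(z, 1, median, na.rm = TRUE); rd[is.na(rd)] <- 0
    z <- z - rd; re <- re + rd
    dd <- median(ce); ce <- ce - dd; overall <- overall + dd
    cd <- apply(z, 2, median, na.rm = TRUE); cd[is.na(cd)] <- 0
    z <- sweep(z, 2, cd); ce <- ce + cd
    dd <- median(re); re <- re - dd; overall <- overall + dd
    s <- sum(abs(z), na.rm = TRUE)
    if (s == 0 || abs(s - old) < tol) break
    old <- s
  }
  overall + ce
}

oracle_normset <- function(ratio_df, bounds) {
  groups <- unique(ratio_df[, c("condition", "replicate")])
  keep <- character()
  for (p in unique(ratio_df$protein)) {
    ok <- TRUE
    for (gi in seq_len(nrow(groups))) {
      for (bi in seq_len(nrow(bounds))) {
        v <- ratio_df$abundance[
          ratio_df$protein == p &
            ratio_df$condition == groups$condition[gi] &
            ratio_df$replicate == groups$replicate[gi] &
            ratio_df$temperature_index == bounds$temperature_index[bi]]
        if (length(v) != 1 || is.na(v) || v < bounds$lower[bi] ||
            v > bounds$upper[bi]) ok <- FALSE
      }
    }
    if (ok) keep <- c(keep, p)
  }
  sort(keep)
}

oracle_overlap <- function(sets, reference = NULL) {
  ids <- unique(unlist(sets))
  out <- list()
  for (id in ids) {
    pat <- paste(vapply(sets, function(s) id %in% s, logical(1)),
                 collapse = "")
    out[[pat]] <- c(out[[pat]], id)
  }
  counts <- vapply(out, length, integer(1))
  refhits <- if (!is.null(reference))
    vapply(out, function(v) sum(v %in% reference), integer(1))
  list(counts = counts, refhits = refhits)
}
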