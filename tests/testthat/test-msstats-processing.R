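test_that("filter boundaries follow the strict 'over three missing' rule", {
  ft <- random_feature_table(2, n_feat = 3, seed = 11, miss_frac = 0)
  d <- featureData(ft)
  # P1 f1 in plex_vehicle_r1: exactly 3 missing -> kept
  sel3 <- d$protein == "P1" & d$feature == "P1_f1" &
    d$plex == "plex_vehicle_r1" & d$temperature_index %in% 0:2
  d$intensity[sel3] <- NA
  # P2 f1 in plex_vehicle_r1: 4 missing -> block dropped
  sel4 <- d$protein == "P2" & d$feature == "P2_f1" &
    d$plex == "plex_vehicle_r1" & d$temperature_index %in% 0:3
  d$intensity[sel4] <- NA
  out <- msstatsFilter(featureTable(d, scale = "log2"))
  o <- featureData(out)
  expect_true(any(o$protein == "P1" & o$feature == "P1_f1" &
                    o$plex == "plex_vehicle_r1"))
  expect_false(any(o$protein == "P2" & o$feature == "P2_f1" &
                     o$plex == "plex_vehicle_r1"))
  rep <- attr(out, "filter_report")
  expect_equal(rep$count_removed[rep$step == "missing_channels"], 1)
})

test_that("shared features then missing blocks then single-feature proteins, with oracle counts", {
  ft <- random_feature_table(6, n_feat = 2, seed = 12, miss_frac = 0.08,
                             shared_prot = "P5")
  d <- featureData(ft)
  # force P1 to lose one feature entirely via missingness (both plex blocks
  # of P1_f1 get > 3 missing), leaving it single-featured
  for (px in unique(d$plex)) {
    rows <- which(d$protein == "P1" & d$feature == "P1_f1" & d$plex == px)
    d$intensity[rows[1:5]] <- NA
  }
  ft2 <- featureTable(d, scale = "log2")
  out <- msstatsFilter(ft2)
  o <- featureData(out)
  expect_false("P5" %in% o$protein)   # shared
  expect_false("P1" %in% o$protein)   # single feature after (b)
  # oracle: replay the three rules naively
  dd <- d[!d$shared, ]
  blk <- paste(dd$protein, dd$feature, dd$plex)
  bad <- names(which(tapply(is.na(dd$intensity), blk, sum) > 3))
  dd <- dd[!blk %in% bad, ]
  nf <- tapply(dd$feature, dd$protein, function(x) length(unique(x)))
  dd <- dd[!dd$protein %in% names(nf)[nf < 2], ]
  expect_equal(nrow(o), nrow(dd))
  expect_setequal(unique(o$protein), unique(dd$protein))
  rep <- attr(out, "filter_report")
  expect_equal(rep$count_removed,
               c(sum(tapply(d$shared, paste(d$protein, d$feature), any)),
                 length(bad), sum(nf < 2)))
})

test_that("imputation reproduces additive blocks, flags fills, and never edits observed cells", {
  # noiseless additive block: value = feature effect + channel effect
  feat_eff <- c(f1 = 0, f2 = 1.5, f3 = -0.5)
  chan_eff <- seq(0, -2.7, length.out = 10)
  g <- expand.grid(feature = names(feat_eff), temperature_index = 0:9,
                   stringsAsFactors = FALSE)
  g$protein <- "P1"; g$plex <- "plexA"; g$condition <- "vehicle"
  g$replicate <- "r1"
  g$feature <- paste0("P1_", g$feature)
  g$temperature <- fix_temps[g$temperature_index + 1]
  g$intensity <- 15 + feat_eff[sub("P1_", "", g$feature)] +
    chan_eff[g$temperature_index + 1]
  truth <- g$intensity
  # the missing cell is a low-abundance one, below the remaining minimum
  hole <- which(g$feature == "P1_f3" & g$temperature_index == 9)
  g$intensity[hole] <- NA
  out <- aftImpute(featureTable(g, scale = "log2"))
  o <- featureData(out)
  expect_equal(o$intensity[hole], truth[hole], tolerance = 1e-6)
  expect_true(o$imputed[hole])
  expect_equal(o$intensity[-hole], truth[-hole])
  expect_false(any(o$imputed[-hole]))
  # block with no missing values is untouched
  g2 <- g; g2$intensity <- truth
  out2 <- aftImpute(featureTable(g2, scale = "log2"))
  expect_equal(featureData(out2)$intensity, truth)
})

test_that("features with too few observations are skipped and reported", {
  g <- data.frame(protein = "P1",
                  feature = rep(c("P1_f1", "P1_f2"), each = 4),
                  plex = "plexA", condition = "vehicle", replicate = "r1",
                  temperature_index = rep(0:3, 2),
                  temperature = rep(fix_temps[1:4], 2),
                  intensity = c(10, 9, 8, 7, 9.5, NA, NA, NA),
                  stringsAsFactors = FALSE)
  out <- aftImpute(featureTable(g, scale = "log2"))
  o <- featureData(out)
  expect_true(all(is.na(o$intensity[o$feature == "P1_f2"][-1])))
  rep <- attr(out, "impute_report")
  expect_equal(rep$feature, "P1_f2")
  expect_equal(rep$reason, "too_few_observed")
})

test_that("median polish matches hand results and two independent oracles", {
  # single feature: summary equals that feature's values
  g <- data.frame(protein = "P1", feature = "P1_f1", plex = "plexA",
                  condition = "vehicle", replicate = "r1",
                  temperature_index = 0:9, temperature = fix_temps,
                  intensity = seq(16, 11.5, by = -0.5),
                  stringsAsFactors = FALSE)
  out <- medianPolishSummarize(featureTable(g, scale = "log2"))
  expect_equal(profileData(out)$abundance, g$intensity)
  # two features offset by a constant: summary = f + delta/2
  g2 <- rbind(g, transform(g, feature = "P1_f2", intensity = intensity + 1))
  out2 <- medianPolishSummarize(featureTable(g2, scale = "log2"))
  expect_equal(profileData(out2)$abundance, g$intensity + 0.5)
  # random matrices vs the hand-coded oracle and stats::medpolish
  set.seed(13)
  for (i in 1:20) {
    nr <- sample(2:6, 1); nc <- sample(3:10, 1)
    m <- matrix(rnorm(nr * nc, 14, 1), nr, nc)
    gg <- expand.grid(fi = seq_len(nr), ci = seq_len(nc))
    g3 <- data.frame(protein = "P1", feature = paste0("f", gg$fi),
                     plex = "plexA", condition = "vehicle", replicate = "r1",
                     temperature_index = gg$ci - 1L,
                     temperature = gg$ci, intensity = m[cbind(gg$fi, gg$ci)],
                     stringsAsFactors = FALSE)
    got <- profileData(medianPolishSummarize(featureTable(g3,
                                                          scale = "log2")))
    got <- got$abundance[order(got$temperature_index)]
    expect_equal(got, unname(oracle_median_polish_summary(m)),
                 tolerance = 1e-8)
    mp <- stats::medpolish(m, eps = 1e-9, maxiter = 200, trace.iter = FALSE)
    expect_equal(got, unname(mp$overall + mp$col), tolerance = 1e-4)
  }
})

test_that("median polish is row-permutation invariant and shift equivariant", {
  set.seed(14)
  m <- matrix(rnorm(40, 14, 1), 4, 10)
  build <- function(mm) {
    gg <- expand.grid(fi = seq_len(nrow(mm)), ci = seq_len(ncol(mm)))
    featureTable(data.frame(
      protein = "P1", feature = paste0("f", gg$fi), plex = "plexA",
      condition = "vehicle", replicate = "r1",
      temperature_index = gg$ci - 1L, temperature = gg$ci,
      intensity = mm[cbind(gg$fi, gg$ci)], stringsAsFactors = FALSE),
      scale = "log2")
  }
  s1 <- profileData(medianPolishSummarize(build(m)))$abundance
  s2 <- profileData(medianPolishSummarize(build(m[c(3, 1, 4, 2), ])))$abundance
  expect_equal(s1, s2)
  s3 <- profileData(medianPolishSummarize(build(m + 2.5)))$abundance
  expect_equal(s3, s1 + 2.5)
})

test_that("reference-channel alignment shifts plexes to the median and is idempotent", {
  # two plexes with references 10 and 12 -> shifts +1 and -1
  g <- expand.grid(condition = c("vehicle", "treated"),
                   temperature_index = 0:9, stringsAsFactors = FALSE)
  g$protein <- "P1"; g$replicate <- ifelse(g$condition == "vehicle", "r1", "r1")
  g$temperature <- fix_temps[g$temperature_index + 1]
  g$abundance <- ifelse(g$condition == "vehicle", 10, 12) -
    0.3 * g$temperature_index
  tab <- proteinProfileTable(g, scale = "log2")
  out <- referenceChannelNormalize(tab)
  o <- profileData(out)
  expect_equal(o$abundance[o$condition == "vehicle"],
               g$abundance[g$condition == "vehicle"] + 1)
  expect_equal(o$abundance[o$condition == "treated"],
               g$abundance[g$condition == "treated"] - 1)
  refs <- o$abundance[o$temperature_index == 0]
  expect_true(all(refs == 11))
  out2 <- referenceChannelNormalize(out)
  expect_equal(profileData(out2)$abundance, o$abundance)
  # single plex: identity
  solo <- proteinProfileTable(g[g$condition == "vehicle", ], scale = "log2")
  expect_equal(profileData(referenceChannelNormalize(solo))$abundance,
               g$abundance[g$condition == "vehicle"])
})
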