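test_that("reference ratios equal brute-force per-group division", {
  tab <- random_protein_table(8, seed = 3)
  ratios <- ratioToReference(tab)
  d <- profileData(tab)
  r <- profileData(ratios)
  expect_true(all(r$abundance[r$temperature_index == 0] == 1))
  for (i in sample(nrow(r), 50)) {
    ref <- d$abundance[d$protein == r$protein[i] &
                         d$condition == r$condition[i] &
                         d$replicate == r$replicate[i] &
                         d$temperature_index == 0]
    raw <- d$abundance[d$protein == r$protein[i] &
                         d$condition == r$condition[i] &
                         d$replicate == r$replicate[i] &
                         d$temperature_index == r$temperature_index[i]]
    expect_equal(r$abundance[i], raw / ref)
  }
  # multiplying back by the reference column recovers the raw table exactly
  ref_map <- d[d$temperature_index == 0, ]
  key <- paste(r$protein, r$condition, r$replicate)
  refv <- ref_map$abundance[match(key, paste(ref_map$protein,
                                             ref_map$condition,
                                             ref_map$replicate))]
  expect_equal(r$abundance * refv, d$abundance)
})

test_that("groups with unusable reference values are excluded and reported", {
  tab <- random_protein_table(3, seed = 4)
  d <- profileData(tab)
  d$abundance[d$protein == "P001" & d$condition == "vehicle" &
                d$replicate == "r1" & d$temperature_index == 0] <- 0
  ratios <- ratioToReference(proteinProfileTable(d, scale = "raw"))
  dropped <- attr(ratios, "dropped")
  expect_equal(nrow(dropped), 1)
  expect_equal(dropped$protein, "P001")
  r <- profileData(ratios)
  expect_equal(nrow(r[r$protein == "P001", ]), 30)  # 3 of 4 groups remain
})

test_that("NormSet selection matches the exhaustive oracle and ignores protein order", {
  tab <- random_protein_table(20, seed = 5, noise = 0.25)
  ratios <- ratioToReference(tab)
  cfg <- processingConfig()
  ns <- buildNormSet(ratios, cfg)
  oracle <- oracle_normset(profileData(ratios), cfg@normset_bounds)
  expect_identical(ns, oracle)
  # ordering invariance
  d <- profileData(ratios)
  d2 <- d[rev(seq_len(nrow(d))), ]
  ns2 <- buildNormSet(proteinProfileTable(d2, scale = "ratio"), cfg)
  expect_identical(ns2, ns)
  # a protein breaching one bound in one replicate is excluded
  d3 <- d
  pick <- ns[1]
  d3$abundance[d3$protein == pick & d3$condition == "treated" &
                 d3$replicate == "r2" & d3$temperature_index == 9] <- 0.9
  ns3 <- buildNormSet(proteinProfileTable(d3, scale = "ratio"), cfg)
  expect_false(pick %in% ns3)
})

test_that("normalization factors undo a known per-temperature distortion", {
  # medians are a known sigmoid times a known distortion d_t constructed in
  # the orthogonal complement of the sigmoid's tangent space, so the curve
  # fit recovers the undistorted sigmoid to first order and
  # Q_t = fitted/median recovers 1/d_t
  set.seed(6)
  tt <- fix_temps
  f <- function(th) (1 - th[1]) / (1 + exp(th[3] - th[2] / tt)) + th[1]
  th0 <- c(0.1, 3036, 58.4)
  frac <- f(th0)
  J <- vapply(1:3, function(j) {
    h <- th0[j] * 1e-6
    thp <- th0; thp[j] <- thp[j] + h
    (f(thp) - frac) / h
  }, numeric(10))
  raw <- rnorm(10, 0, 0.01) * frac
  v <- raw - J %*% solve(crossprod(J), crossprod(J, raw))  # residual-space part
  distort <- as.vector(1 + v / frac)
  distort[1] <- 1
  g <- expand.grid(protein = sprintf("P%02d", 1:11),
                   condition = "vehicle", replicate = "r1",
                   temperature_index = 0:9, stringsAsFactors = FALSE)
  g$temperature <- tt[g$temperature_index + 1]
  g$abundance <- (frac * distort / (frac[1] * distort[1]))[
    g$temperature_index + 1]
  tab <- proteinProfileTable(g, scale = "ratio")
  nf <- computeNormFactors(tab, unique(g$protein))
  expect_equal(unname(nf@Q[as.character(1:9)]), 1 / distort[2:10],
               tolerance = 1e-3)
})

test_that("the best-R2 group is chosen and exact sigmoid medians give unit factors", {
  set.seed(7)
  tt <- fix_temps
  frac <- (1 - 0.1) / (1 + exp(58.4 - 3036 / tt)) + 0.1
  ratio <- frac / frac[1]
  g <- expand.grid(protein = sprintf("P%02d", 1:11),
                   condition = c("vehicle", "treated"),
                   replicate = c("r1", "r2"), temperature_index = 0:9,
                   stringsAsFactors = FALSE)
  g$temperature <- tt[g$temperature_index + 1]
  # group-level jitter survives the median over proteins; the vehicle/r1
  # group is an exact sigmoid, the rest are visibly non-sigmoidal
  jit <- exp(rnorm(40, 0, 0.15))
  gid <- (match(paste(g$condition, g$replicate),
                unique(paste(g$condition, g$replicate))) - 1) * 10 +
    g$temperature_index + 1
  jitv <- ifelse(g$condition == "vehicle" & g$replicate == "r1", 1, jit[gid])
  jitv[g$temperature_index == 0] <- 1
  g$abundance <- ratio[g$temperature_index + 1] * jitv
  nf <- computeNormFactors(proteinProfileTable(g, scale = "ratio"),
                           unique(g$protein))
  expect_identical(unname(nf@condition), "vehicle")
  expect_identical(unname(nf@replicate), "r1")
  expect_equal(unname(nf@Q), rep(1, 10), tolerance = 1e-6)
})

test_that("factor application is an elementwise product that fixes the reference", {
  tab <- ratioToReference(random_protein_table(4, seed = 8))
  Q <- setNames(c(1, seq(1.1, 1.9, by = 0.1)), 0:9)
  nf <- new("NormFactors", Q = Q, condition = "vehicle", replicate = "r1",
            normset = "P001", fit_r2 = 1)
  out <- applyNormFactors(tab, nf)
  d0 <- profileData(tab); d1 <- profileData(out)
  expect_equal(d1$abundance, d0$abundance * Q[as.character(d0$temperature_index)],
               ignore_attr = TRUE)
  expect_true(all(d1$abundance[d1$temperature_index == 0] == 1))
  # missing factor index errors
  expect_error(applyNormFactors(tab, new("NormFactors",
                                         Q = Q[1:5], condition = "vehicle",
                                         replicate = "r1", normset = "x",
                                         fit_r2 = 1)), "missing Q_t")
})

test_that("log2 transform handles missingness and rejects non-positive values", {
  g <- profileData(random_protein_table(2, seed = 9))
  g$abundance[3] <- NA
  out <- log2Transform(proteinProfileTable(g, scale = "raw"))
  expect_true(is.na(profileData(out)$abundance[3]))
  expect_equal(profileData(out)$abundance[-3], log2(g$abundance[-3]))
  g$abundance[5] <- 0
  expect_error(log2Transform(proteinProfileTable(g, scale = "raw")),
               "non-positive")
})

test_that("global median normalization equalizes channel medians", {
  tab <- log2Transform(random_protein_table(10, seed = 10))
  d <- profileData(tab)
  d$abundance <- d$abundance + as.integer(factor(d$temperature_index)) * 0.3
  out <- globalMedianNormalize(proteinProfileTable(d, scale = "log2"))
  o <- profileData(out)
  meds <- tapply(o$abundance, paste(o$condition, o$replicate,
                                    o$temperature_index), median)
  expect_lt(diff(range(meds)), 1e-10)
  # already-equal medians: identity
  out2 <- globalMedianNormalize(out)
  expect_equal(profileData(out2)$abundance, o$abundance)
  # brute-force per-channel shift
  ch <- paste(d$condition, d$replicate, d$temperature_index)
  m <- tapply(d$abundance, ch, median)
  expect_equal(o$abundance, d$abundance - unname(m[ch]) + median(m))
})
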