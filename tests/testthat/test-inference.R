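test_that("the F statistic follows its closed form and matches the anova oracle", {
  expect_equal(fStatistic(1, 1, 1, 10)$statistic, 0)
  expect_equal(fStatistic(1, 1, 1, 10)$pvalue, 1)
  expect_equal(fStatistic(2, 1, 1, 10)$statistic, 10)
  zero <- fStatistic(2, 0, 1, 10)
  expect_true(is.infinite(zero$statistic) && zero$pvalue == 0 && zero$flagged)
  # clipping of negative numerators from numerical noise
  expect_equal(fStatistic(1 - 1e-14, 1, 3, 8)$pvalue, 1)
  set.seed(30)
  for (i in 1:30) {
    n <- 40
    x <- rnorm(n); z <- rnorm(n); y <- rnorm(n)
    full <- lm(y ~ x + z); red <- lm(y ~ x)
    ft <- fStatistic(sum(resid(red)^2), sum(resid(full)^2), 1, n - 3)
    oracle <- anova(red, full)
    expect_equal(ft$statistic, oracle$F[2], tolerance = 1e-10)
    expect_equal(ft$pvalue, oracle$`Pr(>F)`[2], tolerance = 1e-10)
  }
})

test_that("moderation parameters are recovered and degenerate cases collapse correctly", {
  set.seed(31)
  d0 <- 4; s0 <- 0.25; d2 <- 12
  s_sq <- s0 * rf(5000, d2, d0)
  got <- estimateModeration(s_sq, d2)
  expect_lt(abs(got$d0 - d0) / d0, 0.10)
  expect_lt(abs(got$s0_sq - s0) / s0, 0.10)
  # identical variances: d0 infinite, shrunken variance equals the common one
  same <- estimateModeration(rep(0.4, 50), d2)
  expect_true(is.infinite(same$d0))
  expect_equal(same$s0_sq, 0.4, tolerance = 1e-6)
  mf_inf <- moderatedF(2, 1, 2, d2, same, s_sq = 1 / d2)
  expect_equal(mf_inf$s_tilde_sq, 0.4, tolerance = 1e-6)
  expect_error(estimateModeration(rep(0.5, 5), d2), "plain F")
})

test_that("moderated F with d0 = 0 is bit-for-bit the plain F", {
  set.seed(32)
  for (i in 1:20) {
    rss1 <- rchisq(1, 8); rss0 <- rss1 + rchisq(1, 2)
    plain <- fStatistic(rss0, rss1, 2, 8)
    mod <- moderatedF(rss0, rss1, 2, 8, list(d0 = 0, s0_sq = 1))
    expect_identical(mod$statistic, plain$statistic)
    expect_identical(mod$pvalue, plain$pvalue)
  }
})

test_that("moderated null p-values are uniform", {
  set.seed(33)
  n <- 2000; d1 <- 2; d2 <- 8
  rss1 <- 0.3 * rchisq(n, d2)
  rss0 <- rss1 + 0.3 * rchisq(n, d1)
  params <- estimateModeration(rss1 / d2, d2)
  p <- vapply(seq_len(n), function(i)
    moderatedF(rss0[i], rss1[i], d1, d2, params,
               s_sq = rss1[i] / d2)$pvalue, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("empirical-Bayes degrees of freedom are recovered and scale-invariant", {
  set.seed(34)
  d1 <- 2.5; d2 <- 8; s0 <- 0.3
  delta <- s0 * rchisq(5000, d1)
  rss1 <- s0 * rchisq(5000, d2)
  eb <- nparcEbInference(delta, rss1)
  expect_lt(abs(eb$params$d1 - d1) / d1, 0.10)
  expect_lt(abs(eb$params$d2 - d2) / d2, 0.10)
  expect_lt(abs(eb$params$sigma0_sq - s0) / s0, 0.10)
  # a protein with RSS0 = RSS1 gets p = 1
  eb0 <- nparcEbInference(c(0, delta[1:99]), rss1[1:100])
  expect_equal(eb0$pvalue[1], 1)
  # doubling both collections leaves the p-values unchanged
  eb2 <- nparcEbInference(2 * delta, 2 * rss1)
  expect_equal(eb2$pvalue, eb$pvalue, tolerance = 1e-6)
})

test_that("the SCAM Wald test converts DIM to a two-sided normal p-value", {
  mk <- function(dim, se) new("ScamFit", k = 5L, dim = dim, dim_se = se,
                              sigma_bio_sq = 0.1, sigma_error_sq = 0.2,
                              smooths = list(), converged = TRUE,
                              n_obs = 40L)
  expect_equal(scamDimTest(mk(0, 1), "p")$pvalue, 1)
  expect_equal(scamDimTest(mk(1.96, 1), "p")$pvalue, 0.05, tolerance = 1e-3)
  expect_identical(scamDimTest(mk(1, 0), "p")$decision, "failed")
})

test_that("BH adjustment matches the hand step-up oracle and preserves order", {
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(35)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("sigmoid quality filters exclude exact boundary values", {
  mk <- function(r2, p) new("SigmoidFit", p = p, a = 1000, b = 20, tm = 50,
                            r2 = r2, rss = 0.1, converged = TRUE,
                            n_obs = 20L)
  fits <- list(
    keep = list(vehicle = mk(0.85, 0.2), treated = mk(0.9, 0.1)),
    r2_boundary = list(vehicle = mk(0.8, 0.2), treated = mk(0.9, 0.1)),
    plateau_boundary = list(vehicle = mk(0.85, 0.3), treated = mk(0.9, 0.1)),
    one_side = list(vehicle = mk(0.5, 0.2), treated = mk(0.9, 0.1)))
  keep <- nparcPostfilter(fits)
  expect_identical(unname(keep),
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_true(nparcPostfilter(fits, rule = "any")[["one_side"]])
  # crossing each boundary by epsilon flips the decision
  eps <- 1e-9
  expect_true(nparcPostfilter(list(x = list(v = mk(0.8 + eps, 0.3 - eps))))[["x"]])
  expect_false(nparcPostfilter(list(x = list(v = mk(0.8 - eps, 0.3 - eps))))[["x"]])
})

test_that("the replicate-level sigmoid decision enforces all four criteria", {
  expect_identical(
    tppSigmoidDecision(c(2, 1.5), c(0.01, 0.03), c(0.9, 0.7),
                       rep(0.1, 4)), "interactor")
  expect_identical(
    tppSigmoidDecision(c(2, -1), c(0.01, 0.03), c(0.9, 0.7),
                       rep(0.1, 4)), "non-interactor")
  expect_identical(
    tppSigmoidDecision(c(2, 1.5), c(0.01, 0.06), c(0.9, 0.7),
                       rep(0.1, 4)), "non-interactor")
  expect_identical(
    tppSigmoidDecision(c(2, 1.5), c(0.01, 0.03), c(0.75, 0.7),
                       rep(0.1, 4)), "non-interactor")
  expect_identical(
    tppSigmoidDecision(c(2, 1.5), c(0.01, 0.03), c(0.9, 0.7),
                       c(0.1, 0.3, 0.1, 0.1)), "non-interactor")
  expect_identical(
    tppSigmoidDecision(c(2, NA), c(0.01, 0.03), c(0.9, 0.7),
                       rep(0.1, 4)), "failed")
})

test_that("plain-F null p-values on simulated nested linear models are uniform", {
  set.seed(36)
  n_sim <- 2000
  p <- vapply(seq_len(n_sim), function(i) {
    y <- rnorm(20); x <- rnorm(20)
    full <- lm.fit(cbind(1, x, x^2), y)
    red <- lm.fit(cbind(1, x), y)
    fStatistic(sum(red$residuals^2), sum(full$residuals^2), 1, 17)$pvalue
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(n_sim))
})

test_that("the subset contrast reduces to the pooled two-sample t in the one-temperature case", {
  set.seed(37)
  d <- expand.grid(condition = c("vehicle", "treated"),
                   replicate = paste0("r", 1:6), temperature_index = 5L,
                   stringsAsFactors = FALSE)
  d$abundance <- rnorm(nrow(d))
  fit <- fitMixed(d, drop_reference = FALSE)
  res <- mixedContrastTest(fit, 5L)
  tt <- t.test(abundance ~ condition, data = d, var.equal = TRUE)
  # both orderings are treated-first here (R sorts factor levels)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$df2, unname(tt$parameter))
  expect_equal(res$pvalue, tt$p.value, tolerance = 1e-10)
})

test_that("identical conditions give a zero contrast with p = 1", {
  d <- expand.grid(condition = c("vehicle", "treated"),
                   replicate = c("r1", "r2"), temperature_index = 1:9,
                   stringsAsFactors = FALSE)
  set.seed(38)
  base <- rnorm(18)
  d$abundance <- base[match(paste(d$replicate, d$temperature_index),
                            unique(paste(d$replicate, d$temperature_index)))]
  fit <- fitMixed(d, drop_reference = FALSE)
  res <- mixedContrastTest(fit, c(6, 7, 8))
  expect_equal(res$estimate, 0)
  expect_equal(res$pvalue, 1)
})

test_that("null subset contrasts are calibrated at ICC 5%", {
  cal <- runSimulationStudy(templates = "null", designs = "T-F",
                            sigma_bio_sq = 0.014, n_instances = 1000,
                            seed = 1)
  prop <- cal$power$proportion[cal$power$cutoff == 0.05]
  expect_gte(prop, 0.032)
  expect_lte(prop, 0.068)
})

test_that("group-comparison ANOVA has the right residual df and uniform null p-values", {
  # Dataset-3b-like shape: 5 conditions x 3 replicates
  g <- expand.grid(condition = c("vehicle", "c1", "c5", "c10", "c25"),
                   replicate = c("r1", "r2", "r3"), stringsAsFactors = FALSE)
  g$protein <- "P1"; g$temperature_index <- NA; g$temperature <- NA
  set.seed(39)
  g$abundance <- rnorm(nrow(g), 15)
  res <- anovaGroupComparison(proteinProfileTable(g, scale = "log2"))
  expect_equal(unique(res$df2), 10)
  expect_equal(nrow(res), 4)
  # identical sample values: estimate 0, p = 1
  g2 <- g[g$condition %in% c("vehicle", "c1"), ]
  g2$abundance <- rep(c(14, 15, 16), 2)
  res2 <- anovaGroupComparison(proteinProfileTable(g2, scale = "log2"),
                               comparisons = list(c("c1", "vehicle")))
  expect_equal(res2$estimate, 0)
  expect_equal(res2$pvalue, 1)
  # null uniformity over 1000 two-condition simulations
  set.seed(40)
  p <- vapply(1:1000, function(i) {
    gg <- g[g$condition %in% c("vehicle", "c1"), ]
    gg$abundance <- rnorm(6)
    anovaGroupComparison(proteinProfileTable(gg, scale = "log2"),
                         comparisons = list(c("c1", "vehicle")))$pvalue
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1000))
})
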