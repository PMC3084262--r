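test_that("noiseless single-recruiter dataset reproduces the recruiter column", {
  cfg <- sim_config(n_regions = 50, weights = c(A = 1), intercept = 0,
                    noise_sd = 0, missing_rate = 0)
  d <- generate_dataset(cfg, seed = 3)
  expect_equal(unname(d$occupancy[, "TUP1"]), unname(d$occupancy[, "A"]))
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- small_config()
  d1 <- generate_dataset(cfg, seed = 10)
  d2 <- generate_dataset(cfg, seed = 10)
  d3 <- generate_dataset(cfg, seed = 11)
  expect_identical(d1$occupancy, d2$occupancy)
  expect_identical(d1$regions, d2$regions)
  expect_false(identical(d1$occupancy, d3$occupancy))
})

test_that("dataset dimensions, missingness and region layout obey the config", {
  cfg <- sim_config(n_regions = 2000, decoys = c("D1", "D2"))
  d <- generate_dataset(cfg, seed = 5)
  expect_equal(nrow(d$occupancy), 2000L)
  expect_equal(colnames(d$occupancy),
               c(names(cfg$weights), "D1", "D2", "TUP1"))
  # missing fraction within 2 points of the configured 5% on recruiter columns
  miss <- mean(is.na(d$occupancy[, cfg$factors]))
  expect_lt(abs(miss - cfg$missing_rate), 0.02)
  expect_false(anyNA(d$occupancy[, "TUP1"]))
  # regions: 0-based half-open, unique ids, non-overlapping per chromosome
  r <- d$regions
  expect_true(all(r$start < r$end))
  expect_false(anyDuplicated(r$region_id) > 0)
  by_chrom <- split(r, r$chrom)
  expect_true(all(vapply(by_chrom, function(b) {
    b <- b[order(b$start), ]
    all(head(b$end, -1) <= tail(b$start, -1))
  }, logical(1))))
})

test_that("noise calibration yields the target genome-wide R-squared", {
  cfg <- sim_config(n_regions = 6000)
  d <- generate_dataset(cfg, seed = 21)
  fit <- lm(d$occupancy[, "TUP1"] ~ d$truth$latent_occupancy)
  expect_lt(abs(summary(fit)$r.squared - 0.43), 0.04)
})

test_that("complete-case OLS on generated data recovers planted weights", {
  # per-coefficient 95% CI coverage across (seed, recruiter) pairs
  cfg <- sim_config(n_regions = 3000)
  covered <- vapply(1:10, function(s) {
    d <- generate_dataset(cfg, seed = s)
    df <- data.frame(y = d$occupancy[, "TUP1"], d$occupancy[, cfg$factors])
    fit <- lm(y ~ ., data = df[complete.cases(df), ])
    ci <- confint(fit)[names(cfg$weights), ]
    mean(cfg$weights >= ci[, 1] & cfg$weights <= ci[, 2])
  }, numeric(1))
  expect_gte(mean(covered), 0.9)
})

test_that("invalid generator configs are rejected", {
  expect_error(sim_config(n_regions = 5), "invalid-config")
  expect_error(sim_config(missing_rate = 1.2), "invalid-config")
  expect_error(generate_replicates(1:10, n_reps = 0), "invalid-config")
  d <- generate_dataset(small_config(), seed = 1)
  expect_error(generate_deletion_profile(d, "NOPE"), "unknown-factor")
})

test_that("replicates are noisy copies whose mean converges to the profile", {
  profile <- rnorm(500, sd = 2)
  r0 <- generate_replicates(profile, 3, rep_noise_sd = 0, seed = 2)
  expect_equal(r0[, 1], r0[, 2])
  expect_equal(unname(r0[, 3]), profile)
  # CLT bound: mean of 21 unit-noise replicates within 3/sqrt(21) of the
  # profile for at least 99% of regions
  r <- generate_replicates(profile, 21, rep_noise_sd = 1, seed = 4)
  dev <- abs(rowMeans(r) - profile)
  expect_gte(mean(dev < 3 / sqrt(21)), 0.99)
})

test_that("deletion profiles interpolate between redundant and dependent", {
  cfg <- sim_config(n_regions = 40, weights = c(A = 0.8, B = 0.3),
                    intercept = 0.1, noise_sd = 0, missing_rate = 0)
  d <- generate_dataset(cfg, seed = 6)
  y <- d$occupancy[, "TUP1"]
  x <- d$truth$latent_occupancy
  # fully redundant: unchanged (noiseless regime)
  expect_equal(unname(generate_deletion_profile(d, "A", redundancy = 1)),
               unname(y))
  # fully dependent: drops by beta_A * x_A
  expect_equal(unname(generate_deletion_profile(d, "A", redundancy = 0)),
               unname(y - 0.8 * x[, "A"]))
  # half redundancy matches hand computation of intercept + sum(beta x)
  hand <- 0.1 + 0.8 * 0.5 * x[, "A"] + 0.3 * x[, "B"]
  expect_equal(unname(generate_deletion_profile(d, "A", redundancy = 0.5)),
               unname(hand))
})

test_that("sequence generation plants recoverable sites and is deterministic", {
  set.seed(8)
  p <- random_pwm("FAC", width = 6)
  d <- generate_dataset(small_config(n_regions = 30), seed = 2)
  targets <- d$regions$region_id[1:10]
  gs <- generate_sequences(d$regions, list(FAC = p),
                           plant = list(FAC = targets), seed = 12)
  expect_setequal(gs$sites$region_id, targets)
  expect_true(all(gs$sites$offset >= 0))
  widths <- Biostrings::width(gs$sequences)
  expect_equal(unname(widths), d$regions$end - d$regions$start)
  gs2 <- generate_sequences(d$regions, list(FAC = p),
                            plant = list(FAC = targets), seed = 12)
  expect_identical(as.character(gs$sequences), as.character(gs2$sequences))
  # a region shorter than the motif is refused
  short <- data.frame(region_id = "r", chrom = "chr1", start = 0, end = 4)
  expect_error(generate_sequences(short, list(FAC = p), seed = 1),
               "region-too-short")
})

test_that("unplanted sequences carry only background-level motif hits", {
  set.seed(13)
  p <- random_pwm("FAC", width = 8)
  regions <- data.frame(region_id = sprintf("r%03d", 1:300), chrom = "chr1",
                        start = seq(0, by = 400, length.out = 300))
  regions$end <- regions$start + 300
  gs <- generate_sequences(regions, list(FAC = p), plant = list(), seed = 14)
  thr <- 1e-4
  hits <- pwm_hit_regions(gs$sequences, p, thr)
  # expected per-region hit probability from the exact null tail at the
  # integer threshold actually applied
  dist <- pwm_score_distribution(p)
  t_int <- corecruit:::pwm_score_threshold(dist, thr)
  p_pos <- corecruit:::pwm_score_pvalue(dist, t_int)
  n_windows <- 2 * (300 - 8 + 1)
  expected <- 1 - (1 - p_pos)^n_windows
  expect_lte(mean(hits), 3 * expected + 3 * sqrt(expected / 300) + 0.01)
})

test_that("expression changes track occupancy with the configured slope", {
  d <- generate_dataset(sim_config(n_regions = 2500), seed = 9)
  gm <- make_gene_map(d$regions, mapped_fraction = 0.8, seed = 3)
  y <- d$occupancy[, "TUP1"]

  # slope 0: no association
  e0 <- generate_expression(d, gm, slope = 0, noise_sd = 1, seed = 4)
  r0 <- cor(e0$log2_change, y[e0$region_id])
  expect_lt(abs(r0), 0.1)

  # positive slope, no noise: perfect correlation over mapped genes
  e1 <- generate_expression(d, gm, slope = 2, noise_sd = 0, seed = 5)
  expect_equal(cor(e1$log2_change, y[e1$region_id]), 1)

  # slope 1, unit noise: r = sd_y / sqrt(sd_y^2 + 1) within sampling error
  e2 <- generate_expression(d, gm, slope = 1, noise_sd = 1, seed = 6)
  r2 <- cor(e2$log2_change, y[e2$region_id])
  expected <- sd(y) / sqrt(sd(y)^2 + 1)
  expect_lt(abs(r2 - expected), 0.05)
  expect_gt(r2, 0.5)
  expect_lt(r2, 0.9)

  bad_map <- data.frame(gene_id = "g", region_id = "absent",
                        orientation = "+")
  expect_error(generate_expression(d, bad_map, seed = 1), "unknown-region")
})
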