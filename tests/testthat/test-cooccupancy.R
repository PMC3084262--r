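test_that("target classification partitions by cofactor evidence", {
  pv <- matrix(c(0.0005, 0.02, NA,
                 NA, NA, NA), ncol = 2,
               dimnames = list(c("r1", "r2", "r3"), c("TF1", "TF2")))
  pv["r1", 2] <- 0.5
  pv["r2", 2] <- 0.3
  cl <- classify_targets(c("r1", "r2", "r3"), pv, p_bind = 0.001)
  expect_equal(cl$status, c("co-occupied", "not-co-occupied", "no-data"))
  expect_equal(cl$cofactors_bound[1], "TF1")
  counts <- attr(cl, "counts")
  expect_equal(sum(counts), 3L)  # conservation

  # threshold limit: everything with data is co-occupied
  cl1 <- classify_targets(c("r1", "r2"), pv, p_bind = 1)
  expect_true(all(cl1$status == "co-occupied"))

  pv_na <- matrix(NA_real_, 2, 2,
                  dimnames = list(c("r1", "r2"), c("a", "b")))
  expect_true(all(classify_targets(c("r1", "r2"), pv_na)$status == "no-data"))
  expect_error(classify_targets("absent", pv), "empty-join")
})

test_that("recruiter-count bins summarise occupancy per count", {
  d <- generate_dataset(sim_config(n_regions = 2000), seed = 17)
  y <- d$occupancy[, "TUP1"]
  b <- bin_by_recruiter_count(y, d$pvalues, names(default_recruiter_weights()))
  expect_equal(sum(b$n_targets), 2000L)
  # positive planted weights: mean occupancy increases with count (k 0..3)
  expect_true(all(diff(b$mean_z[b$k <= 3]) > 0))

  # single target gets its own bin with se 0 and a flag
  one <- bin_by_recruiter_count(c(r1 = 2), d$pvalues[1, , drop = FALSE],
                                "SUT1")
  expect_equal(one$se_z, 0)
  expect_true(one$single_member)

  # all recruiters unbound: one k=0 bin
  pv_high <- matrix(0.9, 3, 2, dimnames = list(paste0("r", 1:3), c("a", "b")))
  all0 <- bin_by_recruiter_count(setNames(1:3, paste0("r", 1:3)), pv_high,
                                 c("a", "b"))
  expect_equal(all0$k, 0L)
  expect_equal(all0$n_targets, 3L)
})

test_that("count regression matches the closed-form OLS oracle", {
  # frozen from the closed form: x=0..4, y=(1,2,3,5,4):
  # slope = Sxy/Sxx = 9/10, intercept = 3 - 0.9*2, R2 = slope*Sxy/Syy
  r <- regress_on_count(c(1, 2, 3, 5, 4), 0:4)
  expect_equal(r$slope, 0.9, tolerance = 1e-9)
  expect_equal(r$intercept, 1.2, tolerance = 1e-9)
  expect_equal(r$r_squared, 0.81, tolerance = 1e-9)

  y_lin <- 2 + 3 * (0:9)
  r1 <- suppressWarnings(regress_on_count(y_lin, 0:9))  # exact fit
  expect_equal(r1$r_squared, 1)

  set.seed(18)
  y <- rnorm(1000)
  counts <- sample(rep(0:4, 200))
  expect_lt(regress_on_count(y, counts)$r_squared, 0.02)
  expect_error(regress_on_count(1:5, rep(2, 5)), "degenerate-regressor")
})

test_that("reference scaling equalises bound-region means", {
  ids <- paste0("r", 1:10)
  ref <- setNames(rnorm(10) + 2, ids)
  profs <- list(wt = ref, double = ref * 2,
                other = setNames(rnorm(10) + 1, ids))
  scaled <- scale_to_reference(profs, bound_region_ids = ids[1:6])
  sf <- attr(scaled, "scale_factors")
  expect_equal(unname(sf["wt"]), 1)
  expect_equal(unname(sf["double"]), 0.5)
  means <- vapply(scaled, function(p) mean(p[ids[1:6]]), numeric(1))
  expect_lt(max(means) - min(means), 1e-9)
  # invariance to positive rescaling of any input
  profs2 <- profs
  profs2$other <- profs$other * 7
  scaled2 <- scale_to_reference(profs2, ids[1:6])
  expect_equal(scaled2$other, scaled$other)
  zero <- list(wt = ref, bad = setNames(rep(0, 10), ids))
  expect_error(scale_to_reference(zero, ids[1:6]), "unscalable-profile")
})

test_that("group comparison detects real losses and reports exact ties", {
  set.seed(19)
  ids <- sprintf("r%03d", 1:150)
  wt <- setNames(rnorm(150, mean = 2, sd = 0.5), ids)
  groups <- list(g1 = ids[1:50], g2 = ids[51:100])

  same <- group_comparison(wt, wt, groups)
  expect_true(all(same$p_value == 1))

  del <- wt
  del[groups$g1] <- del[groups$g1] - 2
  shifted <- group_comparison(wt, del, groups)
  expect_lt(shifted$p_value[1], 1e-10)
  expect_gt(shifted$p_value[2], 0.9)

  expect_warning(group_comparison(wt, del, list(tiny = ids[1])),
                 "insufficient-group")
})

test_that("fully redundant deletion leaves every cofactor group unchanged", {
  cfg <- sim_config(n_regions = 3000)
  d <- generate_dataset(cfg, seed = 23)
  y <- d$occupancy[, "TUP1"]
  del <- generate_deletion_profile(d, "SUT1", redundancy = 1, seed = 24)
  # scale over ground-truth targets: selecting reference regions on the
  # noisy measurement itself would bias the scale factor upward
  bound_ids <- d$truth$planted_target_ids
  scaled <- scale_to_reference(list(wt = y, del = del), bound_ids)
  groups <- lapply(c(SUT1 = "SUT1", NRG1 = "NRG1", CUP9 = "CUP9"),
                   function(f) rownames(d$pvalues)[
                     !is.na(d$pvalues[, f]) & d$pvalues[, f] < 0.001])
  cmp <- group_comparison(scaled$wt, scaled$del, groups)
  pooled_se <- sqrt(cmp$se_wt^2 + cmp$se_del^2)
  expect_true(all(abs(cmp$mean_wt - cmp$mean_del) < 3 * pooled_se))
  expect_true(all(cmp$p_value > 0.001))
})

test_that("derepression test is calibrated under the null and powered", {
  set.seed(26)
  gm <- data.frame(gene_id = sprintf("g%04d", 1:1100),
                   region_id = sprintf("r%04d", 1:1100))
  bound_ids <- gm$region_id[1:100]
  unbound_ids <- gm$region_id[101:1100]

  pvals <- replicate(500, {
    ex <- data.frame(gene_id = gm$gene_id, log2_change = rnorm(1100))
    derepression_test(ex, bound_ids, unbound_ids, gm)$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  shifted_p <- replicate(20, {
    ex <- data.frame(gene_id = gm$gene_id,
                     log2_change = rnorm(1100) +
                       c(rep(1, 100), rep(0, 1000)))
    derepression_test(ex, bound_ids, unbound_ids, gm)$p_value
  })
  expect_true(all(shifted_p < 1e-5))

  ex <- data.frame(gene_id = gm$gene_id, log2_change = rnorm(1100))
  expect_error(derepression_test(ex, character(0), unbound_ids, gm),
               "empty-group")
})

test_that("decile binning orders genes by derepression", {
  ids <- sprintf("r%02d", 1:20)
  gm <- data.frame(gene_id = sprintf("g%02d", 1:20), region_id = ids)
  z <- setNames(seq(0.1, 2, length.out = 20), ids)
  ex <- data.frame(gene_id = gm$gene_id, log2_change = unname(z))
  bins <- decile_binning(ex, z, gm)
  expect_equal(bins$n, rep(2L, 10))
  expect_true(all(diff(bins$mean_z) > 0))

  # 10 genes into 10 bins: one gene per bin, in expression order
  bins1 <- decile_binning(ex[1:10, ], z, gm[1:10, ])
  expect_equal(bins1$n, rep(1L, 10))
  expect_equal(bins1$mean_change, sort(ex$log2_change[1:10]))

  # independent expression: bin means flat relative to their noise
  set.seed(27)
  ids5k <- sprintf("r%04d", 1:5000)
  gm5k <- data.frame(gene_id = sprintf("g%04d", 1:5000), region_id = ids5k)
  z5k <- setNames(rnorm(5000), ids5k)
  ex5k <- data.frame(gene_id = gm5k$gene_id, log2_change = rnorm(5000))
  b5k <- decile_binning(ex5k, z5k, gm5k)
  se <- 1 / sqrt(500)
  expect_lt(max(b5k$mean_z) - min(b5k$mean_z), 4 * se)

  expect_error(decile_binning(ex[1:5, ], z, gm[1:5, ]), "insufficient-genes")
})
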