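test_that("simulation_config rejects invalid fields, naming them", {
  expect_error(simulation_config(seed = 1, pool_size = 5,
                                 group_sizes = c(LM = 4, PER = 4, M0 = 3)),
               "pool_size")
  expect_error(simulation_config(seed = 1, noise_sd = -0.1), "noise_sd")
  expect_error(simulation_config(seed = 1, baseline_ct_range = c(30, 20)),
               "baseline_ct_range")
  expect_error(simulation_config(seed = 1,
                                 classifier_positive_prob = c(LM = 1.2, PER = 0, M0 = 0)),
               "classifier_positive_prob")
  expect_error(simulation_config(n_targets = 10, seed = 1,
                                 planted_effects = data.frame(
                                   assay_id = "RNU44", group = "PER", log2fc = 1)),
               "non-target")
  expect_error(simulation_config(10), "seed")
})

test_that("identical config yields bit-identical cohorts", {
  cfg <- simulation_config(n_targets = 50, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(unclass(a$ct), unclass(b$ct))
  expect_identical(a$manifest, b$manifest)
})

test_that("zero noise, zero effect: target CT identical across patients", {
  cfg <- simulation_config(n_targets = 30, noise_sd = 0, seed = 5)
  sim <- simulate_cohort(cfg)
  v <- unclass(sim$ct)[sprintf("syn-miR-%04d", 1:30), ]
  spread <- apply(v, 1L, function(r) diff(range(r)))
  expect_true(all(is.na(spread) | spread == 0))
})

test_that("zero noise, planted +2 in PER: CT exactly 2 cycles below LM", {
  cfg <- simulation_config(
    n_targets = 10, noise_sd = 0, seed = 11,
    planted_effects = data.frame(assay_id = "syn-miR-0001",
                                 group = "PER", log2fc = 2))
  sim <- simulate_cohort(cfg)
  g <- sim$manifest$group
  ct_lm <- unclass(sim$ct)["syn-miR-0001", g == "LM"]
  ct_per <- unclass(sim$ct)["syn-miR-0001", g == "PER"]
  expect_equal(unique(ct_lm - rep(ct_per, length.out = length(ct_lm))),
               2, tolerance = 1e-12)
})

test_that("Monte-Carlo: mean CT gap across seeds recovers the planted effect", {
  gaps <- vapply(1:200, function(s) {
    cfg <- simulation_config(
      n_targets = 5, noise_sd = 0.25, detection_ceiling = Inf, seed = s,
      planted_effects = data.frame(assay_id = "syn-miR-0001",
                                   group = "PER", log2fc = 2))
    sim <- simulate_cohort(cfg)
    g <- sim$manifest$group
    mean(unclass(sim$ct)["syn-miR-0001", g == "LM"]) -
      mean(unclass(sim$ct)["syn-miR-0001", g == "PER"])
  }, numeric(1))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 2), 3 * se)
})

test_that("manifest mirrors the cohort design and classifier probabilities", {
  cfg <- simulation_config(n_targets = 5, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_equal(group_census(sim$manifest), c(LM = 10L, PER = 10L, M0 = 3L))
  m <- sim$manifest
  # degenerate probabilities are deterministic
  expect_true(all(m$classifier_positive[m$group == "LM"] == 1L))
  expect_true(all(m$classifier_positive[m$group == "M0"] == 0L))
  # negative control never amplifies
  expect_true(all(is.na(unclass(sim$ct)["ath-miR-159a", ])))
})

test_that("detection ceiling turns high-CT wells non-detected", {
  cfg <- simulation_config(n_targets = 200, noise_sd = 0, seed = 17,
                           detection_ceiling = 35)
  sim <- simulate_cohort(cfg)
  v <- unclass(sim$ct)[sprintf("syn-miR-%04d", 1:200), ]
  expect_true(all(v[!is.na(v)] <= 35))
  expect_gt(sum(is.na(v)), 0)  # uniform 18-38 baselines must cross 35
})

test_that("pooling identical CTs is the identity and known mixes match arithmetic", {
  v <- matrix(20, nrow = 2, ncol = 3,
              dimnames = list(c("t1", "RNU44"), c("LM_01", "LM_02", "LM_03")))
  v["t1", ] <- c(20, 20, 23)
  ct <- ct_matrix(rbind(v, t2 = c(20, 20, 20)))
  man <- sample_manifest(colnames(v), rep("LM", 3))
  p <- pool_patients(ct, man, 3, seed = 1)
  expect_equal(unclass(p$ct)["t2", "LM_pool"], 20)
  expect_equal(unclass(p$ct)["t1", "LM_pool"],
               -log2(mean(2^-c(20, 20, 23))), tolerance = 1e-12)
  expect_equal(round(unclass(p$ct)["t1", "LM_pool"], 3), 20.497)
})

test_that("pooled CT lies between contributing extremes and is monotone", {
  set.seed(42)
  for (i in 1:20) {
    cts <- runif(3, 18, 32)
    ct <- ct_matrix(matrix(c(cts, 20, 20, 20), nrow = 2, byrow = TRUE,
                           dimnames = list(c("t1", "RNU44"),
                                           c("PER_01", "PER_02", "PER_03"))))
    man <- sample_manifest(colnames(ct), rep("PER", 3))
    pooled <- unclass(pool_patients(ct, man, 3, seed = 1)$ct)["t1", ]
    expect_gte(pooled, min(cts))
    expect_lte(pooled, max(cts))
    # lowering one contributing CT never increases the pooled CT
    cts2 <- cts; cts2[1] <- cts2[1] - runif(1, 0, 3)
    ct2 <- ct_matrix(matrix(c(cts2, 20, 20, 20), nrow = 2, byrow = TRUE,
                            dimnames = dimnames(unclass(ct))))
    pooled2 <- unclass(pool_patients(ct2, man, 3, seed = 1)$ct)["t1", ]
    expect_lte(pooled2, pooled)
  }
})

test_that("non-detected wells contribute zero abundance; all-ND pools stay ND", {
  v <- matrix(c(20, NA, 23,
                NA, NA, NA,
                20, 20, 20),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "RNU44"),
                              c("M0_01", "M0_02", "M0_03")))
  ct <- ct_matrix(v)
  man <- sample_manifest(colnames(v), rep("M0", 3))
  p <- pool_patients(ct, man, 3, seed = 2)
  expect_equal(unclass(p$ct)["t1", "M0_pool"],
               -log2(mean(c(2^-20, 0, 2^-23))), tolerance = 1e-12)
  expect_true(is.na(unclass(p$ct)["t2", "M0_pool"]))
})

test_that("pooling a too-small group errors naming the group", {
  cfg <- simulation_config(n_targets = 5, seed = 9,
                           group_sizes = c(LM = 10, PER = 10, M0 = 3))
  sim <- simulate_cohort(cfg)
  keep <- sim$manifest$sample_id[sim$manifest$group != "M0" |
                                   sim$manifest$sample_id == "M0_01"]
  ct <- ct_subset(sim$ct, samples = keep)
  expect_error(pool_patients(ct, sim$manifest, 3, seed = 1), "M0")
})

test_that("noise-free pipeline recovers every planted log2fc exactly", {
  fx <- data.frame(assay_id = c("syn-miR-0001", "syn-miR-0002", "syn-miR-0003"),
                   group = c("PER", "PER", "LM"),
                   log2fc = c(2, -1.5, 3.25))
  cfg <- simulation_config(n_targets = 40, noise_sd = 0,
                           detection_ceiling = Inf, planted_effects = fx,
                           seed = 21)
  run <- quick_screen_norm(cfg)
  for (i in seq_len(nrow(fx))) {
    ddct <- delta_delta_ct(run$norm, paste0(fx$group[i], "_pool"), "M0_pool")
    expect_equal(unname(log2(fold_change(ddct[fx$assay_id[i]]))),
                 fx$log2fc[i], tolerance = 1e-12)
  }
})
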