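# build a pooled normalized matrix + manifest with prescribed ddCT values
# (reference pools at dCT 0, numerator pools at -log2(fc))
pooled_fixture <- function(fc_per_vs_lm, fc_per_vs_m0 = fc_per_vs_lm,
                           fc_lm_vs_m0 = rep(1, length(fc_per_vs_lm)),
                           ids = sprintf("m%02d", seq_along(fc_per_vs_lm))) {
  dct_m0 <- rep(0, length(ids))
  dct_lm <- -log2(fc_lm_vs_m0)
  dct_per <- -log2(fc_per_vs_m0)
  stopifnot(all(abs(fc_per_vs_lm - 2^(dct_lm - dct_per)) < 1e-9))
  m <- cbind(LM_pool = dct_lm, PER_pool = dct_per, M0_pool = dct_m0)
  rownames(m) <- ids
  list(norm = as_norm(m),
       manifest = sample_manifest(c("LM_pool", "PER_pool", "M0_pool"),
                                  c("LM", "PER", "M0"), is_pool = TRUE))
}

test_that("screen_config validates thresholds and contrasts", {
  expect_error(screen_config(up_threshold = 0.9), "thresholds")
  expect_error(screen_config(down_threshold = 1.2), "thresholds")
  expect_error(screen_config(contrasts = list(c("PER", "PER"))), "distinct")
  expect_error(screen_config(contrasts = list(c("PER", "XX"))), "group labels")
})

test_that("calls: 17-fold UP, 0.04-fold DOWN, boundary values NS", {
  fc <- c(17, 0.04, 2.00, 0.500, 1.0, 2.0001, 0.4999)
  fx <- pooled_fixture(fc, fc_per_vs_m0 = fc)
  res <- call_contrast(fx$norm, c("PER", "LM"), fx$manifest)
  expect_equal(res$fold_change, fc, tolerance = 1e-9)
  expect_identical(res$call, c("UP", "DOWN", "NS", "NS", "NS", "UP", "DOWN"))
  expect_identical(res$contrast, rep("PER_vs_LM", 7))
})

test_that("a missing pooled sample fails naming the group", {
  fx <- pooled_fixture(c(2, 3))
  man <- fx$manifest[fx$manifest$group != "M0", ]
  class(man) <- c("sample_manifest", "data.frame")
  expect_error(call_contrast(fx$norm, c("PER", "M0"), man), "M0")
})

test_that("partition and inversion duality hold on random screens", {
  set.seed(12)
  for (i in 1:10) {
    fc <- 2^runif(50, -3, 3)
    fx <- pooled_fixture(fc)
    fwd <- call_contrast(fx$norm, c("PER", "LM"), fx$manifest)
    rev <- call_contrast(fx$norm, c("LM", "PER"), fx$manifest)
    expect_equal(sum(fwd$call == "UP") + sum(fwd$call == "DOWN") +
                   sum(fwd$call == "NS"), 50)
    # thresholds 2.00 and 0.500 are reciprocal: UP <-> DOWN exactly
    expect_identical(fwd$call == "UP", rev$call == "DOWN")
    expect_identical(fwd$call == "DOWN", rev$call == "UP")
  }
})

test_that("triple membership is the direction-agnostic non-NS intersection", {
  mk <- function(calls, lab) data.frame(assay_id = names(calls), contrast = lab,
                                        ddct = 0, fold_change = 1, call = unname(calls),
                                        stringsAsFactors = FALSE)
  r1 <- mk(c(m1 = "UP", m2 = "UP", m3 = "DOWN"), "PER_vs_LM")
  r2 <- mk(c(m1 = "DOWN", m2 = "NS", m3 = "DOWN"), "PER_vs_M0")
  r3 <- mk(c(m1 = "DOWN", m2 = "UP", m3 = "UP"), "LM_vs_M0")
  tr <- triple_differential(list(r1, r2, r3))
  expect_identical(tr$is_triple, c(TRUE, FALSE, TRUE))  # sign flips still count
  expect_identical(tr$call_PER_vs_M0, c("DOWN", "NS", "DOWN"))

  r_bad <- mk(c(m1 = "UP", mX = "NS", m3 = "NS"), "LM_vs_M0")
  expect_error(triple_differential(list(r1, r2, r_bad)), "m2")

  # random calls: equals brute-force intersection of the three non-NS sets
  set.seed(77)
  ids <- sprintf("a%03d", 1:200)
  for (i in 1:10) {
    calls <- replicate(3, sample(c("UP", "DOWN", "NS"), 200, replace = TRUE),
                       simplify = FALSE)
    rs <- lapply(1:3, function(j) {
      v <- calls[[j]]; names(v) <- ids
      mk(v, paste0("c", j))
    })
    tr <- triple_differential(rs)
    brute <- Reduce(intersect, lapply(calls, function(v) ids[v != "NS"]))
    expect_setequal(tr$assay_id[tr$is_triple], brute)
  }
})

test_that("relaxing thresholds never shrinks the triple set", {
  set.seed(13)
  fc1 <- 2^runif(80, -3, 3); fc3 <- 2^runif(80, -2, 2)
  fx <- pooled_fixture(fc1 / fc3 / 1, fc_per_vs_m0 = fc1 / 1,
                       fc_lm_vs_m0 = fc3)
  run <- function(cfg) {
    res <- lapply(cfg$contrasts, function(ctr)
      call_contrast(fx$norm, ctr, fx$manifest, cfg))
    tr <- triple_differential(res)
    tr$assay_id[tr$is_triple]
  }
  strict <- run(screen_config())
  relaxed <- run(screen_config(up_threshold = 1.5, down_threshold = 0.667))
  expect_true(all(strict %in% relaxed))
})

test_that("candidates rank by |log2 fc| with lexicographic tie-break", {
  res <- data.frame(assay_id = c("hsa-miR-31-5p", "hsa-miR-215-5p", "hsa-miR-31-3p"),
                    contrast = "PER_vs_LM", ddct = -log2(c(5.4, 17, 8.9)),
                    fold_change = c(5.4, 17, 8.9),
                    call = "UP", stringsAsFactors = FALSE)
  expect_identical(rank_candidates(res)$fold_change, c(17, 8.9, 5.4))

  tie <- data.frame(assay_id = c("zzz", "aaa"), contrast = "x",
                    ddct = c(-2, 2), fold_change = c(4, 0.25),
                    call = c("UP", "DOWN"), stringsAsFactors = FALSE)
  expect_identical(rank_candidates(tie)$assay_id, c("aaa", "zzz"))

  set.seed(14)
  rnd <- data.frame(assay_id = sprintf("m%03d", sample(1:60)), contrast = "x",
                    ddct = 0, fold_change = 2^runif(60, -4, 4),
                    call = "NS", stringsAsFactors = FALSE)
  got <- rank_candidates(rnd)
  oracle <- rnd[order(-abs(log2(rnd$fold_change)), rnd$assay_id), ]
  expect_identical(got$assay_id, oracle$assay_id)
})

test_that("annotation joins exactly, case-insensitively, and suffix-tolerantly", {
  rec <- data.frame(assay_id = c("hsa-miR-31-5p", "hsa-miR-31-3p",
                                 "hsa-miR-99-5p"),
                    is_triple = TRUE, stringsAsFactors = FALSE)
  ann <- data.frame(assay_id = c("HSA-MIR-31-5P", "hsa-miR-31", "hsa-miR-21",
                                 "hsa-miR-215", "hsa-miR-483"),
                    disease = c("CRC", "CRC-stem", "other", "other", "other"),
                    evidence = "", stringsAsFactors = FALSE)
  strict <- annotate_candidates(rec, ann)
  expect_identical(strict$diseases, c("CRC", "", ""))
  tol <- annotate_candidates(rec, ann, suffix_tolerant = TRUE)
  expect_identical(tol$diseases, c("CRC;CRC-stem", "CRC-stem", ""))
  expect_identical(tol$n_annotations, c(2L, 1L, 0L))
})
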