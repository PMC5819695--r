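# shared fixtures and independent oracles

# small CT matrix built by hand: 3 targets, 3 housekeepers, 1 negative control
tiny_ct <- function(samples = c("s1", "s2")) {
  v <- matrix(c(25, 26,
                29.5, 28,
                33, 31,
                20, 20.5,
                22, 21.5,
                24, 23),
              nrow = 6, byrow = TRUE,
              dimnames = list(c("hsa-miR-31-5p", "hsa-miR-215-5p",
                                "hsa-miR-483-5p", "RNU44", "RNU48", "U6"),
                              samples))
  v <- rbind(v, "ath-miR-159a" = c(NA_real_, NA_real_))
  ct_matrix(v)
}

# random detected-everywhere CT matrix of targets + housekeepers
random_ct <- function(n_targets, samples, seed, lo = 15, hi = 29) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n_targets))
  v <- matrix(runif(n_targets * length(samples), lo, hi),
              nrow = n_targets, dimnames = list(ids, samples))
  hk <- matrix(runif(3 * length(samples), 18, 22), nrow = 3,
               dimnames = list(c("RNU44", "RNU48", "U6"), samples))
  ct_matrix(rbind(v, hk))
}

# wrap a plain dCT matrix as a normalized_matrix
as_norm <- function(m) {
  structure(m, provenance = "MEAN_CT",
            class = c("normalized_matrix", "matrix", "array"))
}

# independent cell-by-cell recomputation of the whole dCT/ddCT/fc chain
chain_oracle <- function(ct, target_sample, reference_sample) {
  roles <- assay_roles(ct)
  hk <- names(roles)[roles == "HOUSEKEEPER"]
  targets <- names(roles)[roles == "TARGET"]
  out <- list()
  for (a in targets) {
    hk_t <- mean(unclass(ct)[hk, target_sample], na.rm = TRUE)
    hk_r <- mean(unclass(ct)[hk, reference_sample], na.rm = TRUE)
    dct_t <- unclass(ct)[a, target_sample] - hk_t
    dct_r <- unclass(ct)[a, reference_sample] - hk_r
    out[[a]] <- list(ddct = dct_t - dct_r, fc = 2^-(dct_t - dct_r))
  }
  out
}

# brute-force two-sided Fisher p by explicit enumeration of all tables with
# the observed margins, probabilities from choose() products
brute_force_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  p_obs <- pr[ks == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# minimal simulate->pool->filter->normalize run used by several tests
quick_screen_norm <- function(config) {
  sim <- simulate_cohort(config)
  pooled <- pool_patients(sim$ct, sim$manifest, config$pool_size,
                          seed = config$seed)
  filt <- detection_filter(pooled$ct, quant_config(),
                           samples_in_scope = colnames(pooled$ct))
  list(sim = sim, pooled = pooled, filt = filt,
       norm = delta_ct(filt$ct, quant_config()))
}
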