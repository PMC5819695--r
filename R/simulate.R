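#' Simulation configuration
#'
#' Describes the synthetic qPCR world the generator emulates: a TaqMan
#' low-density-array style panel (754 target miRNAs plus three housekeeping
#' small RNAs and one plant-miRNA negative control) run on a three-group
#' colorectal-cancer cohort (10 liver-metastasis, 10 peritoneal, 3
#' non-metastasized patients), with per-miRNA baseline CTs, planted
#' group-specific log2 fold changes, Gaussian CT noise and a detection
#' ceiling above which a well reads non-detected.
#'
#' @param n_targets number of target assays (default 754)
#' @param housekeeper_ids housekeeper assay names (default RNU44, RNU48, U6)
#' @param negative_control_id negative-control assay name (default ath-miR-159a)
#' @param group_sizes named integer vector, patients per group
#'   (default `c(LM = 10, PER = 10, M0 = 3)`)
#' @param pool_size patients pooled per group for the array run (default 3)
#' @param baseline_ct_range low/high cycles for the per-miRNA baseline CT,
#'   shared across patients (default 18–38, spanning both the detected and the
#'   filtered regime so the CT < 30 filter is exercised)
#' @param planted_effects data.frame from [planted_effects()], or `NULL`
#' @param planted_baseline_range baseline range used for assays that carry a
#'   planted effect (default 18–26): effects are planted in the well-expressed
#'   regime so that neither the affected nor the reference group is pushed past
#'   the detection filter by the effect itself
#' @param noise_sd per-well Gaussian CT noise, cycles (default 0.25)
#' @param detection_ceiling CT above which a well is stored as non-detected
#'   (default 35; use `Inf` to disable — the 40-cycle run length still applies)
#' @param classifier_positive_prob named probabilities that a patient is
#'   stem-cell-classifier positive (default `c(LM = 1, PER = 0.2, M0 = 0)`,
#'   the marginal rates reported for the cohort)
#' @param housekeeper_baseline_ct baseline CT per housekeeper (recycled;
#'   default 19, 20, 21 cycles — abundant small RNAs, no group effect)
#' @param seed integer seed; mandatory, there is no wall-clock fallback
#'
#' @return a validated list of class `simulation_config`
#' @export
simulation_config <- function(n_targets = 754,
                              housekeeper_ids = c("RNU44", "RNU48", "U6"),
                              negative_control_id = "ath-miR-159a",
                              group_sizes = c(LM = 10, PER = 10, M0 = 3),
                              pool_size = 3,
                              baseline_ct_range = c(18, 38),
                              planted_effects = NULL,
                              planted_baseline_range = c(18, 26),
                              noise_sd = 0.25,
                              detection_ceiling = 35,
                              classifier_positive_prob = c(LM = 1, PER = 0.2, M0 = 0),
                              housekeeper_baseline_ct = c(19, 20, 21),
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("configuration error: `seed` is mandatory and must be a single integer")
  if (!is.numeric(n_targets) || n_targets < 1)
    stop("configuration error: `n_targets` must be a positive count")
  if (!all(GROUP_LEVELS %in% names(group_sizes)))
    stop("configuration error: `group_sizes` must name LM, PER and M0")
  if (any(group_sizes < 1))
    stop("configuration error: `group_sizes` must all be positive")
  if (pool_size < 1 || any(pool_size > group_sizes))
    stop("configuration error: `pool_size` must be positive and no larger than every group size")
  if (length(baseline_ct_range) != 2L || baseline_ct_range[1L] >= baseline_ct_range[2L])
    stop("configuration error: `baseline_ct_range` must satisfy low < high")
  if (noise_sd < 0)
    stop("configuration error: `noise_sd` must be >= 0")
  if (detection_ceiling <= 0)
    stop("configuration error: `detection_ceiling` must be positive")
  p <- classifier_positive_prob
  if (!all(GROUP_LEVELS %in% names(p)) || any(p < 0 | p > 1))
    stop("configuration error: `classifier_positive_prob` must give each group a probability in [0, 1]")
  target_ids <- sprintf("syn-miR-%04d", seq_len(n_targets))
  if (!is.null(planted_effects)) {
    planted_effects <- planted_effects(planted_effects$assay_id,
                                       planted_effects$group,
                                       planted_effects$log2fc)
    bad <- setdiff(planted_effects$assay_id, target_ids)
    if (length(bad) > 0L)
      stop("configuration error: `planted_effects` names non-target assay(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(
    n_targets = as.integer(n_targets), target_ids = target_ids,
    housekeeper_ids = housekeeper_ids,
    negative_control_id = negative_control_id,
    group_sizes = group_sizes[GROUP_LEVELS], pool_size = as.integer(pool_size),
    baseline_ct_range = baseline_ct_range,
    planted_effects = planted_effects,
    planted_baseline_range = planted_baseline_range,
    noise_sd = noise_sd, detection_ceiling = detection_ceiling,
    classifier_positive_prob = p[GROUP_LEVELS],
    housekeeper_baseline_ct = rep_len(housekeeper_baseline_ct,
                                      length(housekeeper_ids)),
    seed = as.integer(seed)),
    class = "simulation_config")
}

#' Planted ground-truth effects
#'
#' Each row plants a group-specific log2 fold change (relative to the M0
#' baseline expression) on one target assay — the truth table against which
#' parameter recovery is measured. One CT cycle corresponds to one doubling,
#' so a planted `log2fc` lowers the affected group's CT by `log2fc` cycles.
#'
#' @param assay_id target assay names (never housekeepers or controls)
#' @param group group whose expression is shifted
#' @param log2fc planted log2 fold change, dimensionless
#' @return data.frame with columns assay_id, group, log2fc
#' @export
planted_effects <- function(assay_id, group, log2fc) {
  assay_id <- as.character(assay_id)
  group <- rep_len(as.character(group), length(assay_id))
  log2fc <- rep_len(as.numeric(log2fc), length(assay_id))
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad) > 0L)
    stop("unknown group label in planted effects: ", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(assay_id, group)))
    stop("duplicate (assay_id, group) in planted effects")
  data.frame(assay_id = assay_id, group = group, log2fc = log2fc,
             stringsAsFactors = FALSE)
}

#' Simulate a patient cohort's CT data
#'
#' Generates one CT column per patient. Target CT = per-miRNA baseline −
#' planted log2fc for the patient's group (one cycle per doubling) + Gaussian
#' noise; housekeeper CT = fixed baseline + noise, with no group effect; the
#' negative control never amplifies. Any drawn CT above the detection ceiling
#' (or the 40-cycle run length) is stored as non-detected. The manifest
#' carries group labels and a Bernoulli stem-cell-classifier status per
#' patient. Identical config (including seed) gives bit-identical output.
#'
#' @param config a [simulation_config()]
#' @return list with elements `ct` (a [ct_matrix()], one column per patient),
#'   `manifest` (a [sample_manifest()]) and `truth` (the planted-effects
#'   data.frame, possibly empty)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gs <- config$group_sizes
  patients <- unlist(lapply(GROUP_LEVELS, function(g)
    sprintf("%s_%02d", g, seq_len(gs[[g]]))), use.names = FALSE)
  pgroup <- rep(GROUP_LEVELS, gs)
  n_pat <- length(patients)

  baselines <- stats::runif(config$n_targets,
                            config$baseline_ct_range[1L],
                            config$baseline_ct_range[2L])
  names(baselines) <- config$target_ids
  truth <- config$planted_effects
  if (!is.null(truth) && nrow(truth) > 0L) {
    # planted assays live in the well-expressed regime (see vignette)
    planted_ids <- unique(truth$assay_id)
    baselines[planted_ids] <- stats::runif(length(planted_ids),
                                           config$planted_baseline_range[1L],
                                           config$planted_baseline_range[2L])
  } else {
    truth <- planted_effects(character(0), character(0), numeric(0))
  }

  ct_target <- matrix(rep(baselines, n_pat), nrow = config$n_targets,
                      dimnames = list(config$target_ids, patients))
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      cols <- pgroup == truth$group[i]
      ct_target[truth$assay_id[i], cols] <-
        ct_target[truth$assay_id[i], cols] - truth$log2fc[i]
    }
  }
  ct_hk <- matrix(rep(config$housekeeper_baseline_ct, n_pat),
                  nrow = length(config$housekeeper_ids),
                  dimnames = list(config$housekeeper_ids, patients))
  ct <- rbind(ct_target, ct_hk)
  if (config$noise_sd > 0)
    ct <- ct + matrix(stats::rnorm(length(ct), 0, config$noise_sd), nrow = nrow(ct))
  ct[ct > min(config$detection_ceiling, 40)] <- NA_real_
  ct[!is.na(ct) & ct < 1] <- 1        # defensive: CT cannot go below one cycle
  negctl <- matrix(NA_real_, nrow = 1L,
                   dimnames = list(config$negative_control_id, NULL))
  ct <- rbind(ct, negctl[, rep(1L, n_pat), drop = FALSE])

  classifier <- stats::rbinom(n_pat, 1L,
                              config$classifier_positive_prob[pgroup])
  manifest <- sample_manifest(patients, pgroup, is_pool = FALSE,
                              attributes = data.frame(classifier_positive = classifier))
  list(ct = ct_matrix(ct, housekeeper_ids = config$housekeeper_ids,
                      negative_control_id = config$negative_control_id),
       manifest = manifest, truth = truth)
}

#' Pool patients into one array sample per group
#'
#' Emulates physical pooling of equal RNA amounts: `pool_size` patients per
#' group are selected reproducibly by `seed`, their linear abundances
#' `2^(-CT)` are averaged, and the pooled CT is `-log2` of that mean — pooling
#' mixes molecules, not cycle numbers. A well that is non-detected in a pooled
#' patient contributes zero abundance; if it is non-detected in every pooled
#' patient (or the pooled CT falls beyond the 40-cycle run) the pooled well is
#' non-detected.
#'
#' @param ct per-patient [ct_matrix()]
#' @param manifest [sample_manifest()] resolving every column of `ct`
#' @param pool_size patients per pooled sample (default 3)
#' @param seed integer driving the selection of pooled patients
#' @return list with `ct` (pooled [ct_matrix()], one `<group>_pool` column per
#'   group), `manifest` (pooled rows, `is_pool = TRUE`) and `members` (named
#'   list of the patient ids pooled per group)
#' @export
pool_patients <- function(ct, manifest, pool_size = 3, seed) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(manifest, "sample_manifest"))
  if (missing(seed)) stop("`seed` is mandatory for reproducible pooling")
  m <- manifest[!manifest$is_pool & manifest$sample_id %in% colnames(ct), ,
                drop = FALSE]
  groups <- GROUP_LEVELS[GROUP_LEVELS %in% m$group]
  set.seed(as.integer(seed))
  members <- list()
  pooled <- matrix(NA_real_, nrow = nrow(ct), ncol = length(groups),
                   dimnames = list(rownames(ct), paste0(groups, "_pool")))
  for (j in seq_along(groups)) {
    g <- groups[j]
    cand <- m$sample_id[m$group == g]
    if (length(cand) < pool_size)
      stop("group '", g, "' has fewer than pool_size = ", pool_size,
           " patients with CT data")
    sel <- if (length(cand) == pool_size) cand else sort(sample(cand, pool_size))
    members[[g]] <- sel
    sub <- unclass(ct)[, sel, drop = FALSE]
    abundance <- 2^(-sub)
    abundance[is.na(abundance)] <- 0
    mean_ab <- rowMeans(abundance)
    pooled_ct <- ifelse(mean_ab > 0, -log2(mean_ab), NA_real_)
    pooled_ct[!is.na(pooled_ct) & pooled_ct > 40] <- NA_real_
    pooled[, j] <- pooled_ct
  }
  roles <- assay_roles(ct)
  pooled_ct_matrix <- ct_matrix(
    pooled,
    housekeeper_ids = names(roles)[roles == "HOUSEKEEPER"],
    negative_control_id = names(roles)[roles == "NEGATIVE_CONTROL"])
  pooled_manifest <- sample_manifest(colnames(pooled), groups, is_pool = TRUE)
  list(ct = pooled_ct_matrix, manifest = pooled_manifest, members = members)
}
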