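#' Run configuration
#'
#' Bundles everything one screening or validation run needs: input paths (or
#' a simulation config to generate inputs), the quantification and screening
#' settings, the significance level and the seed. Referenced inputs must
#' exist unless simulate mode is on.
#'
#' @param out_dir output directory (created if absent)
#' @param ct_table path to a per-patient or pooled CT table (TSV), or `NULL`
#' @param manifest path to the sample manifest (TSV), or `NULL`
#' @param annotation optional path to a disease-association table
#' @param simulate optional [simulation_config()]; when set, inputs are
#'   generated instead of read
#' @param quant a [quant_config()]
#' @param screen a [screen_config()]
#' @param alpha significance level for cohort validation (default 0.05)
#' @param seed integer seed for pooling (and anything else stochastic);
#'   mandatory in simulate mode, defaults to the simulation seed
#' @param validation_assays assay ids for [run_validation()]
#' @param suffix_tolerant annotation matching mode, see [annotate_candidates()]
#' @return a list of class `run_config`
#' @export
run_config <- function(out_dir, ct_table = NULL, manifest = NULL,
                       annotation = NULL, simulate = NULL,
                       quant = quant_config(), screen = screen_config(),
                       alpha = 0.05, seed = NULL,
                       validation_assays = character(0),
                       suffix_tolerant = FALSE) {
  if (is.null(simulate)) {
    for (p in list(ct_table, manifest))
      if (is.null(p) || !file.exists(p))
        stop("input file missing: ", if (is.null(p)) "(unset)" else p,
             " (set `simulate` to generate inputs)")
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
    if (is.null(seed)) seed <- simulate$seed
  }
  if (!is.null(annotation) && !file.exists(annotation))
    stop("annotation file missing: ", annotation)
  if (is.null(seed))
    stop("`seed` is mandatory (no wall-clock fallback)")
  structure(list(out_dir = out_dir, ct_table = ct_table, manifest = manifest,
                 annotation = annotation, simulate = simulate,
                 quant = quant, screen = screen, alpha = alpha,
                 seed = as.integer(seed),
                 validation_assays = validation_assays,
                 suffix_tolerant = suffix_tolerant),
            class = "run_config")
}

# run `expr` as a named pipeline stage: errors abort with the stage name,
# and every file written so far in this run is removed.
run_stage <- function(stage, expr, written) {
  tryCatch(expr, error = function(e) {
    unlink(written$files)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the pooled screening cascade
#'
#' Executes simulate/read -> pool -> detection filter -> dCT -> the three
#' contrasts -> triple-differential intersection -> annotation -> report, in
#' order, writing every result table plus a machine-readable JSON and a
#' human-readable text report to `out_dir`. Identical config and seed give
#' identical outputs. Any stage error aborts with the stage name and removes
#' partial outputs.
#'
#' @param config a [run_config()]
#' @return the run report (list of class `run_report`), invisibly; files
#'   written under `config$out_dir`
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- new.env(); w$files <- character(0)
  emit <- function(path) { w$files <- c(w$files, path); path }

  inputs <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(config$simulate)
      write_ct_table(sim$ct, emit(file.path(config$out_dir, "ct_patients.tsv")))
      write_manifest(sim$manifest, emit(file.path(config$out_dir, "manifest_patients.tsv")))
      utils::write.table(sim$truth,
                         emit(file.path(config$out_dir, "truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim
    } else {
      list(ct = read_ct_table(config$ct_table),
           manifest = read_manifest(config$manifest), truth = NULL)
    }
  }, w)

  pooled <- run_stage("pooling", {
    man <- inputs$manifest
    if (any(man$is_pool)) {
      pm <- man[man$is_pool, , drop = FALSE]
      list(ct = ct_subset(inputs$ct, samples = pm$sample_id), manifest = pm)
    } else {
      ps <- if (!is.null(config$simulate)) config$simulate$pool_size else 3L
      p <- pool_patients(inputs$ct, man, pool_size = ps, seed = config$seed)
      write_ct_table(p$ct, emit(file.path(config$out_dir, "ct_pools.tsv")))
      p
    }
  }, w)

  filt <- run_stage("detection_filter", {
    detection_filter(pooled$ct, config$quant,
                     samples_in_scope = colnames(pooled$ct))
  }, w)

  norm <- run_stage("normalization", delta_ct(filt$ct, config$quant), w)

  contrasts <- run_stage("contrasts", {
    res <- lapply(config$screen$contrasts, function(ctr)
      call_contrast(norm, ctr, pooled$manifest, config$screen))
    names(res) <- vapply(config$screen$contrasts, contrast_label, character(1))
    for (lab in names(res))
      write_contrast_table(res[[lab]],
                           emit(file.path(config$out_dir,
                                          paste0("contrast_", lab, ".tsv"))))
    res
  }, w)

  triple <- run_stage("triple_differential", {
    tr <- triple_differential(unname(contrasts))
    if (!is.null(config$annotation))
      tr <- annotate_candidates(tr, read_annotation(config$annotation),
                                suffix_tolerant = config$suffix_tolerant)
    if (nrow(tr) > 0L)
      write_triple_table(tr, emit(file.path(config$out_dir, "triple_differential.tsv")))
    if (any(tr$is_triple))
      export_dct_heatmap_matrix(
        structure(unclass(norm)[tr$assay_id[tr$is_triple], , drop = FALSE],
                  provenance = attr(norm, "provenance"),
                  class = c("normalized_matrix", "matrix", "array")),
        emit(file.path(config$out_dir, "triple_dct_heatmap.tsv")))
    tr
  }, w)

  report <- run_stage("report", {
    roles <- assay_roles(pooled$ct)
    n_total <- sum(roles == "TARGET")
    per_contrast <- lapply(contrasts, function(r)
      c(UP = sum(r$call == "UP"), DOWN = sum(r$call == "DOWN"),
        NS = sum(r$call == "NS")))
    rep <- structure(list(
      n_assays_total = n_total,
      n_detected = length(filt$retained),
      detected_fraction = length(filt$retained) / n_total,
      per_contrast = per_contrast,
      n_triple = sum(triple$is_triple),
      n_annotated = if ("n_annotations" %in% names(triple))
        sum(triple$is_triple & triple$n_annotations > 0L) else NA_integer_,
      validation = NULL,
      config = list(
        detection_ct_threshold = config$quant$detection_ct_threshold,
        detection_rule = config$quant$detection_rule,
        housekeeper_aggregation = config$quant$housekeeper_aggregation,
        up_threshold = config$screen$up_threshold,
        down_threshold = config$screen$down_threshold,
        contrasts = vapply(config$screen$contrasts, contrast_label, character(1)),
        alpha = config$alpha),
      seed = config$seed), class = "run_report")
    write_run_report(rep,
                     emit(file.path(config$out_dir, "report.json")),
                     emit(file.path(config$out_dir, "report.txt")))
    rep
  }, w)
  invisible(report)
}

#' Whole-cohort validation run
#'
#' Applies [whole_cohort_validation()] to the named assays on the per-patient
#' CT data and writes the validation TSV. Assays absent from the matrix are
#' listed as `missing` and the run continues; an empty assay list yields an
#' empty table.
#'
#' @param config a [run_config()] with `validation_assays` set (or pass
#'   `assays`)
#' @param assays assay ids, defaulting to `config$validation_assays`
#' @param groups the two compared groups (default `c("PER", "LM")`)
#' @param scale test scale, see [whole_cohort_validation()]
#' @return the validation data.frame, invisibly; `validation.tsv` written
#' @export
run_validation <- function(config, assays = config$validation_assays,
                           groups = c("PER", "LM"), scale = "linear") {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- if (!is.null(config$simulate))
    simulate_cohort(config$simulate)
  else
    list(ct = read_ct_table(config$ct_table),
         manifest = read_manifest(config$manifest))
  patients <- inputs$manifest$sample_id[!inputs$manifest$is_pool]
  ct <- ct_subset(inputs$ct, samples = intersect(colnames(inputs$ct), patients))
  norm <- delta_ct(ct, config$quant)
  path <- file.path(config$out_dir, "validation.tsv")
  if (length(assays) == 0L) {
    out <- data.frame(assay_id = character(0), group_a = character(0),
                      group_b = character(0), status = character(0),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out <- whole_cohort_validation(norm, inputs$manifest, assays,
                                 groups = groups, alpha = config$alpha,
                                 scale = scale)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a run report
#'
#' @param report a `run_report` from [run_screen()]
#' @param json_path,txt_path output paths (either may be `NULL` to skip)
#' @return `report`, invisibly
#' @export
write_run_report <- function(report, json_path = NULL, txt_path = NULL) {
  stopifnot(inherits(report, "run_report"))
  if (!is.null(json_path)) {
    x <- unclass(report)
    x$per_contrast <- lapply(x$per_contrast, as.list)  # keep UP/DOWN/NS keys
    if (isTRUE(is.na(x$n_annotated))) x$n_annotated <- NULL
    jsonlite::write_json(x, json_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "wt"); on.exit(close(con))
    writeLines(format(report), con)
  }
  invisible(report)
}

#' @export
format.run_report <- function(x, ...) {
  lines <- c(
    "miRNA panel screening report",
    sprintf("  seed: %d", x$seed),
    sprintf("  targets on panel: %d", x$n_assays_total),
    sprintf("  detected (CT < %s, rule %s): %d (%.1f%%)",
            format(x$config$detection_ct_threshold), x$config$detection_rule,
            x$n_detected, 100 * x$detected_fraction),
    sprintf("  thresholds: UP > %.3g, DOWN < %.3g",
            x$config$up_threshold, x$config$down_threshold))
  for (lab in names(x$per_contrast)) {
    ct <- x$per_contrast[[lab]]
    lines <- c(lines, sprintf("  %s: %d UP, %d DOWN, %d NS",
                              lab, ct[["UP"]], ct[["DOWN"]], ct[["NS"]]))
  }
  lines <- c(lines, sprintf("  triple-differential: %d", x$n_triple))
  if (isTRUE(!is.na(x$n_annotated)))
    lines <- c(lines, sprintf("  annotated triple-differential: %d", x$n_annotated))
  lines
}

#' @export
print.run_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}
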