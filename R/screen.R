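#' Screening configuration
#'
#' Fold-change thresholds for the pooled screen and the ordered list of group
#' contrasts. Calls are strict: UP iff fold change > `up_threshold`, DOWN iff
#' fold change < `down_threshold`, NS otherwise — boundary equality is NS.
#' The defaults (2.00 and 0.500) are reciprocal, so swapping a contrast's
#' orientation maps UP and DOWN onto each other exactly.
#'
#' @param up_threshold fold change above which an assay is called UP
#'   (default 2.00, strict)
#' @param down_threshold fold change below which an assay is called DOWN
#'   (default 0.500, strict)
#' @param contrasts list of `c(numerator group, denominator/reference group)`
#'   pairs; default `PER vs LM`, `PER vs M0`, `LM vs M0`
#' @return a list of class `screen_config`
#' @export
screen_config <- function(up_threshold = 2.00, down_threshold = 0.500,
                          contrasts = list(c("PER", "LM"),
                                           c("PER", "M0"),
                                           c("LM", "M0"))) {
  if (!(0 < down_threshold && down_threshold < 1 && 1 < up_threshold))
    stop("thresholds must satisfy 0 < down_threshold < 1 < up_threshold")
  for (ctr in contrasts) {
    if (length(ctr) != 2L || !all(ctr %in% GROUP_LEVELS) || ctr[1L] == ctr[2L])
      stop("each contrast must be a pair of distinct group labels from LM, PER, M0")
  }
  structure(list(up_threshold = up_threshold, down_threshold = down_threshold,
                 contrasts = contrasts),
            class = "screen_config")
}

contrast_label <- function(contrast) paste0(contrast[1L], "_vs_", contrast[2L])

#' Call one group contrast from pooled dCT values
#'
#' For every assay in the (detection-filtered) normalized matrix, computes
#' ddCT between the two groups' pooled samples, the `2^-ddCT` fold change,
#' and the UP/DOWN/NS call at the configured strict thresholds. Pools carry no
#' replication, so the pooled screen is fold-change thresholding only;
#' inferential tests live at the cohort level.
#'
#' @param norm `normalized_matrix` of pooled samples (from [delta_ct()])
#' @param contrast `c(numerator group, reference group)`
#' @param manifest [sample_manifest()] mapping pooled samples to groups
#' @param config a [screen_config()]
#' @return data.frame with columns `assay_id`, `contrast`, `ddct`,
#'   `fold_change`, `call`, in input assay order
#' @export
call_contrast <- function(norm, contrast, manifest, config = screen_config()) {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(manifest, "sample_manifest"),
            inherits(config, "screen_config"))
  s_num <- pooled_sample_of(manifest, contrast[1L])
  s_ref <- pooled_sample_of(manifest, contrast[2L])
  for (s in c(s_num, s_ref))
    if (!s %in% colnames(norm))
      stop("contrast error: pooled sample '", s, "' for group '",
           contrast[if (s == s_num) 1L else 2L], "' absent from matrix")
  ddct <- delta_delta_ct(norm, s_num, s_ref)
  fc <- fold_change(ddct)
  data.frame(assay_id = names(ddct),
             contrast = contrast_label(contrast),
             ddct = unname(ddct),
             fold_change = unname(fc),
             call = fc_call(fc, config),
             stringsAsFactors = FALSE, row.names = NULL)
}

# strict thresholding; boundary equality is NS
fc_call <- function(fc, config) {
  ifelse(fc > config$up_threshold, "UP",
         ifelse(fc < config$down_threshold, "DOWN", "NS"))
}

#' Triple-differential intersection
#'
#' An assay is triple-differential when its call is non-NS in every one of
#' the three contrasts — direction is deliberately not required to agree
#' across contrasts (an assay induced in PER vs LM may still be repressed
#' relative to M0).
#'
#' @param results list of three contrast data.frames from [call_contrast()],
#'   covering the same assay universe
#' @return data.frame with `assay_id`, one call column per contrast
#'   (`call_<label>`), and `is_triple`
#' @export
triple_differential <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  universe <- results[[1L]]$assay_id
  for (r in results[-1L]) {
    if (!setequal(universe, r$assay_id)) {
      d <- union(setdiff(universe, r$assay_id), setdiff(r$assay_id, universe))
      stop("assay universe mismatch across contrasts: ",
           paste(d, collapse = ", "))
    }
  }
  out <- data.frame(assay_id = universe, stringsAsFactors = FALSE)
  for (r in results) {
    lab <- unique(r$contrast)
    out[[paste0("call_", lab)]] <- r$call[match(universe, r$assay_id)]
  }
  calls <- as.matrix(out[, -1L, drop = FALSE])
  out$is_triple <- rowSums(calls != "NS") == ncol(calls)
  out
}

#' Rank screening candidates by effect magnitude
#'
#' Sorts contrast results by `|log2(fold change)|` descending — the strongest
#' inductions and repressions first — with ties broken lexicographically by
#' assay id.
#'
#' @param results data.frame from [call_contrast()]
#' @return the same data.frame, reordered
#' @export
rank_candidates <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  mag <- abs(log2(results$fold_change))
  results[order(-mag, results$assay_id, method = "radix"), , drop = FALSE]
}

#' Annotate candidates against a disease-association table
#'
#' Joins triple-differential records to a user-supplied annotation table.
#' Matching is exact on the assay id after case normalization; with
#' `suffix_tolerant = TRUE` a stem-named annotation row (e.g. `hsa-miR-31`)
#' also annotates its mature-strand records (`hsa-miR-31-5p`, `hsa-miR-31-3p`).
#'
#' @param records data.frame from [triple_differential()]
#' @param annotation data.frame from [read_annotation()]
#' @param suffix_tolerant also match when the record id minus a `-5p`/`-3p`
#'   suffix equals the annotation id (default `FALSE`)
#' @return `records` with added columns `diseases` (collapsed `;`-separated,
#'   `""` when absent) and `n_annotations`
#' @export
annotate_candidates <- function(records, annotation, suffix_tolerant = FALSE) {
  stopifnot(is.data.frame(records), is.data.frame(annotation))
  ann_key <- tolower(annotation$assay_id)
  get_terms <- function(id) {
    keys <- tolower(id)
    if (suffix_tolerant)
      keys <- unique(c(keys, sub("-[35]p$", "", keys)))
    sort(unique(annotation$disease[ann_key %in% keys]))
  }
  terms <- lapply(records$assay_id, get_terms)
  records$diseases <- vapply(terms, paste, character(1), collapse = ";")
  records$n_annotations <- lengths(terms)
  records
}
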