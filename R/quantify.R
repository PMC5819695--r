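#' Quantification configuration
#'
#' @param detection_ct_threshold CT cutoff in cycles; an assay counts as
#'   detected in a sample only when its CT is strictly below this value
#'   (default 30, the card manufacturer's recommendation; ties at exactly 30
#'   fail).
#' @param detection_rule `"ALL_SAMPLES"` (default; detected in every scoped
#'   sample — conservative, makes every downstream fold change computable) or
#'   `"ANY_SAMPLE"`.
#' @param housekeeper_aggregation `"MEAN_CT"` (default; arithmetic mean CT of
#'   the detected housekeepers, i.e. the geometric mean of their linear
#'   abundances) or `"SINGLE:<assay_id>"` to normalize against one named
#'   housekeeper.
#' @return a list of class `quant_config`
#' @export
quant_config <- function(detection_ct_threshold = 30,
                         detection_rule = c("ALL_SAMPLES", "ANY_SAMPLE"),
                         housekeeper_aggregation = "MEAN_CT") {
  if (detection_ct_threshold <= 0 || detection_ct_threshold > 40)
    stop("`detection_ct_threshold` must lie in (0, 40]")
  detection_rule <- match.arg(detection_rule)
  if (!identical(housekeeper_aggregation, "MEAN_CT") &&
      !startsWith(housekeeper_aggregation, "SINGLE:"))
    stop("`housekeeper_aggregation` must be \"MEAN_CT\" or \"SINGLE:<assay_id>\"")
  structure(list(detection_ct_threshold = detection_ct_threshold,
                 detection_rule = detection_rule,
                 housekeeper_aggregation = housekeeper_aggregation),
            class = "quant_config")
}

#' Detection filter
#'
#' Selects the target assays sufficiently expressed for comparative analysis:
#' a target is retained iff its CT is strictly below the threshold in all
#' scoped samples (`ALL_SAMPLES`) or in at least one (`ANY_SAMPLE`).
#' Non-detected wells always count as failing. Housekeepers and the negative
#' control are never returned as retained targets; the filtered matrix keeps
#' the housekeeper rows so normalization stays possible downstream.
#'
#' @param ct a [ct_matrix()]
#' @param config a [quant_config()]
#' @param samples_in_scope sample names the rule is evaluated over (default
#'   all samples in the matrix)
#' @return list with `retained` (character vector of target assay ids, input
#'   order) and `ct` (the filtered [ct_matrix()]: retained targets plus
#'   housekeepers, scoped samples)
#' @export
detection_filter <- function(ct, config = quant_config(),
                             samples_in_scope = colnames(ct)) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(config, "quant_config"))
  if (length(samples_in_scope) == 0L)
    stop("`samples_in_scope` must be non-empty")
  missing_s <- setdiff(samples_in_scope, colnames(ct))
  if (length(missing_s) > 0L)
    stop("scoped sample(s) absent from matrix: ",
         paste(missing_s, collapse = ", "))
  roles <- assay_roles(ct)
  targets <- names(roles)[roles == "TARGET"]
  sub <- unclass(ct)[targets, samples_in_scope, drop = FALSE]
  detected <- !is.na(sub) & sub < config$detection_ct_threshold
  keep <- if (config$detection_rule == "ALL_SAMPLES")
    rowSums(detected) == ncol(detected) else rowSums(detected) > 0L
  retained <- targets[keep]
  hk <- names(roles)[roles == "HOUSEKEEPER"]
  list(retained = retained,
       ct = ct_subset(ct, assays = c(retained, hk), samples = samples_in_scope))
}

#' Aggregate housekeeper CT for one sample
#'
#' Under `MEAN_CT` returns the arithmetic mean CT of the housekeepers detected
#' in that sample (equivalently the geometric mean of their linear
#' abundances); under `SINGLE:<id>` returns that assay's CT.
#'
#' @param ct a [ct_matrix()]
#' @param sample sample name
#' @param config a [quant_config()]
#' @return housekeeper CT in cycles
#' @export
aggregate_housekeepers <- function(ct, sample, config = quant_config()) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!sample %in% colnames(ct))
    stop("unknown sample: ", sample)
  roles <- assay_roles(ct)
  if (identical(config$housekeeper_aggregation, "MEAN_CT")) {
    hk <- names(roles)[roles == "HOUSEKEEPER"]
    vals <- unclass(ct)[hk, sample]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L)
      stop("normalization error: no detected housekeeper in sample '", sample, "'")
    mean(vals)
  } else {
    id <- sub("^SINGLE:", "", config$housekeeper_aggregation)
    if (!id %in% rownames(ct))
      stop("normalization error: housekeeper '", id, "' absent from matrix")
    v <- unclass(ct)[id, sample]
    if (is.na(v))
      stop("normalization error: housekeeper '", id,
           "' non-detected in sample '", sample, "'")
    v
  }
}

#' Per-sample dCT normalization
#'
#' dCT = CT(target) − CT(housekeeper aggregate), computed per (target,
#' sample). Non-detected targets propagate as missing dCT. The result carries
#' only TARGET-role assays.
#'
#' @param ct a [ct_matrix()] (typically the filtered matrix from
#'   [detection_filter()])
#' @param config a [quant_config()]
#' @return a `normalized_matrix`: targets-by-samples numeric matrix of dCT
#'   values (cycles, may be negative) with a `provenance` attribute recording
#'   the housekeeper aggregation used
#' @export
delta_ct <- function(ct, config = quant_config()) {
  stopifnot(inherits(ct, "ct_matrix"))
  roles <- assay_roles(ct)
  targets <- names(roles)[roles == "TARGET"]
  hk_agg <- vapply(colnames(ct), function(s)
    aggregate_housekeepers(ct, s, config), numeric(1))
  dct <- sweep(unclass(ct)[targets, , drop = FALSE], 2L, hk_agg, `-`)
  structure(dct, provenance = config$housekeeper_aggregation,
            class = c("normalized_matrix", "matrix", "array"))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d assays x %d samples of dCT (housekeeper: %s), %d missing\n",
              nrow(x), ncol(x), attr(x, "provenance"), sum(is.na(x))))
  invisible(x)
}

#' Per-assay ddCT between two samples
#'
#' ddCT = dCT(target sample) − dCT(reference sample). Assays missing a dCT in
#' either sample are omitted with a message.
#'
#' @param norm a `normalized_matrix` from [delta_ct()]
#' @param target_sample,reference_sample sample names
#' @return named numeric vector of ddCT values in cycles
#' @export
delta_delta_ct <- function(norm, target_sample, reference_sample) {
  stopifnot(inherits(norm, "normalized_matrix"))
  for (s in c(target_sample, reference_sample))
    if (!s %in% colnames(norm)) stop("unknown sample: ", s)
  a <- stats::setNames(unclass(norm)[, target_sample], rownames(norm))
  b <- stats::setNames(unclass(norm)[, reference_sample], rownames(norm))
  ok <- !is.na(a) & !is.na(b)
  if (any(!ok))
    message(sum(!ok), " assay(s) missing dCT in '", target_sample, "' or '",
            reference_sample, "' omitted from ddCT")
  (a - b)[ok]
}

#' Fold change from ddCT
#'
#' The relative-quantification mapping `2^(-ddCT)`: one cycle earlier means
#' one doubling more template, so ddCT −2 is a 4-fold induction and
#' ddCT `-log2(17)` a 17-fold one.
#'
#' @param ddct ddCT in cycles (vectorized)
#' @return dimensionless expression ratio(s)
#' @export
fold_change <- function(ddct) 2^(-ddct)
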