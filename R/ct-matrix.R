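#' CT matrix: assay-by-sample cycle-threshold values
#'
#' A `ct_matrix` is the raw input to the whole pipeline: a numeric matrix with
#' one row per assay and one column per sample, holding qPCR cycle-threshold
#' (CT) values in cycles. Wells that never crossed the fluorescence threshold
#' ("Undetermined" on the instrument) are stored as `NA` and carry explicit
#' non-detected semantics everywhere downstream. Each assay has a role:
#' `"TARGET"`, `"HOUSEKEEPER"` or `"NEGATIVE_CONTROL"`; exactly the configured
#' housekeeper ids are housekeepers.
#'
#' @param values numeric matrix; rownames are assay ids, colnames sample names.
#'   `NA` marks a non-detected well. Numeric CTs must lie in (0, 40].
#' @param housekeeper_ids assay ids to flag as housekeepers
#'   (default `RNU44`, `RNU48`, `U6` — the small RNAs present on every card).
#' @param negative_control_id assay id of the no-template/plant-miRNA control
#'   (default `ath-miR-159a`).
#'
#' @return an object of class `ct_matrix`: the value matrix with a `roles`
#'   attribute (named character vector over assays).
#' @export
ct_matrix <- function(values,
                      housekeeper_ids = c("RNU44", "RNU48", "U6"),
                      negative_control_id = "ath-miR-159a") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  assays <- rownames(values)
  samples <- colnames(values)
  if (is.null(assays) || is.null(samples))
    stop("`values` must have assay rownames and sample colnames")
  if (anyDuplicated(assays))
    stop("duplicate assay name: ", assays[duplicated(assays)][1L])
  if (anyDuplicated(samples))
    stop("duplicate sample name: ", samples[duplicated(samples)][1L])
  bad <- which(!is.na(values) & (values <= 0 | values > 40), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("CT outside (0, 40] at assay '%s', sample '%s'",
                 assays[bad[1L, 1L]], samples[bad[1L, 2L]]))
  roles <- rep("TARGET", length(assays))
  names(roles) <- assays
  roles[assays %in% housekeeper_ids] <- "HOUSEKEEPER"
  roles[assays %in% negative_control_id] <- "NEGATIVE_CONTROL"
  structure(values, roles = roles, class = c("ct_matrix", "matrix", "array"))
}

#' @export
print.ct_matrix <- function(x, ...) {
  r <- assay_roles(x)
  cat(sprintf("<ct_matrix> %d assays x %d samples (%d TARGET, %d HOUSEKEEPER, %d NEGATIVE_CONTROL), %d non-detected wells\n",
              nrow(x), ncol(x),
              sum(r == "TARGET"), sum(r == "HOUSEKEEPER"),
              sum(r == "NEGATIVE_CONTROL"), sum(is.na(x))))
  invisible(x)
}

#' Assay roles of a CT matrix
#'
#' @param x a `ct_matrix`
#' @return named character vector, one of TARGET / HOUSEKEEPER /
#'   NEGATIVE_CONTROL per assay, in row order.
#' @export
assay_roles <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  attr(x, "roles")
}

#' Subset a CT matrix, preserving assay roles
#'
#' @param ct a `ct_matrix`
#' @param assays,samples character vectors of names to keep (default all)
#' @return a `ct_matrix`
#' @export
ct_subset <- function(ct, assays = rownames(ct), samples = colnames(ct)) {
  stopifnot(inherits(ct, "ct_matrix"))
  missing_a <- setdiff(assays, rownames(ct))
  if (length(missing_a) > 0L)
    stop("unknown assay: ", paste(missing_a, collapse = ", "))
  missing_s <- setdiff(samples, colnames(ct))
  if (length(missing_s) > 0L)
    stop("unknown sample: ", paste(missing_s, collapse = ", "))
  v <- unclass(ct)[assays, samples, drop = FALSE]
  attr(v, "roles") <- assay_roles(ct)[assays]
  class(v) <- c("ct_matrix", "matrix", "array")
  v
}

GROUP_LEVELS <- c("LM", "PER", "M0")

#' Sample manifest
#'
#' Per-sample metadata driving contrasts and association tests: the metastasis
#' group (`LM` liver metastasis, `PER` peritoneal carcinomatosis, `M0` no
#' metastasis), whether the sample is a pooled array sample, and any number of
#' binary clinico-pathological attributes (e.g. `pT4_positive`,
#' `classifier_positive`) coded 0/1.
#'
#' @param sample_id character, unique
#' @param group character, each one of `"LM"`, `"PER"`, `"M0"`
#' @param is_pool logical flag per sample (default all `FALSE`)
#' @param attributes data.frame of 0/1 columns, one row per sample, or `NULL`
#' @return a data.frame of class `sample_manifest`
#' @export
sample_manifest <- function(sample_id, group, is_pool = FALSE, attributes = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1L])
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad) > 0L)
    stop("unknown group label: ", paste(bad, collapse = ", "),
         " (expected LM, PER or M0)")
  if (length(group) != length(sample_id))
    stop("`group` must have one entry per sample")
  is_pool <- rep_len(as.logical(is_pool), length(sample_id))
  m <- data.frame(sample_id = sample_id, group = group, is_pool = is_pool,
                  stringsAsFactors = FALSE)
  if (!is.null(attributes) && ncol(attributes) > 0L) {
    if (nrow(attributes) != nrow(m))
      stop("`attributes` must have one row per sample")
    for (nm in names(attributes)) {
      v <- attributes[[nm]]
      if (!all(is.na(v) | v %in% c(0L, 1L)))
        stop("attribute '", nm, "' must be coded 0/1")
      m[[nm]] <- as.integer(v)
    }
  }
  class(m) <- c("sample_manifest", "data.frame")
  m
}

#' Names of the binary attribute columns of a manifest
#' @param manifest a `sample_manifest`
#' @return character vector (possibly empty)
#' @export
manifest_attributes <- function(manifest) {
  setdiff(names(manifest), c("sample_id", "group", "is_pool"))
}

#' Group census of a manifest
#' @param manifest a `sample_manifest`
#' @param pools count pooled samples instead of patient samples?
#' @return named integer vector over LM, PER, M0
#' @export
group_census <- function(manifest, pools = FALSE) {
  m <- manifest[manifest$is_pool == pools, , drop = FALSE]
  vapply(GROUP_LEVELS, function(g) sum(m$group == g), integer(1))
}

# Map each group to its (single) pooled sample column; errors if absent.
pooled_sample_of <- function(manifest, group) {
  hit <- manifest$sample_id[manifest$is_pool & manifest$group == group]
  if (length(hit) == 0L)
    stop("contrast error: no pooled sample for group '", group, "'")
  if (length(hit) > 1L)
    stop("contrast error: multiple pooled samples for group '", group, "'")
  hit
}
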