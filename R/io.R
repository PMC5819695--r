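#' Read a CT table from delimited text
#'
#' Parses an instrument-style export: header row, first column the assay id,
#' remaining columns one per sample. Missing-value tokens (by default
#' `Undetermined`, `NA` and the empty string) map to the non-detected state.
#' Parsing is locale-independent (dot decimal separator).
#'
#' @param path file path or connection
#' @param sep field separator; TSV is canonical, `","`/`";"` accepted
#' @param missing_tokens character tokens to read as non-detected
#' @param housekeeper_ids,negative_control_id role assignment, see [ct_matrix()]
#' @return a [ct_matrix()]
#' @export
read_ct_table <- function(path, sep = "\t",
                          missing_tokens = c("Undetermined", "NA", ""),
                          housekeeper_ids = c("RNU44", "RNU48", "U6"),
                          negative_control_id = "ath-miR-159a") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("CT table needs an assay-id column plus at least one sample column")
  assays <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(assays))
    stop("duplicate assay name: ", assays[duplicated(assays)][1L])
  if (anyDuplicated(samples))
    stop("duplicate sample name: ", samples[duplicated(samples)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  nd <- vals %in% missing_tokens
  num <- suppressWarnings(as.numeric(vals))
  unparsable <- which(!nd & is.na(num), arr.ind = FALSE)
  if (length(unparsable) > 0L) {
    i <- unparsable[1L]
    stop(sprintf("unparsable CT value '%s' at assay '%s', sample '%s'",
                 vals[i], assays[(i - 1L) %% length(assays) + 1L],
                 samples[(i - 1L) %/% length(assays) + 1L]))
  }
  num[nd] <- NA_real_
  dim(num) <- dim(vals)
  dimnames(num) <- list(assays, samples)
  ct_matrix(num, housekeeper_ids = housekeeper_ids,
            negative_control_id = negative_control_id)
}

#' Write a CT table
#'
#' Deterministic writer: same matrix, byte-identical file. Non-detected wells
#' are serialized as `Undetermined`, matching the instrument convention of the
#' inputs, so `read_ct_table(write_ct_table(x))` is the identity.
#'
#' @param ct a [ct_matrix()]
#' @param path output file
#' @param sep field separator (default TSV)
#' @return `path`, invisibly
#' @export
write_ct_table <- function(ct, path, sep = "\t") {
  stopifnot(inherits(ct, "ct_matrix"))
  vals <- unclass(ct)
  txt <- matrix(format_ct(vals), nrow = nrow(vals),
                dimnames = dimnames(vals))
  df <- data.frame(assay_id = rownames(vals), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

# full-precision decimal serialization; NA -> "Undetermined"
format_ct <- function(x) {
  out <- vapply(as.vector(x), function(v) {
    if (is.na(v)) "Undetermined" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Read a sample manifest
#'
#' Expects columns `sample_id`, `group`, `is_pool` plus optional binary
#' attribute columns coded 0/1. Unknown group tokens and duplicate sample ids
#' are rejected.
#'
#' @param path file path or connection
#' @param sep field separator
#' @return a [sample_manifest()]
#' @export
read_manifest <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "is_pool")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  attr_cols <- setdiff(names(df), need)
  sample_manifest(df$sample_id, df$group,
                  is_pool = as.logical(as.integer(df$is_pool)),
                  attributes = if (length(attr_cols) > 0L)
                    df[, attr_cols, drop = FALSE] else NULL)
}

#' Write a sample manifest
#' @param manifest a [sample_manifest()]
#' @param path output file
#' @param sep field separator
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path, sep = "\t") {
  df <- as.data.frame(manifest)
  df$is_pool <- as.integer(df$is_pool)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a miRNA disease-association annotation table
#'
#' A user-supplied lookup (e.g. exported from a cancer-miRNA literature
#' database) with columns `assay_id`, `disease`, `evidence`.
#'
#' @param path file path or connection
#' @param sep field separator
#' @return data.frame with columns assay_id, disease, evidence
#' @export
read_annotation <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("assay_id", "disease")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(df$assay_id)))
    stop("annotation contains an empty assay_id")
  if (is.null(df$evidence)) df$evidence <- ""
  df[, c("assay_id", "disease", "evidence")]
}

#' Write / read a contrast-result table
#'
#' TSV with stable column order `assay_id, contrast, ddct, fold_change, call`.
#' Fold changes are serialized with 3 significant digits; ddCT at full
#' precision so that calls survive a round trip exactly.
#'
#' @param results data.frame as returned by [call_contrast()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_contrast_table <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  df <- data.frame(
    assay_id = results$assay_id,
    contrast = results$contrast,
    ddct = format(results$ddct, digits = 17, scientific = FALSE, trim = TRUE),
    fold_change = signif(results$fold_change, 3),
    call = results$call,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_contrast_table
#' @export
read_contrast_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$ddct <- as.numeric(df$ddct)
  df$fold_change <- as.numeric(df$fold_change)
  df
}

#' Write / read a triple-differential table
#'
#' One row per assay with the three per-contrast calls and the membership
#' flag; read-back reproduces every call exactly.
#'
#' @param records data.frame as returned by [triple_differential()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_triple_table <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  df <- records
  df$is_triple <- as.integer(df$is_triple)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_triple_table
#' @export
read_triple_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$is_triple <- as.logical(df$is_triple)
  df
}

#' Export a dCT matrix for heat-map rendering
#'
#' Writes the assay-by-sample dCT grid as TSV, preceded by comment lines
#' recording the observed minimum and maximum dCT — the anchors of a 3-color
#' scale (low dCT = high expression).
#'
#' @param norm a normalized (dCT) matrix from [delta_ct()]
#' @param path output file
#' @return the anchors, `c(min, max)`, invisibly
#' @export
export_dct_heatmap_matrix <- function(norm, path) {
  stopifnot(inherits(norm, "normalized_matrix"), length(norm) > 0L)
  vals <- unclass(norm)
  rng <- range(vals, na.rm = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# color_scale_min_dct: %s",
                       format(rng[1L], digits = 17, trim = TRUE)),
               sprintf("# color_scale_max_dct: %s",
                       format(rng[2L], digits = 17, trim = TRUE))), con)
  txt <- matrix(vapply(as.vector(vals), function(v)
    if (is.na(v)) "NA" else format(v, digits = 17, scientific = FALSE, trim = TRUE),
    character(1)), nrow = nrow(vals), dimnames = dimnames(vals))
  df <- data.frame(assay_id = rownames(vals), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(rng)
}

#' Read back an exported dCT heat-map matrix
#' @param path file written by [export_dct_heatmap_matrix()]
#' @return list with `values` (numeric matrix) and `anchors` (`c(min, max)`)
#' @export
read_dct_heatmap_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  anchors <- as.numeric(sub("^# color_scale_(min|max)_dct: ", "", meta))
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")], sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- df[[1L]]
  list(values = vals, anchors = anchors)
}
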