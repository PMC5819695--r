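#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table (rows = groups, columns =
#' attribute positive/negative). The two-sided p-value follows the standard
#' "probability at most that of the observed table" rule: it sums the
#' hypergeometric probabilities of every table with the observed margins whose
#' probability does not exceed the observed one (relative tie tolerance
#' 1e-7, the usual convention for floating-point equality of probabilities).
#'
#' @param table 2x2 matrix of non-negative integer counts, total > 0
#' @return the two-sided p-value, in (0, 1]
#' @export
fisher_exact_two_sided <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("`table` must be 2x2")
  if (any(m < 0) || any(m != round(m)) || sum(m) == 0)
    stop("`table` must hold non-negative integer counts with a positive total")
  r1 <- m[1L, 1L] + m[1L, 2L]
  r2 <- m[2L, 1L] + m[2L, 2L]
  c1 <- m[1L, 1L] + m[2L, 1L]
  c2 <- m[1L, 2L] + m[2L, 2L]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    message("degenerate 2x2 table (empty margin); p = 1")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(m[1L, 1L], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sample t by default (`df = nA + nB - 2`); Welch's
#' unequal-variance form available behind a flag. Degenerate zero-variance
#' inputs return p = 1 when the means agree and p = 0 (flagged) when they do
#' not.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2, finite
#' @param welch use the Welch-Satterthwaite approximation instead of the
#'   pooled-variance form (default `FALSE`)
#' @return list with `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`, `degenerate`
#' @export
students_t_two_sample <- function(values_a, values_b, welch = FALSE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("values must be finite")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  out <- list(mean_a = ma, mean_b = mb,
              sem_a = sqrt(va / na), sem_b = sqrt(vb / nb),
              degenerate = FALSE)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) return(degenerate_t(out, ma, mb))
    out$t <- (ma - mb) / sqrt(se2)
    out$df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    if (sp2 == 0) return(degenerate_t(out, ma, mb))
    out$t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    out$df <- df
  }
  out$p <- 2 * stats::pt(-abs(out$t), out$df)
  out
}

degenerate_t <- function(out, ma, mb) {
  out$degenerate <- ma != mb
  out$t <- if (ma == mb) 0 else sign(ma - mb) * Inf
  out$df <- NA_real_
  out$p <- if (ma == mb) 1 else 0
  if (out$degenerate)
    message("zero pooled variance with unequal means; p = 0 (degenerate)")
  out
}

#' Whole-cohort single-assay validation
#'
#' Compares per-patient expression of selected assays between two groups on
#' the full cohort: the fold change is the ratio of group mean linear
#' expressions (`2^-dCT`), the per-group SEM accompanies it, and significance
#' comes from a Student's t-test at level `alpha`. The test can run on the
#' linear scale (default, matching mean-and-SEM bar plots) or on the dCT
#' scale.
#'
#' @param per_sample_dct `normalized_matrix` of per-patient dCT values
#' @param manifest [sample_manifest()] covering the patients
#' @param assays assay ids to validate
#' @param groups `c(numerator group, reference group)`
#'   (default `c("PER", "LM")`)
#' @param alpha significance level (default 0.05)
#' @param scale `"linear"` (test on `2^-dCT`) or `"dct"`
#' @param welch passed to [students_t_two_sample()]
#' @return data.frame, one row per testable assay: group sizes, means and
#'   SEMs on the tested scale, fold change, t, df, p, `significant`; assays
#'   with fewer than 2 usable values in either group are skipped with a
#'   message, assays absent from the matrix are reported as `missing`
#' @export
whole_cohort_validation <- function(per_sample_dct, manifest, assays,
                                    groups = c("PER", "LM"), alpha = 0.05,
                                    scale = c("linear", "dct"), welch = FALSE) {
  stopifnot(inherits(per_sample_dct, "normalized_matrix"),
            inherits(manifest, "sample_manifest"))
  scale <- match.arg(scale)
  m <- manifest[!manifest$is_pool, , drop = FALSE]
  sa <- intersect(m$sample_id[m$group == groups[1L]], colnames(per_sample_dct))
  sb <- intersect(m$sample_id[m$group == groups[2L]], colnames(per_sample_dct))
  rows <- lapply(assays, function(id) {
    base <- data.frame(assay_id = id, group_a = groups[1L], group_b = groups[2L],
                       stringsAsFactors = FALSE)
    if (!id %in% rownames(per_sample_dct)) {
      base$status <- "missing"
      return(pad_validation_row(base))
    }
    da <- unclass(per_sample_dct)[id, sa]; da <- da[!is.na(da)]
    db <- unclass(per_sample_dct)[id, sb]; db <- db[!is.na(db)]
    if (length(da) < 2L || length(db) < 2L) {
      message("assay '", id, "' skipped: fewer than 2 usable values in a group")
      base$status <- "skipped"
      return(pad_validation_row(base))
    }
    lin_a <- 2^-da; lin_b <- 2^-db
    va <- if (scale == "linear") lin_a else da
    vb <- if (scale == "linear") lin_b else db
    tt <- students_t_two_sample(va, vb, welch = welch)
    base$status <- "tested"
    base$n_a <- length(da); base$n_b <- length(db)
    base$mean_a <- tt$mean_a; base$mean_b <- tt$mean_b
    base$sem_a <- tt$sem_a; base$sem_b <- tt$sem_b
    base$fold_change <- mean(lin_a) / mean(lin_b)
    base$t <- tt$t; base$df <- tt$df; base$p <- tt$p
    base$significant <- tt$p < alpha
    base
  })
  do.call(rbind, rows)
}

pad_validation_row <- function(base) {
  for (nm in c("n_a", "n_b", "mean_a", "mean_b", "sem_a", "sem_b",
               "fold_change", "t", "df", "p"))
    base[[nm]] <- NA_real_
  base$significant <- NA
  base
}

#' Group-by-attribute association
#'
#' Builds the 2x2 contingency table of a binary clinical attribute across two
#' groups and applies the two-sided Fisher exact test — e.g. pT4 status 7/10
#' in the peritoneal group vs 0/10 in the liver-metastasis group.
#'
#' @param manifest [sample_manifest()] (patient rows are used)
#' @param attribute name of a 0/1 attribute column
#' @param group_a,group_b group labels (rows of the table, in this order;
#'   columns are attribute positive / negative)
#' @return list with `table` (2x2 matrix) and `p`
#' @export
attribute_association <- function(manifest, attribute, group_a, group_b) {
  stopifnot(inherits(manifest, "sample_manifest"))
  if (!attribute %in% manifest_attributes(manifest))
    stop("unknown attribute: ", attribute)
  m <- manifest[!manifest$is_pool & manifest$group %in% c(group_a, group_b), ,
                drop = FALSE]
  v <- m[[attribute]]
  if (anyNA(v))
    stop("missing '", attribute, "' value for sample ",
         m$sample_id[which(is.na(v))[1L]])
  tab <- matrix(c(sum(m$group == group_a & v == 1L),
                  sum(m$group == group_a & v == 0L),
                  sum(m$group == group_b & v == 1L),
                  sum(m$group == group_b & v == 0L)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c(group_a, group_b), c("positive", "negative")))
  list(table = tab, p = fisher_exact_two_sided(tab))
}
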