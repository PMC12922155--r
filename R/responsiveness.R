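# Responsiveness calling: fold change on the linear scale, Student's t-test
# on log2 abundances, the >2-fold & p<0.05 rule at >=1 post-treatment
# timepoint, collapse to responsive proteins, and PCA-based QC.

#' Configuration of the responsiveness test
#'
#' A peptide is called responsive when, at at least one tested timepoint, the
#' fold change versus baseline strictly exceeds `fc_threshold` and the
#' two-sample t-test p-value is strictly below `alpha`. Only increases are
#' called: the comparative analysis downstream consumes hormone-*induced*
#' phosphorylation.
#'
#' @param fc_threshold fold-change gate (linear scale, strict `>`), default 2.
#' @param alpha significance gate (strict `<`), default 0.05.
#' @param timepoints_tested post-treatment timepoints compared to 0 min.
#' @param min_replicates minimum non-missing replicates per condition for a
#'   timepoint to be testable, default 2.
#' @param log2_test if `TRUE` (default) the t-test runs on log2 abundances;
#'   fold change is always the ratio of linear means.
#' @param var_equal if `TRUE` (default) classical pooled-variance Student's
#'   t-test; `FALSE` gives Welch.
#' @param p_adjust multiple-testing correction applied per timepoint
#'   ("none", default, or any [stats::p.adjust] method).
#' @return a list of class `"stat_config"`.
#' @export
stat_config <- function(fc_threshold = 2, alpha = 0.05,
                        timepoints_tested = c(15L, 30L, 90L),
                        min_replicates = 2L, log2_test = TRUE,
                        var_equal = TRUE, p_adjust = "none") {
  stopifnot(fc_threshold > 1, alpha > 0, alpha < 1, min_replicates >= 2)
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 timepoints_tested = as.integer(timepoints_tested),
                 min_replicates = as.integer(min_replicates),
                 log2_test = log2_test, var_equal = var_equal,
                 p_adjust = p_adjust),
            class = "stat_config")
}

#' Fold change between two replicate groups
#'
#' Ratio of linear-scale means, treated over baseline. Returns `NA` (not
#' testable) when either group has fewer than `min_replicates` non-missing
#' values or the baseline mean is zero.
#'
#' @param treated,baseline numeric vectors of replicate abundances.
#' @param min_replicates minimum usable replicates per group.
#' @return ratio, or `NA_real_` when not testable.
#' @export
fold_change <- function(treated, baseline, min_replicates = 2L) {
  treated <- treated[!is.na(treated)]
  baseline <- baseline[!is.na(baseline)]
  if (length(treated) < min_replicates || length(baseline) < min_replicates) {
    return(NA_real_)
  }
  mb <- mean(baseline)
  if (mb == 0) return(NA_real_)
  mean(treated) / mb
}

#' Two-sample Student's t-test with degenerate-variance conventions
#'
#' Two-sided, unpaired t-test (pooled variance by default, Welch optionally).
#' Conventions for zero within-group variance: equal means give p = 1,
#' unequal means give p = 0. Returns `NA` when either group has fewer than
#' two non-missing values.
#'
#' @param x,y numeric vectors (typically log2 abundances).
#' @param var_equal pooled (classical Student) if `TRUE`, default.
#' @return the p-value.
#' @export
student_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Call hormone-responsive phosphopeptides
#'
#' For each peptide and each tested timepoint, computes the fold change of
#' linear means versus 0 min and the t-test p-value (on log2 abundances by
#' default). A peptide is `responsive` when some tested timepoint passes both
#' strict gates; `first_responsive_timepoint` is the earliest such timepoint.
#' Peptides with no testable timepoint are flagged `"insufficient data"` and
#' are never responsive.
#'
#' @param peptides phosphopeptide data.frame from
#'   [read_phosphopeptide_table()] or the synthetic generator.
#' @param config a [stat_config()].
#' @return data.frame with per-timepoint `fc_*`/`p_*` columns, `responsive`,
#'   `first_responsive_timepoint` and `status`.
#' @export
call_responsive <- function(peptides, config = stat_config()) {
  tps <- config$timepoints_tested
  n <- nrow(peptides)
  base_cols <- condition_columns(0L)
  baseline <- as.matrix(peptides[, base_cols, drop = FALSE])
  out <- data.frame(peptide_id = peptides$peptide_id,
                    protein_accession = peptides$protein_accession,
                    stringsAsFactors = FALSE)
  fc <- p <- matrix(NA_real_, n, length(tps),
                    dimnames = list(NULL, as.character(tps)))
  for (j in seq_along(tps)) {
    treated <- as.matrix(peptides[, condition_columns(tps[j]), drop = FALSE])
    for (i in seq_len(n)) {
      tr <- treated[i, ]
      bl <- baseline[i, ]
      fc[i, j] <- fold_change(tr, bl, config$min_replicates)
      if (!is.na(fc[i, j])) {
        if (config$log2_test) {
          tr <- log2(tr[!is.na(tr) & tr > 0])
          bl <- log2(bl[!is.na(bl) & bl > 0])
        } else {
          tr <- tr[!is.na(tr)]
          bl <- bl[!is.na(bl)]
        }
        if (length(tr) >= config$min_replicates &&
            length(bl) >= config$min_replicates) {
          p[i, j] <- student_t_test(tr, bl, config$var_equal)
        } else {
          fc[i, j] <- NA_real_   # log-transform lost too many replicates
        }
      }
    }
    if (config$p_adjust != "none") {
      p[, j] <- stats::p.adjust(p[, j], method = config$p_adjust)
    }
    out[[sprintf("fc_%d", tps[j])]] <- fc[, j]
    out[[sprintf("p_%d", tps[j])]] <- p[, j]
  }
  hit <- !is.na(fc) & !is.na(p) & fc > config$fc_threshold & p < config$alpha
  out$responsive <- rowSums(hit) > 0
  out$first_responsive_timepoint <- apply(hit, 1L, function(h) {
    if (any(h)) tps[which(h)[1L]] else NA_integer_
  })
  out$status <- ifelse(rowSums(!is.na(fc)) == 0, "insufficient data", "ok")
  out
}

#' Collapse peptide calls to responsive proteins
#'
#' A protein is responsive iff at least one of its phosphopeptides is
#' responsive. Output is sorted and deduplicated.
#'
#' @param calls output of [call_responsive()].
#' @return character vector of responsive protein accessions.
#' @export
collapse_to_proteins <- function(calls) {
  sort(unique(calls$protein_accession[calls$responsive]))
}

#' PCA quality control of the quantification matrix
#'
#' Column-centered principal component analysis of the log2 abundance matrix
#' (peptides in rows, samples in columns). Rows containing any missing value
#' are dropped for the PCA only. A deterministic sign convention is applied:
#' within each component the loading of largest magnitude is made positive.
#'
#' @param log2_matrix numeric matrix, peptides x samples; column names are
#'   sample labels.
#' @param n_components number of components to return scores for (default 2).
#' @return a list with `scores` (samples x components), `prop_var`
#'   (proportion of variance per component) and `n_rows_used`; `NULL` with a
#'   warning when fewer than 3 complete rows exist.
#' @export
pca_qc <- function(log2_matrix, n_components = 2L) {
  complete <- stats::complete.cases(log2_matrix)
  x <- log2_matrix[complete, , drop = FALSE]
  if (nrow(x) < 3L) {
    warning("fewer than 3 complete peptide rows; PCA QC skipped")
    return(NULL)
  }
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pr$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  list(scores = scores,
       prop_var = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)],
       n_rows_used = nrow(x))
}

#' Log2 abundance matrix of a phosphopeptide table
#'
#' @param peptides phosphopeptide data.frame.
#' @return numeric matrix peptides x samples (log2; zeros become `NA`).
#' @export
log2_abundance_matrix <- function(peptides) {
  m <- as.matrix(peptides[, abundance_columns(), drop = FALSE])
  m[!is.na(m) & m <= 0] <- NA
  rownames(m) <- peptides$peptide_id
  log2(m)
}

#' Mean silhouette width of a sample grouping on PCA scores
#'
#' Convenience QC metric: how cleanly a labeling (e.g. timepoint) separates
#' on the first two principal components.
#'
#' @param scores samples x components score matrix from [pca_qc()].
#' @param labels grouping vector, one per sample.
#' @return mean silhouette width.
#' @export
silhouette_score <- function(scores, labels) {
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) stop("need at least two groups")
  sil <- cluster::silhouette(cl, stats::dist(scores))
  mean(sil[, "sil_width"])
}
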