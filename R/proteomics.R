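# Label-free proteomics containers, normalization/filtering, per-line log2
# ratios, the Table-style selection rules and fold/percent conversions.

#' Protein quantification container
#'
#' Bundles a proteins x samples abundance table (wide tibble, one column per
#' sample, `NA` = not detected), a sample sheet and per-protein annotations.
#'
#' @param abundance Tibble: `protein_id` plus one numeric column per sample
#'   (non-negative normalized abundances; zeros are treated as missing).
#' @param samples Tibble: `sample_id`, `group`.
#' @param proteins Tibble: `protein_id` plus annotation columns (at least
#'   `peptides`; optionally `unique_peptides`, `description`, `location`,
#'   `encoded`).
#' @return A `protein_quant` object.
#' @export
protein_quant <- function(abundance, samples, proteins) {
  if (!"protein_id" %in% names(abundance)) abort("`abundance` needs a `protein_id` column.")
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` needs columns `sample_id` and `group`.")
  }
  missing_cols <- setdiff(samples$sample_id, names(abundance))
  if (length(missing_cols)) {
    abort(paste0("Samples absent from the abundance table: ",
                 paste(missing_cols, collapse = ", ")))
  }
  vals <- as.matrix(abundance[samples$sample_id])
  if (any(vals < 0, na.rm = TRUE)) abort("Abundances must be >= 0.")
  x <- list(abundance = tibble::as_tibble(abundance),
            samples = tibble::as_tibble(samples),
            proteins = tibble::as_tibble(proteins))
  class(x) <- "protein_quant"
  x
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("<protein_quant> ", nrow(x$abundance), " proteins x ",
      nrow(x$samples), " samples\n", sep = "")
  grp <- table(x$samples$group)
  cat("  groups: ", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "),
      "\n", sep = "")
  pre <- attr(x, "preprocessed", exact = TRUE)
  if (isTRUE(pre)) cat("  preprocessed (normalized + missingness-filtered)\n")
  invisible(x)
}

pq_matrix <- function(pq, sample_ids = pq$samples$sample_id) {
  m <- as.matrix(pq$abundance[sample_ids])
  rownames(m) <- pq$abundance$protein_id
  m[m == 0] <- NA_real_   # zeros carry no quantitative information
  m
}

#' Normalize columns and filter by missingness for a two-group comparison
#'
#' Each sample column is rescaled so that its total abundance over the
#' commonly observed proteins equals the grand mean of the raw totals
#' (total-abundance normalization). Proteins missing in two or more
#' biological replicates of either comparison group are then dropped; the
#' removed proteins are recorded in the `dropped` attribute. The operation
#' is idempotent.
#'
#' @param pq A [protein_quant].
#' @param groups Character vector of the two group labels being compared;
#'   defaults to all groups (missingness then assessed per group).
#' @param max_missing Maximum missing replicates tolerated per group
#'   (default 1, i.e. proteins with `NA` in two or more replicates of a
#'   group are excluded).
#' @param scope `"per_comparison"` restricts samples to the chosen groups
#'   before filtering (the strictest reading of the exclusion rule);
#'   `"all_samples"` keeps every sample and applies the missingness rule per
#'   group across all of them.
#' @return A filtered, normalized `protein_quant` for the selected samples.
#' @export
preprocess_abundances <- function(pq, groups = unique(pq$samples$group),
                                  max_missing = 1,
                                  scope = c("per_comparison", "all_samples")) {
  scope <- match.arg(scope)
  samples <- if (scope == "per_comparison") {
    dplyr::filter(pq$samples, .data$group %in% groups)
  } else {
    pq$samples
  }
  if (any(table(samples$group) < 2)) abort("Each group needs at least 2 samples.")
  m <- pq_matrix(pq, samples$sample_id)
  if (any(colSums(!is.na(m)) == 0)) abort("A sample column is entirely missing.")
  n_miss <- sapply(groups, function(g) {
    cols <- samples$sample_id[samples$group == g]
    rowSums(is.na(m[, cols, drop = FALSE]))
  })
  keep <- rowSums(n_miss > max_missing) == 0
  dropped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  common <- complete.cases(m)
  if (!any(common)) abort("No retained protein is observed in every sample; cannot normalize.")
  totals <- colSums(m[common, , drop = FALSE])
  scale <- mean(totals) / totals
  m_norm <- sweep(m, 2, scale, `*`)
  abundance <- dplyr::bind_cols(
    tibble::tibble(protein_id = rownames(m)),
    tibble::as_tibble(m_norm)
  )
  out <- protein_quant(
    abundance = abundance,
    samples = samples,
    proteins = dplyr::filter(pq$proteins, .data$protein_id %in% abundance$protein_id)
  )
  attr(out, "preprocessed") <- TRUE
  attr(out, "dropped") <- dropped
  attr(out, "truth") <- attr(pq, "truth", exact = TRUE)
  out
}

#' Per-protein log2 mutant/reference abundance ratio
#'
#' `log2(mean(mutant) / mean(reference))` over observed values only —
#' the ratio-of-arithmetic-means convention of proteomics-platform ratio
#' tables. Set `method = "mean_of_logs"` for the mean paired log-ratio
#' alternative.
#'
#' @param pq A preprocessed [protein_quant].
#' @param mutant_group,ref_group Group labels.
#' @param method Ratio convention (see above).
#' @return Tibble: `protein_id`, `log2_ratio`.
#' @export
log2_group_ratio <- function(pq, mutant_group, ref_group,
                             method = c("ratio_of_means", "mean_of_logs")) {
  method <- match.arg(method)
  cols_mut <- pq$samples$sample_id[pq$samples$group == mutant_group]
  cols_ref <- pq$samples$sample_id[pq$samples$group == ref_group]
  if (!length(cols_mut) || !length(cols_ref)) abort("Unknown group label.")
  m <- pq_matrix(pq)
  mean_mut <- rowMeans(m[, cols_mut, drop = FALSE], na.rm = TRUE)
  mean_ref <- rowMeans(m[, cols_ref, drop = FALSE], na.rm = TRUE)
  if (method == "ratio_of_means") {
    bad <- !is.na(mean_ref) & mean_ref == 0
    if (any(bad)) warn("Zero reference mean for some proteins; ratio set to NA.")
    lr <- ifelse(bad, NA_real_, log2(mean_mut / mean_ref))
  } else {
    lr <- rowMeans(log2(m[, cols_mut, drop = FALSE]), na.rm = TRUE) -
      rowMeans(log2(m[, cols_ref, drop = FALSE]), na.rm = TRUE)
  }
  tibble::tibble(protein_id = rownames(m), log2_ratio = unname(lr))
}

#' Select concordantly regulated proteins (published-table rules)
#'
#' Keeps proteins that are significant (`fdr < fdr_max`) in *both* mutant
#' lines, change in the same direction in both, reach `|log2 ratio| >=
#' log2_min` in at least one line (boundary included), and were identified
#' by at least `min_peptides` peptides.
#'
#' @param diff_line1,diff_line2 Per-line results sharing `protein_id`,
#'   `log2_ratio` and `fdr` columns (see [rots_test()] results joined with
#'   [log2_group_ratio()]).
#' @param annotations Tibble with `protein_id` and `peptides` (plus any
#'   annotation columns, which are carried through).
#' @param fdr_max,log2_min,min_peptides Selection thresholds.
#' @return Tibble of selected proteins with both lines' ratios and FDRs.
#' @export
select_regulated <- function(diff_line1, diff_line2, annotations,
                             fdr_max = 0.05, log2_min = 0.5, min_peptides = 2) {
  if (!setequal(diff_line1$protein_id, diff_line2$protein_id)) {
    only1 <- setdiff(diff_line1$protein_id, diff_line2$protein_id)
    only2 <- setdiff(diff_line2$protein_id, diff_line1$protein_id)
    abort(paste0("Result tables cover different proteins. Only in line 1: ",
                 paste(head(only1, 5), collapse = ", "),
                 "; only in line 2: ", paste(head(only2, 5), collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    dplyr::select(diff_line1, "protein_id", log2_line1 = "log2_ratio", fdr_line1 = "fdr"),
    dplyr::select(diff_line2, "protein_id", log2_line2 = "log2_ratio", fdr_line2 = "fdr"),
    by = "protein_id"
  ) %>%
    dplyr::left_join(annotations, by = "protein_id")
  joined %>%
    dplyr::filter(
      .data$fdr_line1 < fdr_max,
      .data$fdr_line2 < fdr_max,
      sign(.data$log2_line1) == sign(.data$log2_line2),
      pmax(abs(.data$log2_line1), abs(.data$log2_line2)) >= log2_min,
      .data$peptides >= min_peptides
    )
}

#' Convert log2 ratios to folds and percent-of-reference
#'
#' `fold = 2^x`; `percent_of_reference = 100 * 2^x`. Presentation helpers:
#' `percent_floor` (the floored integer percent used when quoting "declined
#' to N% of reference") and `fold_round` (the rounded fold used when quoting
#' "N-fold higher").
#'
#' @param log2_ratio Numeric vector of log2 ratios.
#' @return Tibble: `log2_ratio`, `fold`, `percent_of_reference`,
#'   `percent_floor`, `fold_round`.
#' @examples
#' fold_conversions(c(-1.35, -1.96))  # 39% and 25% of reference
#' @export
fold_conversions <- function(log2_ratio) {
  if (any(!is.finite(log2_ratio))) abort("`log2_ratio` must be finite.")
  fold <- 2^log2_ratio
  tibble::tibble(
    log2_ratio = log2_ratio,
    fold = fold,
    percent_of_reference = 100 * fold,
    percent_floor = floor(100 * fold),
    fold_round = round(fold)
  )
}
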