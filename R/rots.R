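# Reproducibility-optimized test statistic (ROTS) for two-group label-free
# proteomics, with bootstrap top-list reproducibility optimization and
# permutation-based p-values and FDR.

# Regularized two-group statistic family on log2 abundances:
#   d(a1, a2) = |mean1 - mean2| / (a1 + a2 * se_pooled)
# computed over observed values only. Returns the numerator and pooled
# standard error so the grid of (a1, a2) can be applied cheaply.
rots_stat_parts <- function(x, idx1, idx2) {
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  pooled_var <- ifelse(df > 0, (ss1 + ss2) / pmax(df, 1), NA_real_)
  se <- sqrt(pooled_var * (1 / n1 + 1 / n2))
  list(num = abs(m1 - m2), se = se, n1 = n1, n2 = n2)
}

rots_d <- function(parts, a1, a2) {
  d <- parts$num / (a1 + a2 * parts$se)
  d[!is.finite(d)] <- 0
  d
}

# Top-k overlap profile for a pair of rankings: overlap[k] = |top_k(1) n
# top_k(2)| / k, evaluated at the requested k values.
toplist_overlap <- function(d1, d2, topk) {
  n <- length(d1)
  r1 <- rank(-d1, ties.method = "first")
  r2 <- rank(-d2, ties.method = "first")
  worst <- pmax(r1, r2)
  cum <- cumsum(tabulate(worst, nbins = n))
  cum[topk] / topk
}

default_param_grid <- function() {
  tibble::tibble(
    a1 = c(0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 1),
    a2 = c(1, 1, 1, 1, 1, 1, 1, 0)
  )
}

default_topk_grid <- function(n_prot) {
  k <- c(25, 50, 100, 200, 400, 800)
  unique(pmin(k[k <= n_prot | k == 25], max(n_prot - 1, 1)))
}

#' Reproducibility-optimized differential-abundance test
#'
#' Tests each protein for a two-group difference on log2-transformed
#' normalized abundances with the regularized statistic
#' `d(a1, a2) = |mean1 - mean2| / (a1 + a2 * se_pooled)`. The
#' regularization `(a1, a2)` and the top-list size `k` are not fixed a
#' priori: they are chosen to maximize the reproducibility Z-score
#' `Z_k = (R_k - R0_k) / sd(R_k)`, where `R_k` is the average top-k overlap
#' between rankings from pairs of within-group bootstrap resamples and
#' `R0_k` the same under group-label permutation. P-values come from the
#' permutation null of the selected statistic, pooled across proteins, and
#' the FDR at rank `r` is the mean permutation count of null statistics at
#' least as large as the observed r-th statistic divided by `r`, monotonized
#' from the bottom of the ranking.
#'
#' @param pq A preprocessed [protein_quant] (see [preprocess_abundances()]).
#' @param groups Length-2 character vector: the two groups to compare
#'   (test group first, reference second).
#' @param B Number of bootstrap/permutation pairs for the optimization
#'   (study protocol: 1000).
#' @param param_grid Tibble of candidate `(a1, a2)` regularizations; `a1`
#'   has a positive floor wherever `a2 = 1` so zero pooled variance cannot
#'   produce infinite statistics.
#' @param topk_grid Candidate top-list sizes.
#' @param n_perm Number of group-label permutations for p/FDR estimation.
#' @param seed Integer seed (bootstraps and permutations are drawn on
#'   samples sorted by id, so results are invariant to input row/column
#'   order).
#' @return A `rots_result`: list with `table` (protein_id, log2_ratio, d, p,
#'   fdr) and run metadata (`a1`, `a2`, `k`, `z`, `B`, `n_perm`, `seed`,
#'   `groups`).
#' @references The reproducibility-optimization scheme follows the
#'   published ROTS family of statistics for omics data.
#' @export
rots_test <- function(pq, groups, B = 1000, param_grid = default_param_grid(),
                      topk_grid = NULL, n_perm = 1000, seed = 1L) {
  if (B < 2) abort("`B` must be at least 2.")
  if (nrow(param_grid) == 0) abort("`param_grid` is empty.")
  if (length(groups) != 2) abort("`groups` must name exactly two groups.")
  samples <- dplyr::filter(pq$samples, .data$group %in% groups) %>%
    dplyr::arrange(.data$sample_id)
  ids_order <- order(pq$abundance$protein_id)
  m <- pq_matrix(pq, samples$sample_id)[ids_order, , drop = FALSE]
  x <- log2(m)
  n_prot <- nrow(x)
  if (is.null(topk_grid)) topk_grid <- default_topk_grid(n_prot)
  topk_grid <- sort(unique(pmin(topk_grid, n_prot)))
  idx1 <- which(samples$group == groups[1])
  idx2 <- which(samples$group == groups[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    abort("Each group needs at least 2 replicates.")
  }
  n_grid <- nrow(param_grid)
  n_k <- length(topk_grid)

  with_seed(seed, {
    boot_cols <- function() {
      c(sample(idx1, length(idx1), replace = TRUE),
        sample(idx2, length(idx2), replace = TRUE))
    }
    perm_boot_cols <- function() {
      perm <- sample(c(idx1, idx2))
      p1 <- perm[seq_along(idx1)]
      p2 <- perm[-seq_along(idx1)]
      c(sample(p1, length(p1), replace = TRUE),
        sample(p2, length(p2), replace = TRUE))
    }
    i1 <- seq_along(idx1)
    i2 <- length(idx1) + seq_along(idx2)
    d_for_cols <- function(cols) {
      parts <- rots_stat_parts(x[, cols, drop = FALSE], i1, i2)
      lapply(seq_len(n_grid), function(g) {
        rots_d(parts, param_grid$a1[g], param_grid$a2[g])
      })
    }
    overlap_obs <- array(NA_real_, c(B, n_grid, n_k))
    overlap_null <- array(NA_real_, c(B, n_grid, n_k))
    for (b in seq_len(B)) {
      db1 <- d_for_cols(boot_cols()); db2 <- d_for_cols(boot_cols())
      dn1 <- d_for_cols(perm_boot_cols()); dn2 <- d_for_cols(perm_boot_cols())
      for (g in seq_len(n_grid)) {
        overlap_obs[b, g, ] <- toplist_overlap(db1[[g]], db2[[g]], topk_grid)
        overlap_null[b, g, ] <- toplist_overlap(dn1[[g]], dn2[[g]], topk_grid)
      }
    }
    z <- matrix(NA_real_, n_grid, n_k)
    for (g in seq_len(n_grid)) {
      for (j in seq_len(n_k)) {
        s <- sd(overlap_obs[, g, j])
        if (is.finite(s) && s > 0) {
          z[g, j] <- (mean(overlap_obs[, g, j]) - mean(overlap_null[, g, j])) / s
        }
      }
    }
    if (all(is.na(z))) abort("Reproducibility optimization degenerated (no variance in overlaps).")
    best <- which(z == max(z, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a1 <- param_grid$a1[best[1]]
    a2 <- param_grid$a2[best[1]]
    k_best <- topk_grid[best[2]]

    parts_obs <- rots_stat_parts(x, idx1, idx2)
    d_obs <- rots_d(parts_obs, a1, a2)

    null_d <- matrix(NA_real_, n_prot, n_perm)
    all_cols <- c(idx1, idx2)
    for (p in seq_len(n_perm)) {
      perm <- sample(all_cols)
      parts <- rots_stat_parts(x[, perm, drop = FALSE], i1, i2)
      null_d[, p] <- rots_d(parts, a1, a2)
    }
    sorted_null <- sort(as.vector(null_d))
    n_null <- length(sorted_null)
    cnt_ge <- n_null - findInterval(d_obs - 1e-12, sorted_null)
    p_val <- (cnt_ge + 1) / (n_null + 1)

    ord <- order(d_obs, decreasing = TRUE)
    fdr <- numeric(n_prot)
    fdr[ord] <- (cnt_ge[ord] / n_perm) / seq_len(n_prot)
    fdr[ord] <- rev(cummin(rev(pmin(fdr[ord], 1))))

    lr <- log2_group_ratio(pq, groups[1], groups[2])
    lr <- lr$log2_ratio[match(rownames(x), lr$protein_id)]
    out <- list(
      table = tibble::tibble(
        protein_id = rownames(x),
        log2_ratio = lr,
        d = d_obs, p = p_val, fdr = fdr
      ),
      a1 = a1, a2 = a2, k = k_best, z = max(z, na.rm = TRUE),
      B = B, n_perm = n_perm, seed = seed, groups = groups
    )
    class(out) <- "rots_result"
    out
  })
}

#' @export
print.rots_result <- function(x, ...) {
  cat("<rots_result> ", x$groups[1], " vs ", x$groups[2], "\n", sep = "")
  cat(sprintf("  statistic: d = |m1 - m2| / (%.3g + %.3g * se), top-k = %d (Z = %.2f)\n",
              x$a1, x$a2, x$k, x$z))
  cat(sprintf("  B = %d bootstraps, %d permutations, seed %d\n",
              x$B, x$n_perm, as.integer(x$seed)))
  cat(sprintf("  %d proteins, %d at FDR < 0.05\n",
              nrow(x$table), sum(x$table$fdr < 0.05)))
  invisible(x)
}

#' @rdname rots_test
#' @param x,object A `rots_result`.
#' @param ... Unused.
#' @export
tidy.rots_result <- function(x, ...) x$table

#' @rdname rots_test
#' @export
glance.rots_result <- function(x, ...) {
  tibble::tibble(a1 = x$a1, a2 = x$a2, k = x$k, z = x$z, B = x$B,
                 n_perm = x$n_perm, seed = as.integer(x$seed),
                 n_proteins = nrow(x$table),
                 n_fdr05 = sum(x$table$fdr < 0.05))
}

#' @rdname rots_test
#' @export
autoplot.rots_result <- function(object, ...) {
  df <- object$table %>%
    dplyr::mutate(significant = .data$fdr < 0.05 & .data$p < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 ratio", y = "-log10 p",
                  title = sprintf("%s vs %s (a1 = %.2g, a2 = %g, k = %d)",
                                  object$groups[1], object$groups[2],
                                  object$a1, object$a2, object$k))
}
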