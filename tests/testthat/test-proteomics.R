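test_that("preprocessing drops proteins missing in >= 2 replicates per group", {
  vals <- rbind(
    c(10, 11, 12, 13, 14,   20, 21, 22, 23, 24),   # complete
    c(NA, NA, 12, 13, 14,   20, 21, 22, 23, 24),   # 2 missing in group A
    c(NA, 11, 12, 13, 14,   20, NA, 22, 23, 24),   # 1 missing in each
    c(10, 11, 12, 13, 14,   NA, NA, NA, 23, 24)    # 3 missing in group B
  )
  pq <- toy_protein_quant(vals, rep(c("A", "B"), each = 5))
  pre <- preprocess_abundances(pq, groups = c("A", "B"))
  expect_setequal(pre$abundance$protein_id, c("prot01", "prot03"))
  expect_setequal(attr(pre, "dropped"), c("prot02", "prot04"))
  # a looser rule keeps the 2-missing protein
  pre2 <- preprocess_abundances(pq, groups = c("A", "B"), max_missing = 2)
  expect_true("prot02" %in% pre2$abundance$protein_id)
})

test_that("normalization equalizes column totals and is idempotent", {
  set.seed(5)
  vals <- matrix(rlnorm(200, 10, 1), nrow = 20)
  vals[sample(length(vals), 8)] <- NA
  pq <- toy_protein_quant(vals, rep(c("A", "B"), each = 5))
  pre <- preprocess_abundances(pq, groups = c("A", "B"))
  m <- as.matrix(pre$abundance[-1])
  common <- stats::complete.cases(m)
  totals <- colSums(m[common, , drop = FALSE])
  expect_lt(diff(range(totals)) / mean(totals), 1e-12)
  twice <- preprocess_abundances(pre, groups = c("A", "B"))
  expect_equal(twice$abundance, pre$abundance, tolerance = 1e-12)
  # fully missing column
  vals2 <- vals; vals2[, 1] <- NA
  expect_error(preprocess_abundances(toy_protein_quant(vals2, rep(c("A", "B"), each = 5))),
               "entirely missing")
})

test_that("log2_group_ratio follows the ratio-of-means convention", {
  vals <- rbind(c(4, 4, 8, 8), c(2, 6, 4, 12), c(5, 5, 5, 5))
  pq <- toy_protein_quant(vals, c("B", "B", "A", "A"))
  lr <- log2_group_ratio(pq, "A", "B")
  expect_equal(lr$log2_ratio, c(1, 1, 0))   # mean A / mean B
  # mean-of-logs alternative differs for protein 2
  lr2 <- log2_group_ratio(pq, "A", "B", method = "mean_of_logs")
  expect_equal(lr2$log2_ratio[1], 1)
  expect_equal(lr2$log2_ratio[2],
               mean(log2(c(4, 12))) - mean(log2(c(2, 6))))
})

test_that("select_regulated equals a brute-force clause filter", {
  tbl <- function(ids, lfc, fdr) tibble::tibble(protein_id = ids,
                                                log2_ratio = lfc, fdr = fdr)
  ids <- sprintf("p%d", 1:6)
  line1 <- tbl(ids, c( 0.8, 0.6, 0.4, 0.6, -0.6, 0.9),
                    c(0.01, 0.01, 0.01, 0.20, 0.01, 0.01))
  line2 <- tbl(ids, c( 0.7, -0.6, 0.45, 0.7, -0.8, 0.3),
                    c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  ann <- tibble::tibble(protein_id = ids,
                        peptides = c(3L, 3L, 3L, 3L, 3L, 1L))
  sel <- select_regulated(line1, line2, ann)
  # brute force over all four clauses
  brute <- character()
  for (i in seq_along(ids)) {
    ok <- line1$fdr[i] < 0.05 && line2$fdr[i] < 0.05 &&
      sign(line1$log2_ratio[i]) == sign(line2$log2_ratio[i]) &&
      max(abs(line1$log2_ratio[i]), abs(line2$log2_ratio[i])) >= 0.5 &&
      ann$peptides[i] >= 2
    if (ok) brute <- c(brute, ids[i])
  }
  expect_setequal(sel$protein_id, brute)
  expect_setequal(sel$protein_id, c("p1", "p5"))   # engineered outcome
  # sign disagreement excluded even when both significant and large
  expect_false("p2" %in% sel$protein_id)
  # boundary |log2| = 0.5 is included
  b1 <- tbl("q1", 0.5, 0.01); b2 <- tbl("q1", 0.2, 0.01)
  expect_equal(nrow(select_regulated(b1, b2,
    tibble::tibble(protein_id = "q1", peptides = 2L))), 1)
  # empty input and mismatched ids
  expect_equal(nrow(select_regulated(line1[0, ], line2[0, ], ann)), 0)
  expect_error(select_regulated(line1, line2[-1, ], ann), "different proteins")
})

test_that("fold conversions reproduce the published per-protein claims", {
  psac <- fold_conversions(c(-1.35, -1.96))
  expect_equal(psac$percent_floor, c(39, 25))
  expect_equal(psac$percent_of_reference, c(39.2292, 25.7028), tolerance = 1e-4)
  ape1 <- fold_conversions(c(1.16, 1.58))
  expect_equal(ape1$fold_round, c(2, 3))
  expect_equal(fold_conversions(0)$fold, 1)
  expect_equal(fold_conversions(0)$percent_of_reference, 100)
  # exact inverse of the log2 ratio
  x <- c(-2.3, -0.5, 0, 0.7, 3.1)
  expect_equal(log2(fold_conversions(x)$fold), x, tolerance = 1e-12)
  expect_error(fold_conversions(NA), "finite")
})

test_that("degenerate grid reduces the statistic to the mean difference", {
  set.seed(7)
  vals <- 2^matrix(rnorm(300, 20, 2), nrow = 30)
  pq <- toy_protein_quant(vals, rep(c("A", "B"), each = 5))
  pre <- preprocess_abundances(pq, groups = c("A", "B"))
  res <- rots_test(pre, c("A", "B"), B = 20, n_perm = 50,
                   param_grid = tibble::tibble(a1 = 1, a2 = 0), seed = 1)
  m <- log2(as.matrix(pre$abundance[-1]))
  diffs <- abs(rowMeans(m[, 1:5]) - rowMeans(m[, 6:10]))
  expect_equal(order(res$table$d, decreasing = TRUE),
               order(diffs[match(res$table$protein_id, pre$abundance$protein_id)],
                     decreasing = TRUE))
  expect_equal(res$a1, 1)
  expect_equal(res$a2, 0)
})

test_that("rots_test is invariant to row and sample order, FDR is monotone", {
  sc <- study_scenario()
  sc$proteomics$n_prot <- 80
  pq <- gen_abundance_matrix(sc, seed = 11)
  pre <- preprocess_abundances(pq, groups = c("cpftsy.1-25.7", "WT"))
  run <- function(p) rots_test(p, c("cpftsy.1-25.7", "WT"), B = 40,
                               n_perm = 60, seed = 5)
  res1 <- run(pre)
  shuf <- pre
  perm <- sample.int(nrow(shuf$abundance))
  shuf$abundance <- shuf$abundance[perm, ]
  cols <- sample(shuf$samples$sample_id)
  shuf$samples <- shuf$samples[match(cols, shuf$samples$sample_id), ]
  res2 <- run(shuf)
  expect_equal(res1$table, res2$table)
  expect_equal(c(res1$a1, res1$a2, res1$k), c(res2$a1, res2$a2, res2$k))
  # FDR is non-decreasing going down the ranking
  ord <- order(res1$table$d, decreasing = TRUE)
  expect_true(all(diff(res1$table$fdr[ord]) >= -1e-12))
  expect_true(all(res1$table$fdr >= 0 & res1$table$fdr <= 1))
  # guard rails
  expect_error(rots_test(pre, c("cpftsy.1-25.7", "WT"), B = 1), "at least 2")
  expect_error(rots_test(pre, c("cpftsy.1-25.7", "WT"),
                         param_grid = tibble::tibble()[0, ]), "empty")
})
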