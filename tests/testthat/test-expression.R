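empty_sig <- dplyr::tibble(gene = character(), programme = character(),
                           lfc_cluster1 = numeric(), lfc_cluster2 = numeric(),
                           base_mean = numeric())

test_that("QC boundaries are strict and planted failures are exactly removed", {
  # constructed matrix: 10 cells x 400 genes, full detection except planted
  counts <- matrix(5L, nrow = 400, ncol = 10,
                   dimnames = list(sprintf("g%03d", 1:400),
                                   sprintf("c%02d", 1:10)))
  counts[301:400, 1] <- 0L   # cell 1: exactly 300 genes detected -> excluded
  counts[300:400, 2] <- 0L   # cell 2: 299 genes -> excluded
  counts[100:400, 3] <- 0L   # cell 3: 99 genes -> excluded
  mito <- stats::setNames(rep(0.05, 10), colnames(counts))
  mito["c04"] <- 0.10        # exactly 10% -> excluded
  mito["c05"] <- 0.0999      # just under -> kept
  qc <- qc_filter(counts, mito_fraction = mito)
  expect_equal(qc$report$passed,
               c(FALSE, FALSE, FALSE, FALSE, rep(TRUE, 6)))
  expect_equal(colnames(qc$counts), sprintf("c%02d", 5:10))
  # idempotence
  qc2 <- qc_filter(qc$counts, mito_fraction = mito[colnames(qc$counts)])
  expect_equal(colnames(qc2$counts), colnames(qc$counts))
})

test_that("QC removes exactly the planted failures of the generator", {
  cfg <- expression_config(cells_per_cluster = c(60, 0, 60), n_genes = 1500,
                           signature = empty_sig, qc_fail_rate = 1 / 6,
                           mito_shape1 = 2, mito_shape2 = 200)
  sim <- simulate_expression(cfg, seed = 17)
  qc <- qc_filter(sim$counts,
                  stats::setNames(sim$cells$mito_fraction, sim$cells$cell_id))
  expect_equal(sum(!qc$report$passed), 20L)
  expect_setequal(qc$report$cell_id[!qc$report$passed],
                  sim$cells$cell_id[sim$cells$planted_qc_fail != "none"])
})

test_that("normalisation scales to a common library size then log2(1 + x)", {
  counts <- matrix(c(2L, 19998L, 10L, 90L), nrow = 2,
                   dimnames = list(c("gA", "gB"), c("c1", "c2")))
  norm <- normalize_log(counts)
  expect_equal(norm["gA", "c1"], log2(1 + 2 / 20000 * 1e4))  # = 1
  expect_equal(norm["gA", "c1"], 1)
  # all-equal matrix stays all-equal
  eq <- matrix(4L, 5, 3, dimnames = list(letters[1:5], LETTERS[1:3]))
  expect_equal(length(unique(as.vector(normalize_log(eq)))), 1L)
  # independent two-line oracle on a random matrix
  set.seed(5)
  m <- matrix(rpois(60, 8), 10, 6,
              dimnames = list(letters[1:10], LETTERS[1:6]))
  oracle <- log2(1 + t(t(m) / colSums(m)) * 1e4)
  expect_equal(unname(normalize_log(m)), unname(oracle), ignore_attr = TRUE)
  # all-zero cell dropped with a warning
  z <- m; z[, 2] <- 0L
  expect_warning(nz <- normalize_log(z), "all-zero")
  expect_equal(ncol(nz), 5L)
})

test_that("clustering validates k, is deterministic, and recovers planted structure", {
  sig <- dplyr::tibble(gene = sprintf("s%02d", 1:30), programme = "TR1",
                       lfc_cluster1 = rep(c(2.5, -2), 15),
                       lfc_cluster2 = rep(c(-2, 2.5), 15), base_mean = 20)
  cfg <- expression_config(cells_per_cluster = c(70, 60, 70), n_genes = 500,
                           signature = sig, qc_fail_rate = 0)
  sim <- simulate_expression(cfg, seed = 18)
  norm <- normalize_log(sim$counts)
  expect_error(cluster_cells(norm, k = 1), class = "tr1kit_parameter_error")
  l1 <- cluster_cells(norm, k = 3, seed = 4)
  l2 <- cluster_cells(norm, k = 3, seed = 4)
  expect_identical(l1$cluster, l2$cluster)
  expect_gt(adjusted_rand(l1$cluster, sim$cells$true_cluster), 0.8)
  # canonical labels: cluster 0 is the largest
  expect_equal(which.max(tabulate(l1$cluster + 1L)) - 1L, 0L)
})

test_that("differential expression of a group against itself is null", {
  cfg <- expression_config(cells_per_cluster = c(20, 0, 0), n_genes = 80,
                           signature = empty_sig, qc_fail_rate = 0)
  sim <- simulate_expression(cfg, seed = 19)
  ids <- sim$cells$cell_id
  de <- de_negative_binomial(sim$counts, ids, ids)
  expect_true(all(abs(de$log_fc) < 1e-8))
  expect_false(any(de$significant))
})

test_that("swapping groups negates log fold-changes and keeps p-values", {
  cfg <- expression_config(cells_per_cluster = c(25, 0, 25), n_genes = 120,
                           signature = dplyr::tibble(
                             gene = "hot", programme = "TR1", lfc_cluster1 = 0,
                             lfc_cluster2 = 3, base_mean = 15),
                           qc_fail_rate = 0)
  sim <- simulate_expression(cfg, seed = 20)
  a <- sim$cells$cell_id[sim$cells$true_cluster == 2]
  b <- sim$cells$cell_id[sim$cells$true_cluster == 0]
  de_ab <- de_negative_binomial(sim$counts, a, b)
  de_ba <- de_negative_binomial(sim$counts, b, a)
  expect_equal(de_ab$log_fc, -de_ba$log_fc, tolerance = 1e-8)
  expect_equal(de_ab$p_value, de_ba$p_value, tolerance = 1e-8)
  expect_true(de_ab$significant[de_ab$gene == "hot"])
  expect_gt(de_ab$log_fc[de_ab$gene == "hot"], 2)
})

test_that("the NB fit agrees with an independent glm.nb-based oracle", {
  cfg <- expression_config(cells_per_cluster = c(40, 0, 40), n_genes = 30,
                           signature = dplyr::tibble(
                             gene = sprintf("sig%d", 1:3), programme = "TR1",
                             lfc_cluster1 = 0, lfc_cluster2 = c(1, 2, 3),
                             base_mean = 10),
                           qc_fail_rate = 0)
  sim <- simulate_expression(cfg, seed = 23)
  a <- sim$cells$cell_id[sim$cells$true_cluster == 2]
  b <- sim$cells$cell_id[sim$cells$true_cluster == 0]
  de <- de_negative_binomial(sim$counts, a, b)

  lib <- colSums(sim$counts)
  s <- lib / mean(lib[c(a, b)])
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))), levels = c("b", "a"))
  off <- log(s[c(a, b)])
  for (g in c("sig1", "sig2", "sig3")) {
    y <- sim$counts[g, c(a, b)]
    fit <- MASS::glm.nb(y ~ grp + offset(off))
    null <- stats::glm(y ~ offset(off),
                       family = MASS::negative.binomial(fit$theta))
    p_oracle <- stats::pchisq(null$deviance - fit$deviance, df = 1,
                              lower.tail = FALSE)
    mine <- de[de$gene == g, ]
    expect_equal(log(mine$p_value + 1e-300), log(p_oracle + 1e-300),
                 tolerance = 0.05)
    expect_equal(mine$log_fc, unname(coef(fit)["grpa"]) / log(2),
                 tolerance = 0.05)
  }
})

test_that("all-zero genes are degenerate with p = 1 and log_fc = 0", {
  counts <- matrix(rpois(300, 4), nrow = 10,
                   dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:30)))
  counts[4, ] <- 0L
  de <- de_negative_binomial(counts, sprintf("c%d", 1:15), sprintf("c%d", 16:30))
  expect_true(de$degenerate[4])
  expect_equal(de$p_value[4], 1)
  expect_equal(de$log_fc[4], 0)
  expect_false(de$significant[4])
})

test_that("BH adjustment is monotone and never below the raw p-value", {
  counts <- matrix(rnbinom(3000, mu = 6, size = 2), nrow = 100,
                   dimnames = list(sprintf("g%d", 1:100), sprintf("c%d", 1:30)))
  de <- de_negative_binomial(counts, sprintf("c%d", 1:15), sprintf("c%d", 16:30))
  expect_true(all(de$p_adj >= de$p_value - 1e-12))
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-12))
  expect_error(de_negative_binomial(counts, sprintf("c%d", 1:2),
                                    sprintf("c%d", 16:30)),
               class = "tr1kit_input_error")
})

test_that("concordance is 1 on identical inputs and 0 under sign flip", {
  de <- structure(dplyr::tibble(gene = sprintf("g%d", 1:20),
                                log_fc = seq(-3, 3, length.out = 20),
                                significant = TRUE),
                  class = c("tr1_de", class(dplyr::tibble())))
  res <- logfc_concordance(de, de)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$concordant_fraction, 1)
  flipped <- de
  flipped$log_fc <- -flipped$log_fc
  res2 <- logfc_concordance(de, flipped)
  expect_equal(res2$pearson_r, -1)
  expect_equal(res2$concordant_fraction, 0)
  expect_error(logfc_concordance(de[1:2, ], de[1:2, ]),
               class = "tr1kit_input_error")
})

test_that("signatures equal to cluster up-gene sets give 100% overlap", {
  mk_de <- function(up_genes, all_genes) {
    structure(dplyr::tibble(
      gene = all_genes,
      log_fc = ifelse(all_genes %in% up_genes, 3, 0),
      significant = all_genes %in% up_genes
    ), class = c("tr1_de", class(dplyr::tibble())))
  }
  genes <- sprintf("g%02d", 1:40)
  up1 <- genes[1:12]; up2 <- genes[21:35]
  de_list <- list("1" = mk_de(up1, genes), "2" = mk_de(up2, genes))
  ov <- signature_cluster_overlap(de_list, list(TFH = up1, TR1 = up2))
  pct <- ov$percentages
  expect_equal(pct$percent[pct$signature == "TFH" & pct$cluster == "1"], 100)
  expect_equal(pct$percent[pct$signature == "TR1" & pct$cluster == "2"], 100)
  expect_equal(pct$percent[pct$signature == "TFH" & pct$cluster == "2"], 0)
  expect_lt(ov$test$p_value, 0.01)
  expect_error(signature_cluster_overlap(de_list, list(TFH = "absent")),
               class = "tr1kit_input_error")
})
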