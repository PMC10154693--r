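#' Quality-control filter for single-cell count matrices
#'
#' Keeps cells expressing more than `min_genes` genes and with mitochondrial
#' content strictly below `max_mito` (both boundaries exclusive: a cell with
#' exactly 300 detected genes or exactly 10% mitochondrial reads is removed).
#'
#' @param counts Non-negative integer matrix, genes x cells, with dimnames.
#' @param mito_fraction Named per-cell mitochondrial fraction in `[0, 1]`;
#'   alternatively supply `mito_genes`.
#' @param mito_genes Character vector of mitochondrial gene names used to
#'   compute the fraction from `counts` when `mito_fraction` is missing.
#' @param min_genes,max_mito QC thresholds (defaults 300 genes, 10%).
#'
#' @return List of class `qc_result`: `report` (tibble `cell_id`,
#'   `genes_detected`, `mito_fraction`, `passed`) and `counts` (the matrix
#'   restricted to passing cells).
#' @export
qc_filter <- function(counts, mito_fraction = NULL, mito_genes = NULL,
                      min_genes = 300L, max_mito = 0.10) {
  assert_that(is.matrix(counts) || inherits(counts, "Matrix"),
              "counts must be a matrix", class = "tr1kit_input_error")
  assert_that(all(counts >= 0), "counts must be non-negative",
              class = "tr1kit_input_error")
  cells <- colnames(counts) %||% as.character(seq_len(ncol(counts)))

  if (is.null(mito_fraction)) {
    assert_that(!is.null(mito_genes),
                "supply mito_fraction or mito_genes for the QC filter",
                class = "tr1kit_config_error")
    mt <- intersect(mito_genes, rownames(counts))
    tot <- Matrix::colSums(counts)
    mito_fraction <- ifelse(tot > 0, Matrix::colSums(counts[mt, , drop = FALSE]) / tot, 0)
    names(mito_fraction) <- cells
  }
  assert_that(all(cells %in% names(mito_fraction)),
              "mito_fraction must cover every cell", class = "tr1kit_config_error")
  mito_fraction <- mito_fraction[cells]
  assert_that(all(mito_fraction >= 0 & mito_fraction <= 1),
              "mito_fraction must lie in [0, 1]", class = "tr1kit_input_error")

  report <- tibble(
    cell_id = cells,
    genes_detected = as.integer(Matrix::colSums(counts > 0)),
    mito_fraction = unname(mito_fraction)
  ) |>
    mutate(passed = .data$genes_detected > min_genes & .data$mito_fraction < max_mito)

  structure(
    list(report = report, counts = counts[, report$passed, drop = FALSE]),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", sum(x$report$passed), "of", nrow(x$report), "cells pass QC\n")
  invisible(x)
}

#' Library-size normalisation and log transform
#'
#' Scales each cell to a common library size then applies `log2(1 + x)`.
#' All-zero cells are dropped with a warning. The per-cell scale factors are
#' kept in the `"size_factors"` attribute so the transform is invertible.
#'
#' @param counts Genes x cells count matrix.
#' @param scale_factor Common library size (default 10,000).
#' @return Normalised matrix with attribute `size_factors` (original library
#'   sizes of the retained cells).
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    warn(sprintf("%d all-zero cell(s) excluded from normalisation", sum(lib == 0)))
    counts <- counts[, lib > 0, drop = FALSE]
    lib <- lib[lib > 0]
  }
  assert_that(length(lib) > 0, "no cells with non-zero counts",
              class = "tr1kit_input_error")
  out <- log2(1 + sweep(as.matrix(counts), 2L, lib / scale_factor, "/"))
  attr(out, "size_factors") <- lib
  out
}

#' Cluster cells by PCA and k-means
#'
#' Principal components of the normalised matrix (cells as observations) feed
#' a k-means clustering with multiple restarts. Labels are relabelled
#' canonically: cluster 0 is the largest, then by decreasing size. PCA is used
#' as the quantitative embedding; tSNE is display-only elsewhere.
#'
#' @param normalized Normalised genes x cells matrix (from [normalize_log()]).
#' @param k Number of clusters (>= 2, default 3).
#' @param n_pcs Number of principal components (capped at the data rank).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return Tibble of class `cluster_labels`: `cell_id`, `cluster` (0-based);
#'   attributes `k`, `n_pcs`, `seed`.
#' @export
cluster_cells <- function(normalized, k = 3L, n_pcs = 20L, seed = 1L, nstart = 25L) {
  assert_that(k >= 2, "k must be at least 2")
  assert_that(ncol(normalized) >= k, "need at least k cells")
  emb <- stats::prcomp(t(normalized), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(emb$x))
  km <- with_seed(seed, stats::kmeans(emb$x[, seq_len(n_pcs), drop = FALSE],
                                      centers = k, nstart = nstart))
  # canonical labels: 0 = largest cluster
  order_by_size <- order(-tabulate(km$cluster, nbins = k), seq_len(k))
  relabel <- integer(k)
  relabel[order_by_size] <- seq_len(k) - 1L
  out <- tibble(
    cell_id = colnames(normalized) %||% as.character(seq_len(ncol(normalized))),
    cluster = relabel[km$cluster]
  )
  attr(out, "k") <- k
  attr(out, "n_pcs") <- n_pcs
  attr(out, "seed") <- seed
  class(out) <- c("cluster_labels", class(out))
  out
}

# Newton refinement of a group mean m under NB(mu = s * m, theta).
nb_group_mean <- function(y, s, theta, iters = 4L) {
  sy <- sum(y)
  if (sy == 0) return(0)
  m <- sy / sum(s)
  for (it in seq_len(iters)) {
    denom <- s * m + theta
    f <- sy / m - sum((y + theta) * s / denom)
    fp <- -sy / m^2 + sum((y + theta) * s^2 / denom^2)
    if (!is.finite(f) || !is.finite(fp) || fp == 0) break
    step <- f / fp
    m_new <- m - step
    if (!is.finite(m_new) || m_new <= 0) m_new <- m / 2
    if (abs(m_new - m) < 1e-10 * (m + 1e-10)) { m <- m_new; break }
    m <- m_new
  }
  m
}

nb_loglik <- function(y, s, m, theta) {
  sum(stats::dnbinom(y, size = theta, mu = s * m, log = TRUE))
}

#' Negative-binomial differential expression between two cell groups
#'
#' Per-gene negative-binomial model with a group indicator and a library-size
#' offset: dispersion is estimated by maximum likelihood
#' ([MASS::theta.ml()]; method-of-moments fallback), group means by Newton
#' profile iterations, and the p-value by the likelihood-ratio test (1 df).
#' P-values are Benjamini-Hochberg adjusted and a gene is called significant
#' when `|log2FC| >= lfc_threshold` and adjusted p `<= alpha` (defaults:
#' fold-change at least 4 and FDR at most 1%). The fold change is
#' `log2((mean_a + pc) / (mean_b + pc))` on library-size-normalised means with
#' pseudo-count `pc = 1 /` total cells; group A is always the numerator.
#'
#' @param counts Raw genes x cells count matrix (not normalised).
#' @param cells_a,cells_b Column names (or indices) of the two groups; both
#'   must have at least 3 cells.
#' @param lfc_threshold,alpha Significance rule (defaults 2 and 0.01).
#' @return Tibble of class `tr1_de`: `gene`, `mean_a`, `mean_b`, `log_fc`,
#'   `p_value`, `p_adj`, `significant`, `degenerate`.
#' @export
de_negative_binomial <- function(counts, cells_a, cells_b,
                                 lfc_threshold = 2, alpha = 0.01) {
  counts <- as.matrix(counts)
  ia <- if (is.character(cells_a)) match(cells_a, colnames(counts)) else as.integer(cells_a)
  ib <- if (is.character(cells_b)) match(cells_b, colnames(counts)) else as.integer(cells_b)
  assert_that(!anyNA(ia) && !anyNA(ib), "unknown cell ids",
              class = "tr1kit_input_error")
  assert_that(length(ia) >= 3 && length(ib) >= 3,
              "both groups need at least 3 cells", class = "tr1kit_input_error")

  lib <- colSums(counts)
  s_all <- lib / mean(lib[c(ia, ib)])
  sa <- s_all[ia]; sb <- s_all[ib]
  n_tot <- length(ia) + length(ib)
  pc <- 1 / n_tot

  one_gene <- function(y) {
    ya <- y[ia]; yb <- y[ib]
    if (sum(ya) + sum(yb) == 0) {
      return(c(mean_a = 0, mean_b = 0, log_fc = 0, p_value = 1, degenerate = 1))
    }
    yab <- c(ya, yb); sab <- c(sa, sb)
    # Poisson profile means start the fit
    m_a <- sum(ya) / sum(sa); m_b <- sum(yb) / sum(sb)
    mu_full <- c(sa * m_a, sb * m_b)
    theta <- tryCatch(
      suppressWarnings(as.numeric(MASS::theta.ml(yab, pmax(mu_full, 1e-8), limit = 25))),
      error = function(e) {
        mu <- pmax(mu_full, 1e-8)
        z <- sum((yab - mu)^2 - mu)
        if (z <= 0) 1e8 else sum(mu^2) / z
      }
    )
    if (!is.finite(theta) || theta <= 0) theta <- 1e8
    theta <- min(theta, 1e8)
    m_a <- nb_group_mean(ya, sa, theta)
    m_b <- nb_group_mean(yb, sb, theta)
    m_0 <- nb_group_mean(yab, sab, theta)
    lrt <- 2 * (nb_loglik(ya, sa, m_a, theta) + nb_loglik(yb, sb, m_b, theta) -
                  nb_loglik(yab, sab, m_0, theta))
    c(mean_a = m_a, mean_b = m_b,
      log_fc = log2((m_a + pc) / (m_b + pc)),
      p_value = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
      degenerate = 0)
  }

  stats_mat <- unname(t(apply(counts, 1L, one_gene)))
  out <- tibble(
    gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_a = stats_mat[, 1L], mean_b = stats_mat[, 2L],
    log_fc = stats_mat[, 3L], p_value = stats_mat[, 4L],
    degenerate = stats_mat[, 5L] == 1
  ) |>
    mutate(
      p_adj = stats::p.adjust(.data$p_value, method = "BH"),
      significant = !.data$degenerate & abs(.data$log_fc) >= lfc_threshold &
        .data$p_adj <= alpha
    ) |>
    select("gene", "mean_a", "mean_b", "log_fc", "p_value", "p_adj",
           "significant", "degenerate")
  attr(out, "n_a") <- length(ia)
  attr(out, "n_b") <- length(ib)
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("tr1_de", class(out))
  out
}

#' Concordance of log fold-changes between two comparisons
#'
#' Pearson correlation of paired per-gene log2 fold-changes, plus the fraction
#' of genes changing in the same direction with similar magnitude
#' (`|difference| <= band`). By default only genes significant in at least one
#' of the two comparisons enter.
#'
#' @param de_a,de_b `tr1_de` tibbles sharing genes.
#' @param band Magnitude band for concordance (default 1 log2 unit).
#' @param only_significant Restrict to genes significant in either comparison.
#' @return One-row tibble of class `tr1_concordance`: `pearson_r`, `p_value`,
#'   `concordant_fraction`, `n_genes`, `band`.
#' @export
logfc_concordance <- function(de_a, de_b, band = 1.0, only_significant = TRUE) {
  paired <- inner_join(
    as_tibble(de_a) |> select("gene", lfc_a = "log_fc", sig_a = "significant"),
    as_tibble(de_b) |> select("gene", lfc_b = "log_fc", sig_b = "significant"),
    by = "gene"
  )
  if (only_significant) paired <- filter(paired, .data$sig_a | .data$sig_b)
  assert_that(nrow(paired) >= 3, "fewer than 3 shared genes",
              class = "tr1kit_input_error")
  ct <- stats::cor.test(paired$lfc_a, paired$lfc_b, method = "pearson")
  out <- tibble(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    concordant_fraction = mean(sign(paired$lfc_a) == sign(paired$lfc_b) &
                                 abs(paired$lfc_a - paired$lfc_b) <= band),
    n_genes = nrow(paired),
    band = band
  )
  class(out) <- c("tr1_concordance", class(out))
  out
}

#' Overlap of lineage signatures with cluster-specific upregulation
#'
#' For each supplied signature (e.g. TFH- and TR1-specific gene sets), the
#' percentage of its genes significantly upregulated in each tetramer-positive
#' cluster versus the conventional pool, with a chi-square test of signature
#' membership against the cluster in which a gene is upregulated.
#'
#' @param de_by_cluster Named list of `tr1_de` results, one per cluster (e.g.
#'   `list("1" = de_cluster1, "2" = de_cluster2)`), each computed against the
#'   conventional cells.
#' @param signatures Named list of character gene sets (e.g.
#'   `list(TFH = ..., TR1 = ...)`).
#' @return List of class `signature_overlap`: `percentages` tibble
#'   (`signature`, `cluster`, `n_signature`, `n_up`, `percent`) and `test`
#'   (one-row tibble from the chi-square).
#' @export
signature_cluster_overlap <- function(de_by_cluster, signatures) {
  assert_that(length(signatures) > 0 && !is.null(names(signatures)),
              "signatures must be a named list", class = "tr1kit_input_error")
  assert_that(length(de_by_cluster) > 0 && !is.null(names(de_by_cluster)),
              "de_by_cluster must be a named list", class = "tr1kit_input_error")

  up_sets <- purrr::map(de_by_cluster, function(de) {
    de$gene[de$significant & de$log_fc > 0]
  })
  tested <- unique(unlist(purrr::map(de_by_cluster, "gene")))

  percentages <- purrr::imap(signatures, function(genes, sig_name) {
    present <- intersect(genes, tested)
    assert_that(length(present) > 0,
                paste0("signature '", sig_name, "' shares no genes with the DE results"),
                class = "tr1kit_input_error")
    purrr::imap(up_sets, function(up, cl) {
      tibble(signature = sig_name, cluster = cl,
             n_signature = length(present),
             n_up = length(intersect(present, up)),
             percent = 100 * length(intersect(present, up)) / length(present))
    }) |> bind_rows()
  }) |> bind_rows()

  test <- NULL
  if (length(signatures) == 2 && length(up_sets) == 2) {
    tab <- matrix(percentages$n_up, nrow = 2, byrow = TRUE,
                  dimnames = list(names(signatures), names(up_sets)))
    expected <- outer(rowSums(tab), colSums(tab)) / max(sum(tab), 1)
    test <- if (sum(tab) == 0) {
      tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
             method = "none")
    } else if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      tibble(statistic = NA_real_, df = NA_integer_, p_value = ft$p.value,
             method = "fisher")
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p_value = ct$p.value, method = "pearson")
    }
  }

  structure(list(percentages = percentages, test = test),
            class = "signature_overlap")
}

#' @export
print.signature_overlap <- function(x, ...) {
  cat("<signature_overlap>\n")
  print(x$percentages)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}
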