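#' Default cluster-specific expression signature
#'
#' Per-gene log2 fold-changes (relative to the conventional-T-cell baseline,
#' cluster 0) for the genes that characterise the three expected populations:
#' naive/conventional markers (down in both tetramer-positive clusters),
#' TFH-associated genes (strongly up in cluster 1) and TR1-associated genes
#' (strongly up in cluster 2). Magnitudes follow the differential expression
#' reported for tetramer-positive versus Tconv cells in this system; the
#' cross-cluster attenuation factor makes each programme specific to its
#' cluster at the |log2FC| >= 2 significance threshold.
#'
#' @param attenuation Fraction of a programme's log2FC applied in the other
#'   tetramer-positive cluster.
#' @return Tibble with columns `gene`, `programme`, `lfc_cluster1`,
#'   `lfc_cluster2` and `base_mean`.
#' @export
default_expression_signature <- function(attenuation = 0.4) {
  up <- c(
    Pdcd1 = 3.420, Nt5e = 3.141, Cxcr5 = 2.989, Il10 = 2.865, Nfil3 = 2.750,
    Ifng = 2.704, Il21 = 2.703, Tigit = 2.636, Lag3 = 2.507, Ascl2 = 2.445,
    Tox2 = 2.181, Bcl6 = 1.811, Maf = 1.764, Rbpj = 1.760, Cxcr3 = 1.697,
    Il4 = 1.686, Ctla4 = 1.665, Icos = 1.210, Cd226 = 1.141
  )
  down <- c(Il7r = 1.415, Ccr7 = 1.549, Lef1 = 1.607, Klf2 = 2.667,
            Myc = 3.455, Sell = 4.367)
  tfh <- c("Cxcr5", "Il4", "Bcl6", "Ascl2", "Tox2", "Icos")

  bind_rows(
    tibble(gene = names(up), magnitude = unname(up),
           programme = ifelse(names(up) %in% tfh, "TFH", "TR1")),
    tibble(gene = names(down), magnitude = -unname(down), programme = "naive")
  ) |>
    mutate(
      lfc_cluster1 = case_when(
        .data$programme == "TFH" ~ .data$magnitude,
        .data$programme == "TR1" ~ attenuation * .data$magnitude,
        TRUE ~ .data$magnitude
      ),
      lfc_cluster2 = case_when(
        .data$programme == "TR1" ~ .data$magnitude,
        .data$programme == "TFH" ~ attenuation * .data$magnitude,
        TRUE ~ .data$magnitude
      ),
      base_mean = 20
    ) |>
    select("gene", "programme", "lfc_cluster1", "lfc_cluster2", "base_mean")
}

#' Configuration for the single-cell expression simulator
#'
#' @param cells_per_cluster Integer vector of length 3: cells in clusters
#'   0 (Tconv-like), 1 (TFH-like) and 2 (TR1-like). Defaults scale to the
#'   ~530 quality-passing cells of the emulated experiment.
#' @param n_genes Total genes (must cover the signature genes).
#' @param signature Tibble as produced by [default_expression_signature()];
#'   genes absent from it get log2FC 0 in all clusters.
#' @param theta Negative-binomial dispersion (variance = mu + mu^2/theta),
#'   shared across genes by default.
#' @param base_mean_shape,base_mean_rate Gamma parameters for non-signature
#'   baseline means.
#' @param libsize_sdlog Log-normal sd of per-cell size factors.
#' @param mito_shape1,mito_shape2 Beta parameters of the per-cell
#'   mitochondrial fraction for healthy cells (mean ~4%).
#' @param qc_fail_rate Fraction of cells planted as QC failures (half by
#'   mitochondrial content >= 10%, half by collapsed library depth).
#' @return List of class `expression_config`.
#' @export
expression_config <- function(
    cells_per_cluster = c(230, 90, 210),
    n_genes = 2000,
    signature = default_expression_signature(),
    theta = 2,
    base_mean_shape = 0.6, base_mean_rate = 0.3,
    libsize_sdlog = 0.3,
    mito_shape1 = 2, mito_shape2 = 48,
    qc_fail_rate = 0.05) {
  assert_that(theta > 0, "negative-binomial dispersion theta must be positive")
  assert_that(length(cells_per_cluster) == 3 && all(cells_per_cluster >= 0),
              "cells_per_cluster must be 3 non-negative counts")
  assert_that(n_genes >= nrow(signature),
              "n_genes must cover the signature genes")
  assert_that(qc_fail_rate >= 0 && qc_fail_rate <= 1, "qc_fail_rate in [0,1]")
  structure(
    list(cells_per_cluster = cells_per_cluster, n_genes = n_genes,
         signature = signature, theta = theta,
         base_mean_shape = base_mean_shape, base_mean_rate = base_mean_rate,
         libsize_sdlog = libsize_sdlog,
         mito_shape1 = mito_shape1, mito_shape2 = mito_shape2,
         qc_fail_rate = qc_fail_rate),
    class = "expression_config"
  )
}

#' Simulate a gene-by-cell count matrix with three-population structure
#'
#' Counts are negative binomial with cluster-specific means
#' `mu = size_factor * base_mean * 2^log2FC(cluster)` and dispersion `theta`
#' (variance `mu + mu^2/theta`). Mitochondrial fractions are Beta-distributed
#' and independent of cluster; a configurable fraction of cells is planted as
#' quality-control failures.
#'
#' @param config An [expression_config()].
#' @param seed Integer seed.
#' @param cells Optional tibble with columns `cell_id` and `true_cluster`
#'   (0/1/2) to simulate expression for an existing cell roster (e.g. from
#'   [simulate_repertoire()]); overrides `cells_per_cluster`.
#'
#' @return List of class `expression_truth`: integer matrix `counts`
#'   (genes x cells, dimnames set), tibble `cells` (`cell_id`,
#'   `true_cluster`, `mito_fraction`, `size_factor`, `planted_qc_fail`) and
#'   tibble `genes` (`gene`, `base_mean`, `theta`, `lfc_cluster1`,
#'   `lfc_cluster2`).
#'
#' @examples
#' sim <- simulate_expression(expression_config(cells_per_cluster = c(30, 10, 20),
#'                                              n_genes = 200), seed = 1)
#' dim(sim$counts)
#' @export
simulate_expression <- function(config = expression_config(), seed = 1L, cells = NULL) {
  if (!inherits(config, "expression_config")) config <- do.call(expression_config, config)

  with_seed(seed, {
    if (is.null(cells)) {
      n_cells <- sum(config$cells_per_cluster)
      cells <- tibble(
        cell_id = sprintf("cell%04d", seq_len(n_cells)),
        true_cluster = rep(0:2, times = config$cells_per_cluster)
      )
    } else {
      cells <- as_tibble(cells) |> select("cell_id", "true_cluster")
    }
    n_cells <- nrow(cells)
    assert_that(n_cells > 0, "no cells to simulate")

    sig <- config$signature
    n_extra <- config$n_genes - nrow(sig)
    genes <- bind_rows(
      sig |> select("gene", "base_mean", "lfc_cluster1", "lfc_cluster2"),
      tibble(
        gene = sprintf("gene%05d", seq_len(n_extra)),
        base_mean = stats::rgamma(n_extra, shape = config$base_mean_shape,
                                  rate = config$base_mean_rate),
        lfc_cluster1 = 0, lfc_cluster2 = 0
      )
    ) |>
      mutate(theta = config$theta)

    cells <- cells |>
      mutate(
        size_factor = stats::rlnorm(n_cells, meanlog = 0, sdlog = config$libsize_sdlog),
        mito_fraction = stats::rbeta(n_cells, config$mito_shape1, config$mito_shape2),
        planted_qc_fail = "none"
      )
    n_fail <- round(config$qc_fail_rate * n_cells)
    if (n_fail > 0) {
      idx <- sample.int(n_cells, n_fail)
      half <- idx[seq_len(ceiling(n_fail / 2))]
      rest <- setdiff(idx, half)
      cells$mito_fraction[half] <- 0.10 + 0.40 * stats::rbeta(length(half), 1, 3)
      cells$planted_qc_fail[half] <- "mito"
      if (length(rest) > 0) {
        cells$size_factor[rest] <- cells$size_factor[rest] * 0.005
        cells$planted_qc_fail[rest] <- "depth"
      }
    }

    lfc <- cbind(0, genes$lfc_cluster1, genes$lfc_cluster2)  # genes x 3
    mu <- (genes$base_mean * 2^lfc[, cells$true_cluster + 1L]) *
      rep(cells$size_factor, each = nrow(genes))
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = rep(genes$theta, n_cells)),
      nrow = nrow(genes), ncol = n_cells,
      dimnames = list(genes$gene, cells$cell_id)
    )

    structure(list(counts = counts, cells = cells, genes = genes),
              class = "expression_truth")
  })
}

#' @export
print.expression_truth <- function(x, ...) {
  cat("<expression_truth> ", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  print(count(x$cells, .data$true_cluster))
  invisible(x)
}
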