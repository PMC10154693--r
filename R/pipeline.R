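#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: input paths (or the
#' synthetic generators standing in for them), alignment and clustering
#' parameters, and the significance rule for differential expression
#' (defaults: |log2FC| >= 2, i.e. fold-change at least 4, and FDR <= 0.01).
#'
#' @param out_dir Output directory for artifacts and the manifest.
#' @param seed Global seed; every stage derives its randomness from it.
#' @param simulate Generate synthetic inputs with the bundled generators
#'   (`TRUE`, default) or read them from `paths`.
#' @param paths Named list of input paths when `simulate = FALSE`:
#'   `germline_fasta`, `contigs_fasta`, `metadata_tsv` and (for the
#'   expression stage) `counts_mtx`, `genes_tsv`, `barcodes_tsv`.
#' @param stages Named logical list enabling `clonotype`, `repertoire`,
#'   `expression`, `lineage`.
#' @param repertoire,expression Generator configurations
#'   ([repertoire_config()], [expression_config()]) used when simulating.
#' @param germline_counts Segments generated per (chain, class) when
#'   simulating, as `c(n_v_alpha, n_j_alpha, n_v_beta, n_j_beta)`.
#' @param spacer_len,scoring,min_score Recombinome and alignment parameters.
#' @param k,n_pcs Clustering parameters.
#' @param lfc_threshold,de_alpha Differential-expression significance rule.
#' @param band Log2 band for fold-change concordance.
#' @param enrichment_background Background for positional residue enrichment.
#' @param min_genes,max_mito QC thresholds.
#' @param signatures Named list of signature gene sets for the overlap test;
#'   defaults to the TFH/TR1 programmes of [default_expression_signature()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            simulate = TRUE,
                            paths = list(),
                            stages = list(clonotype = TRUE, repertoire = TRUE,
                                          expression = TRUE, lineage = TRUE),
                            repertoire = repertoire_config(),
                            expression = expression_config(),
                            germline_counts = c(6L, 4L, 6L, 4L),
                            spacer_len = 50L,
                            scoring = alignment_scoring(),
                            min_score = 10,
                            k = 3L, n_pcs = 20L,
                            lfc_threshold = 2, de_alpha = 0.01,
                            band = 1.0,
                            enrichment_background = "combined",
                            min_genes = 300L, max_mito = 0.10,
                            signatures = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  assert_that(inherits(cfg, "pipeline_config"), "not a pipeline_config",
              class = "tr1kit_validation_error")
  assert_that(is.character(cfg$out_dir) && length(cfg$out_dir) == 1L,
              "out_dir must be a single path", class = "tr1kit_validation_error")
  assert_that(is.numeric(cfg$seed) && cfg$seed >= 0,
              "seed must be a non-negative integer", class = "tr1kit_validation_error")
  if (!isTRUE(cfg$simulate)) {
    need <- c("germline_fasta", "contigs_fasta", "metadata_tsv")
    if (isTRUE(cfg$stages$expression)) {
      need <- c(need, "counts_mtx", "genes_tsv", "barcodes_tsv")
    }
    missing <- setdiff(need, names(cfg$paths))
    assert_that(length(missing) == 0,
                paste("config lacks input paths:", paste(missing, collapse = ", ")),
                class = "tr1kit_validation_error")
    for (p in unlist(cfg$paths[need])) {
      assert_that(file.exists(p), paste("input path does not exist:", p),
                  class = "tr1kit_validation_error")
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config()]
#'   (generator configurations are given as plain key-value maps).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path),
              class = "tr1kit_io_error")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$repertoire)) {
    raw$repertoire <- do.call(repertoire_config,
                              purrr::map(raw$repertoire, ~ if (is.list(.x)) purrr::map(.x, unlist) else unlist(.x)))
  }
  if (!is.null(raw$expression)) raw$expression <- do.call(expression_config, raw$expression)
  if (!is.null(raw$scoring)) raw$scoring <- do.call(alignment_scoring, raw$scoring)
  cfg <- do.call(pipeline_config, raw)
  validate_pipeline_config(cfg)
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "tr1kit_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates (optionally) synthetic-data generation, clonotype calling,
#' repertoire statistics, expression QC/clustering/differential expression and
#' clonotype-by-cluster lineage sharing; writes every artifact plus a JSON
#' report and an MD5 manifest under `config$out_dir`. Fully deterministic
#' given the configuration seed.
#'
#' @param config A [pipeline_config()] (or YAML path for
#'   [read_pipeline_config()]).
#' @return A list of class `pipeline_result` with elements `report` (nested
#'   list, also written as `report.json`), `tables` (the main tibbles) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  tables <- list()
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv_file(df, p)
    written <<- c(written, p)
  }

  # ---- inputs ----
  inputs <- run_stage("inputs", {
    if (isTRUE(config$simulate)) {
      gc <- config$germline_counts
      germline <- generate_germline_reference(gc[1], gc[2], gc[3], gc[4],
                                              seed = config$seed)
      truth <- simulate_repertoire(germline, config$repertoire, seed = config$seed)
      expr <- simulate_expression(config$expression, seed = config$seed + 1L,
                                  cells = truth$cells)
      write_fixture_bundle(truth, expr, file.path(config$out_dir, "inputs"))
      metadata <- truth$cells |>
        left_join(expr$cells |> select("cell_id", "mito_fraction"), by = "cell_id")
      list(germline = germline, contigs = truth$contigs, metadata = metadata,
           counts = expr$counts, truth = truth, expr = expr)
    } else {
      germline <- parse_germline_fasta(config$paths$germline_fasta)
      contigs <- read_contig_fasta(config$paths$contigs_fasta)
      metadata <- read_tsv_file(config$paths$metadata_tsv)
      counts <- if (isTRUE(config$stages$expression)) {
        read_counts(config$paths$counts_mtx, config$paths$genes_tsv,
                    config$paths$barcodes_tsv)
      }
      list(germline = germline, contigs = contigs, metadata = metadata,
           counts = counts, truth = NULL, expr = NULL)
    }
  })
  pools <- unique(inputs$metadata$pool)

  # ---- clonotype calling ----
  if (isTRUE(config$stages$clonotype)) {
    run_stage("clonotype", {
      recombinome <- build_recombinome(inputs$germline, config$spacer_len)
      calls <- call_cell_clonotype(inputs$contigs, recombinome,
                                   scoring = config$scoring,
                                   min_score = config$min_score)
      cells <- calls$cells |>
        left_join(inputs$metadata |> select("cell_id", "pool"), by = "cell_id")
      groups <- group_clonotypes(cells)
      members <- clonotype_members(groups)
      calls_tbl <- calls$calls |>
        left_join(cells |> select("cell_id", "pool"), by = "cell_id") |>
        left_join(members |> select("cell_id", "group_id"), by = "cell_id")
      emit(calls_tbl, "clonotype_calls.tsv")
      emit(members |> left_join(cells |> select("cell_id", "pool"), by = "cell_id"),
           "clonotype_members.tsv")
      tables$calls <- calls_tbl
      tables$cells <- cells
      tables$groups <- groups
      report$clonotype <- list(
        n_cells = nrow(cells), n_paired = sum(cells$paired),
        n_ambiguous = sum(cells$ambiguous),
        n_clonotypes = nrow(groups),
        per_pool = cells |>
          filter(.data$paired) |> count(.data$pool, name = "paired_cells")
      )
    })
  }

  # ---- repertoire statistics ----
  if (isTRUE(config$stages$repertoire) && !is.null(tables$groups)) {
    run_stage("repertoire", {
      cells <- tables$cells
      pool_groups <- purrr::map(
        stats::setNames(pools, pools),
        function(p) group_clonotypes(filter(cells, .data$pool == p))
      )
      sizes <- purrr::imap(pool_groups, function(g, p) {
        glance(clonal_size_distribution(g)) |> mutate(pool = p, .before = 1)
      }) |> bind_rows()
      emit(sizes, "clonal_sizes.tsv")

      shared <- tidyr::crossing(pool_a = pools, pool_b = pools) |>
        filter(.data$pool_a < .data$pool_b) |>
        rowwise() |>
        mutate(n_shared = length(shared_clonotypes(pool_groups[[.data$pool_a]],
                                                   pool_groups[[.data$pool_b]]))) |>
        ungroup()
      emit(shared, "shared_clonotypes.tsv")

      lead <- tibble::tribble(
        ~element, ~chain, ~class,
        "TRAV5D-4", "alpha", "V",
        "TRAJ18", "alpha", "J",
        "TRBV1", "beta", "V"
      )
      usage <- purrr::pmap(lead, function(element, chain, class) {
        u <- vj_usage(tables$calls |> filter(.data$productive),
                      element, chain, class)
        test <- chi_square_independence(u)
        u |> mutate(p_value = test$p_value)
      }) |> bind_rows()
      emit(usage, "vj_usage.tsv")

      cdr3 <- tables$calls |>
        filter(.data$productive, !is.na(.data$cdr3_aa)) |>
        select("pool", "chain", "cdr3_aa")
      lengths_tbl <- cdr3_length_summary(cdr3)
      emit(lengths_tbl, "cdr3_lengths.tsv")
      enrich <- positional_residue_enrichment(
        cdr3, background = config$enrichment_background)
      emit(enrich, "cdr3_enrichment.tsv")

      # one CDR3beta per distinct clonotype, per pool
      charged <- tables$calls |>
        filter(.data$productive, .data$chain == "beta", !is.na(.data$cdr3_aa)) |>
        distinct(.data$pool, .data$identifier, .data$cdr3_aa) |>
        group_by(.data$pool) |>
        group_modify(~ charged_p2p3_fraction(.x$cdr3_aa)) |>
        ungroup()
      emit(charged, "charged_p2p3.tsv")

      report$repertoire <- list(
        clonal_sizes = sizes, shared = shared,
        usage = usage |> select("element", "pool", "used", "total", "p_value"),
        cdr3_lengths = lengths_tbl, charged_p2p3 = charged
      )
      tables$usage <- usage
      tables$charged <- charged
    })
  }

  # ---- expression ----
  if (isTRUE(config$stages$expression)) {
    run_stage("expression", {
      md <- inputs$metadata
      assert_that("mito_fraction" %in% names(md),
                  "metadata lacks mito_fraction", class = "tr1kit_config_error")
      mito <- stats::setNames(md$mito_fraction, md$cell_id)
      qc <- qc_filter(inputs$counts, mito_fraction = mito,
                      min_genes = config$min_genes, max_mito = config$max_mito)
      norm <- normalize_log(qc$counts)
      labels <- cluster_cells(norm, k = config$k, n_pcs = config$n_pcs,
                              seed = config$seed)
      emit(qc$report, "qc_report.tsv")
      emit(labels, "cluster_labels.tsv")

      de_by_cluster <- purrr::map(
        stats::setNames(1:(config$k - 1), 1:(config$k - 1)),
        function(cl) {
          a <- labels$cell_id[labels$cluster == cl]
          b <- labels$cell_id[labels$cluster == 0L]
          if (length(a) < 3L || length(b) < 3L) return(NULL)
          de_negative_binomial(qc$counts, a, b,
                               lfc_threshold = config$lfc_threshold,
                               alpha = config$de_alpha)
        }
      )
      de_by_cluster <- purrr::compact(de_by_cluster)
      purrr::iwalk(de_by_cluster, function(de, cl) {
        emit(de, sprintf("de_cluster%s_vs_cluster0.tsv", cl))
      })

      # per-pool DE versus the conventional pool, for cross-pool concordance
      tet_pools <- setdiff(pools, "Tconv")
      qc_cells <- qc$report$cell_id[qc$report$passed]
      pool_cells <- purrr::map(stats::setNames(pools, pools), function(p) {
        intersect(md$cell_id[md$pool == p], qc_cells)
      })
      de_by_pool <- NULL
      concordance <- NULL
      if ("Tconv" %in% pools && length(tet_pools) >= 1 &&
          length(pool_cells$Tconv) >= 3 &&
          all(lengths(pool_cells[tet_pools]) >= 3)) {
        de_by_pool <- purrr::map(stats::setNames(tet_pools, tet_pools), function(p) {
          de_negative_binomial(qc$counts, pool_cells[[p]], pool_cells$Tconv,
                               lfc_threshold = config$lfc_threshold,
                               alpha = config$de_alpha)
        })
        if (length(tet_pools) >= 2) {
          concordance <- tidyr::crossing(a = tet_pools, b = tet_pools) |>
            filter(.data$a < .data$b) |>
            rowwise() |>
            mutate(res = list(tryCatch(
              logfc_concordance(de_by_pool[[.data$a]], de_by_pool[[.data$b]],
                                band = config$band),
              tr1kit_input_error = function(e) NULL))) |>
            ungroup() |>
            filter(!purrr::map_lgl(.data$res, is.null)) |>
            tidyr::unnest("res")
          if (nrow(concordance) > 0) emit(concordance, "logfc_concordance.tsv")
        }
      }

      signatures <- config$signatures %||% {
        sig <- default_expression_signature()
        list(TFH = sig$gene[sig$programme == "TFH"],
             TR1 = sig$gene[sig$programme == "TR1"])
      }
      overlap <- tryCatch(
        signature_cluster_overlap(de_by_cluster[c("1", "2")], signatures),
        error = function(e) NULL
      )
      if (!is.null(overlap)) emit(overlap$percentages, "signature_overlap.tsv")

      tables$qc <- qc$report
      tables$labels <- labels
      tables$de_by_cluster <- de_by_cluster
      tables$de_by_pool <- de_by_pool
      report$expression <- list(
        n_pass_qc = sum(qc$report$passed),
        n_fail_qc = sum(!qc$report$passed),
        cluster_sizes = count(labels, .data$cluster),
        n_significant = purrr::imap(de_by_cluster,
                                    ~ tibble(cluster = .y, n = sum(.x$significant))) |>
          bind_rows(),
        concordance = concordance,
        signature_overlap = if (!is.null(overlap)) overlap$percentages
      )
    })
  }

  # ---- lineage sharing ----
  if (isTRUE(config$stages$lineage) && !is.null(tables$groups) &&
      !is.null(tables$labels)) {
    run_stage("lineage", {
      tet_cells <- inputs$metadata |> filter(.data$pool != "Tconv")
      tet_groups <- group_clonotypes(
        tables$cells |> filter(.data$cell_id %in% tet_cells$cell_id))
      ctab <- clonotype_cluster_table(tet_groups, tables$labels)
      if (nrow(ctab) > 0) {
        emit(as_tibble(ctab), "clonotype_cluster_table.tsv")
        sharing <- sharing_summary(ctab)
        prop <- proportionality_check(ctab)
        emit(sharing, "sharing_summary.tsv")
        emit(prop, "proportionality.tsv")
        tables$cluster_table <- ctab
        report$lineage <- list(
          sharing = sharing,
          proportionality = glance(prop)
        )
      } else {
        report$lineage <- list(sharing = NULL, proportionality = NULL)
      }
    })
  }

  # ---- report + manifest ----
  report$parameters <- list(
    seed = config$seed, spacer_len = config$spacer_len,
    min_score = config$min_score, k = config$k, n_pcs = config$n_pcs,
    lfc_threshold = config$lfc_threshold, de_alpha = config$de_alpha,
    min_genes = config$min_genes, max_mito = config$max_mito
  )
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, dataframe = "rows", force = TRUE)
  written <- c(written, report_path)
  manifest <- file_manifest(written, file.path(config$out_dir, "manifest.json"))

  structure(list(report = report, tables = tables, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:", paste(names(x$report), collapse = ", "), "\n")
  invisible(x)
}
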