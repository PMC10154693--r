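#' Configuration for the paired-chain repertoire simulator
#'
#' Defaults emulate the oligoclonal insulin-register-specific repertoires the
#' pipeline was designed for: four pools (the tetramer-negative `Tconv`
#' control and three tetramer-positive register pools `R1`, `R2`, `R3`) with
#' the paired-cell counts, per-pool clonality, V/J usage skew and CDR3beta
#' charged-motif prevalence reported for that system. Every probability and
#' weight is overridable.
#'
#' @param n_cells Named integer vector of cells per pool.
#' @param clone_size_mean Named numeric vector; mean clone size per pool
#'   (clone sizes are 1 + geometric). 1 gives an all-singleton pool.
#' @param lead_usage Named list of per-pool probabilities that a rearrangement
#'   uses the lead (skewed) element of each class: entries `v_alpha`,
#'   `j_alpha`, `v_beta`, each a named vector over pools. Remaining
#'   probability is spread uniformly over the other segments.
#' @param charged_motif_prob Named numeric vector per pool: probability that a
#'   clone's CDR3beta carries an aspartate/glutamate at position 2 or 3.
#' @param junction_mean_nt Mean junction length in nucleotides before framing.
#' @param junction_cap_nt Hard cap on junction length (the assembler the data
#'   model emulates caps junctions at 50 nt).
#' @param dual_alpha_rate Probability that a clone carries two productive
#'   alpha rearrangements.
#' @param error_rate Per-base substitution probability applied independently
#'   to every contig copy.
#' @param leak_rate Probability that a repeated tetramer-positive clonotype
#'   also seeds cells in the Tconv pool (whole-clonotype low-avidity leak).
#' @param leak_cells Number of Tconv cells added per leaked clonotype.
#' @param cluster_probs List with elements `tconv` and `tet` giving the
#'   probabilities that a cell of a clone falls in expression clusters 0/1/2.
#' @param productive Logical; keep all simulated chains in frame and stop-free.
#'
#' @return A list of class `repertoire_config`.
#' @export
repertoire_config <- function(
    n_cells = c(Tconv = 131, R1 = 144, R2 = 94, R3 = 155),
    clone_size_mean = c(Tconv = 1.05, R1 = 1.26, R2 = 4.5, R3 = 6),
    lead_usage = list(
      v_alpha = c(Tconv = 0.107, R1 = 0.175, R2 = 0.403, R3 = 0.425),
      j_alpha = c(Tconv = 0.076, R1 = 0.091, R2 = 0.186, R3 = 0.265),
      v_beta  = c(Tconv = 0.103, R1 = 0.050, R2 = 0.200, R3 = 0.671)
    ),
    charged_motif_prob = c(Tconv = 0.15, R1 = 0.372, R2 = 0.101, R3 = 0.512),
    junction_mean_nt = 21,
    junction_cap_nt = 50,
    dual_alpha_rate = 0.10,
    error_rate = 0,
    leak_rate = 0.3,
    leak_cells = 1L,
    cluster_probs = list(tconv = c(0.88, 0.06, 0.06), tet = c(0.10, 0.27, 0.63)),
    productive = TRUE) {
  cfg <- list(
    n_cells = n_cells, clone_size_mean = clone_size_mean,
    lead_usage = lead_usage, charged_motif_prob = charged_motif_prob,
    junction_mean_nt = junction_mean_nt, junction_cap_nt = junction_cap_nt,
    dual_alpha_rate = dual_alpha_rate, error_rate = error_rate,
    leak_rate = leak_rate, leak_cells = leak_cells,
    cluster_probs = cluster_probs, productive = productive
  )
  probs <- c(cfg$charged_motif_prob, cfg$dual_alpha_rate, cfg$error_rate, cfg$leak_rate,
             unlist(cfg$lead_usage), unlist(cfg$cluster_probs))
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  assert_that(all(cfg$n_cells >= 0), "n_cells must be non-negative")
  structure(cfg, class = "repertoire_config")
}

# Per-segment sampling weights for one pool: lead element carries `lead_p`,
# the rest share the remainder uniformly.
usage_weights <- function(names, lead_p) {
  assert_that(length(names) >= 1, "usage weights need at least one segment")
  if (length(names) == 1L) return(stats::setNames(1, names))
  w <- rep((1 - lead_p) / (length(names) - 1L), length(names))
  w[1L] <- lead_p
  stats::setNames(w, names)
}

DE_CODONS <- c("GAT", "GAC", "GAA", "GAG")

draw_junction <- function(mean_nt, cap_nt, productive, motif = NULL, min_codons = 0L) {
  len <- min(stats::rgeom(1L, prob = 1 / (mean_nt + 1)), cap_nt)
  if (productive) {
    len <- min(3L * round(len / 3), 3L * (cap_nt %/% 3L))
    len <- max(len, 3L * min_codons)
    n_codons <- len %/% 3L
    if (n_codons == 0L) return("")
    codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    if (isTRUE(motif)) {
      # CDR3 P2/P3 are the first two junction codons: plant D/E in one of them
      codons[sample(1:2, 1L)] <- sample(DE_CODONS, 1L)
    } else if (isFALSE(motif)) {
      # motif explicitly absent: keep D/E out of P2 and P3
      head_n <- min(2L, n_codons)
      codons[seq_len(head_n)] <- sample(setdiff(SENSE_CODONS, DE_CODONS),
                                        head_n, replace = TRUE)
    }
    paste(codons, collapse = "")
  } else {
    if (len == 0L) return("")
    random_dna(len)
  }
}

mutate_sequence <- function(seq, error_rate) {
  if (error_rate <= 0 || nchar(seq) == 0L) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(bases)) < error_rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit],
                         function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1))
  }
  paste(bases, collapse = "")
}

#' Simulate an oligoclonal paired-chain single-cell TCR repertoire
#'
#' Draws clonotypes (paired alpha/beta rearrangements built as
#' V + junction + J over a supplied germline reference), expands them into
#' cells according to a per-pool clone-size distribution, optionally leaks
#' repeated tetramer-positive clonotypes into the Tconv pool, and emits
#' per-cell contigs with an optional per-base substitution error.
#'
#' @param germline Germline segment tibble from
#'   [generate_germline_reference()] or [read_fasta()] + parsing.
#' @param config A [repertoire_config()].
#' @param seed Integer seed; output is a pure function of (germline, config,
#'   seed).
#'
#' @return A list of class `repertoire_truth` with tibbles `clones` (one row
#'   per clonotype: pool, size, true paired identifier, cluster-assignment
#'   probabilities), `clone_chains` (one row per rearrangement), `cells`
#'   (cell id, pool, clone id, true expression cluster) and `contigs` (one row
#'   per per-cell chain copy, id `cell|chain|index`).
#'
#' @examples
#' germ <- generate_germline_reference(4, 3, 4, 3, seed = 1)
#' rep <- simulate_repertoire(germ, repertoire_config(n_cells = c(R1 = 20)), seed = 2)
#' rep$clones
#' @export
simulate_repertoire <- function(germline, config = repertoire_config(), seed = 1L) {
  validate_germline(germline)
  if (!inherits(config, "repertoire_config")) config <- do.call(repertoire_config, config)
  pools <- names(config$n_cells)
  assert_that(length(pools) > 0, "n_cells must be a named vector of pools")

  seg <- function(chain, class) filter(germline, .data$chain == !!chain, .data$segment_class == !!class)
  v_a <- seg("alpha", "V"); j_a <- seg("alpha", "J")
  v_b <- seg("beta", "V"); j_b <- seg("beta", "J")
  assert_that(nrow(v_a) > 0 && nrow(j_a) > 0 && nrow(v_b) > 0 && nrow(j_b) > 0,
              "germline must contain V and J segments for both chains",
              class = "tr1kit_config_error")

  seq_of <- stats::setNames(germline$sequence, germline$name)

  with_seed(seed, {
    clone_rows <- list(); chain_rows <- list(); clone_counter <- 0L

    for (pool in pools) {
      n <- config$n_cells[[pool]]
      if (n == 0L) next
      m <- max(config$clone_size_mean[[pool]] %||% 1, 1)
      sizes <- integer(0)
      while (sum(sizes) < n) {
        sizes <- c(sizes, 1L + stats::rgeom(32L, prob = min(1 / m, 1)))
      }
      sizes <- sizes[cumsum(sizes) - sizes < n]
      sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])

      lead_p <- function(slot, fallback) {
        p <- config$lead_usage[[slot]]
        if (is.null(p)) fallback else (p[[pool]] %||% fallback)
      }
      w_va <- usage_weights(v_a$name, lead_p("v_alpha", 1 / nrow(v_a)))
      w_ja <- usage_weights(j_a$name, lead_p("j_alpha", 1 / nrow(j_a)))
      w_vb <- usage_weights(v_b$name, lead_p("v_beta", 1 / nrow(v_b)))
      w_jb <- usage_weights(j_b$name, 1 / nrow(j_b))
      motif_p <- config$charged_motif_prob[[pool]] %||% 0
      cl_probs <- if (pool == "Tconv") config$cluster_probs$tconv else config$cluster_probs$tet

      for (sz in sizes) {
        clone_counter <- clone_counter + 1L
        clone_id <- sprintf("clone%04d", clone_counter)
        n_alpha <- 1L + (stats::runif(1) < config$dual_alpha_rate)

        one_chain <- function(chain, v_tab, w_v, j_tab, w_j,
                              motif = NULL, min_codons = 0L) {
          v <- sample(names(w_v), 1L, prob = w_v)
          j <- sample(names(w_j), 1L, prob = w_j)
          junction <- draw_junction(config$junction_mean_nt, config$junction_cap_nt,
                                    config$productive, motif, min_codons)
          tibble(clone_id = clone_id, chain = chain, v_name = v,
                 junction_nt = junction, j_name = j,
                 sequence = paste0(seq_of[[v]], junction, seq_of[[j]]))
        }

        # beta junctions carry >= 2 codons so CDR3 P2/P3 are generator-controlled
        ch <- bind_rows(
          purrr::map(seq_len(n_alpha), ~ one_chain("alpha", v_a, w_va, j_a, w_ja)),
          one_chain("beta", v_b, w_vb, j_b, w_jb,
                    motif = stats::runif(1) < motif_p, min_codons = 2L)
        )
        ident <- paste(sort(paste(ch$v_name, ch$junction_nt, ch$j_name, sep = "-")),
                       collapse = "+")
        clone_rows[[clone_counter]] <- tibble(
          clone_id = clone_id, pool = pool, size = sz, true_identifier = ident,
          p_cluster0 = cl_probs[1], p_cluster1 = cl_probs[2], p_cluster2 = cl_probs[3]
        )
        chain_rows[[clone_counter]] <- ch
      }
    }

    clones <- bind_rows(clone_rows)
    clone_chains <- bind_rows(chain_rows)

    if (length(clone_rows) == 0L) {
      return(structure(list(clones = clones, clone_chains = clone_chains,
                            cells = tibble(), contigs = tibble(), germline = germline),
                       class = "repertoire_truth"))
    }

    # Low-avidity leak: whole repeated tetramer+ clonotypes reappear as Tconv cells.
    leak <- clones |>
      filter(.data$pool != "Tconv", .data$size > 1L) |>
      filter(stats::runif(n()) < config$leak_rate)

    cells <- clones |>
      select("clone_id", "pool", "size") |>
      tidyr::uncount(.data$size)
    if (nrow(leak) > 0L) {
      cells <- bind_rows(
        cells,
        leak |> select("clone_id") |> mutate(pool = "Tconv") |>
          tidyr::uncount(config$leak_cells)
      )
    }
    cells <- cells |>
      mutate(cell_id = sprintf("cell%04d", row_number())) |>
      left_join(clones |> select("clone_id", "p_cluster0", "p_cluster1", "p_cluster2"),
                by = "clone_id") |>
      rowwise() |>
      mutate(true_cluster = sample(0:2, 1L,
                                   prob = c(.data$p_cluster0, .data$p_cluster1, .data$p_cluster2))) |>
      ungroup() |>
      select("cell_id", "pool", "clone_id", "true_cluster")

    contigs <- cells |>
      select("cell_id", "clone_id") |>
      left_join(clone_chains, by = "clone_id", relationship = "many-to-many") |>
      group_by(.data$cell_id, .data$chain) |>
      mutate(contig_index = row_number()) |>
      ungroup() |>
      mutate(
        contig_id = paste(.data$cell_id, .data$chain, .data$contig_index, sep = "|"),
        sequence = vapply(.data$sequence, mutate_sequence, character(1),
                          error_rate = config$error_rate, USE.NAMES = FALSE)
      ) |>
      select("contig_id", "cell_id", "chain", "contig_index", "sequence")

    # leaked clones now have members in two pools; recompute realised sizes
    clones <- clones |>
      select(-"size") |>
      left_join(count(cells, .data$clone_id, name = "size"), by = "clone_id")

    structure(list(clones = clones, clone_chains = clone_chains,
                   cells = cells, contigs = contigs, germline = germline),
              class = "repertoire_truth")
  })
}

#' @export
print.repertoire_truth <- function(x, ...) {
  cat("<repertoire_truth>\n")
  cat("  clones:", nrow(x$clones), " cells:", nrow(x$cells),
      " contigs:", nrow(x$contigs), "\n")
  if (nrow(x$cells) > 0) print(count(x$cells, .data$pool))
  invisible(x)
}
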