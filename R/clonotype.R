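#' Call per-cell clonotypes from assembled TCR contigs
#'
#' Runs segment assignment, junction extraction and CDR3 translation for every
#' contig of every cell, builds the per-chain identifier
#' `"Vname-junction-Jname"`, and derives each cell's paired identifier: the
#' lexicographically sorted tuple of all productive per-chain identifiers
#' (joined with `"+"`). Cells lacking a productive chain at either locus are
#' flagged unpaired; cells with more than `max_chains_per_locus` productive
#' chains at one locus are flagged ambiguous and excluded from pairing.
#'
#' @param contigs Tibble with columns `contig_id`, `cell_id`, `chain`
#'   (`"alpha"`/`"beta"`) and `sequence`.
#' @param recombinome A [build_recombinome()] result.
#' @param scoring An [alignment_scoring()] list.
#' @param min_score Minimum alignment score (see [assign_segments()]).
#' @param max_chains_per_locus Productive chains tolerated per locus before a
#'   cell is called ambiguous (default 2, admitting dual-alpha cells).
#'
#' @return A list of class `clonotype_calls` with tibbles:
#'   * `calls` — one row per passing contig: `cell_id`, `chain`, `contig_id`,
#'     `v_name`, `junction_nt`, `j_name`, `identifier`, `cdr3_aa`,
#'     `productive`;
#'   * `cells` — one row per cell: `cell_id`, `paired_identifier` (`NA` when
#'     unpaired), `n_alpha`, `n_beta`, `paired`, `ambiguous`.
#'
#' @examples
#' germ <- generate_germline_reference(2, 2, 2, 2, seed = 1)
#' rep <- simulate_repertoire(germ, repertoire_config(n_cells = c(R1 = 5)), seed = 2)
#' calls <- call_cell_clonotype(rep$contigs, build_recombinome(germ))
#' calls$cells
#' @export
call_cell_clonotype <- function(contigs, recombinome,
                                scoring = alignment_scoring(), min_score = 10,
                                max_chains_per_locus = 2L) {
  contigs <- as_tibble(contigs)
  assert_that(nrow(contigs) > 0, "at least one contig is required",
              class = "tr1kit_input_error")
  assert_that(all(c("contig_id", "cell_id", "chain", "sequence") %in% names(contigs)),
              "contigs need columns contig_id, cell_id, chain, sequence",
              class = "tr1kit_input_error")

  asg <- assign_segments(contigs, recombinome, scoring = scoring, min_score = min_score)
  asg <- left_join(asg, contigs |> select("contig_id", "cell_id", "sequence"),
                   by = "contig_id")

  calls <- asg |>
    filter(.data$passed) |>
    rowwise() |>
    mutate(
      junction_nt = extract_junction(.data$sequence, pick(everything())),
      cdr3 = list(tryCatch(
        translate_cdr3(.data$sequence, pick(everything())),
        tr1kit_annotation_error = function(e) list(cdr3_aa = NA_character_, productive = FALSE)
      ))
    ) |>
    ungroup() |>
    mutate(
      cdr3_aa = map_chr(.data$cdr3, "cdr3_aa"),
      productive = purrr::map_lgl(.data$cdr3, "productive"),
      identifier = paste(.data$v_name, .data$junction_nt, .data$j_name, sep = "-")
    ) |>
    select("cell_id", "chain", "contig_id", "v_name", "junction_nt", "j_name",
           "identifier", "cdr3_aa", "productive")

  cells <- contigs |>
    distinct(.data$cell_id) |>
    left_join(
      calls |>
        filter(.data$productive) |>
        distinct(.data$cell_id, .data$chain, .data$identifier) |>
        group_by(.data$cell_id) |>
        summarise(
          n_alpha = sum(.data$chain == "alpha"),
          n_beta = sum(.data$chain == "beta"),
          paired_identifier = paste(sort(.data$identifier), collapse = "+"),
          .groups = "drop"
        ),
      by = "cell_id"
    ) |>
    mutate(
      n_alpha = tidyr::replace_na(.data$n_alpha, 0L),
      n_beta = tidyr::replace_na(.data$n_beta, 0L),
      ambiguous = .data$n_alpha > max_chains_per_locus |
        .data$n_beta > max_chains_per_locus,
      paired = .data$n_alpha >= 1L & .data$n_beta >= 1L & !.data$ambiguous,
      paired_identifier = ifelse(.data$paired, .data$paired_identifier, NA_character_)
    )

  structure(list(calls = calls, cells = cells), class = "clonotype_calls")
}

#' Group cells into clonotypes by identical paired identifiers
#'
#' Cells whose paired identifiers (V element, junctional nucleotide sequence
#' and J gene name for every productive chain) are identical belong to one
#' clonotype. Unpaired or ambiguous cells are excluded.
#'
#' @param calls A `clonotype_calls` object from [call_cell_clonotype()], or a
#'   tibble with columns `cell_id` and `paired_identifier`.
#' @return A tibble with one row per clonal group: `group_id` (assigned by
#'   decreasing size, then identifier), `paired_identifier`, `size` and a
#'   list-column `cells` of member cell ids.
#'
#' @export
group_clonotypes <- function(calls) {
  cells <- if (inherits(calls, "clonotype_calls")) calls$cells else as_tibble(calls)
  assert_that(all(c("cell_id", "paired_identifier") %in% names(cells)),
              "need columns cell_id and paired_identifier",
              class = "tr1kit_input_error")
  cells |>
    filter(!is.na(.data$paired_identifier)) |>
    group_by(.data$paired_identifier) |>
    summarise(size = n(), cells = list(.data$cell_id), .groups = "drop") |>
    arrange(desc(.data$size), .data$paired_identifier) |>
    mutate(group_id = sprintf("ctype%04d", row_number())) |>
    select("group_id", "paired_identifier", "size", "cells")
}

#' Long cell-to-clonotype mapping
#'
#' @param groups A [group_clonotypes()] result.
#' @return Tibble with columns `cell_id`, `group_id`, `paired_identifier`,
#'   `size`.
#' @export
clonotype_members <- function(groups) {
  groups |>
    select("group_id", "paired_identifier", "size", "cells") |>
    tidyr::unnest_longer("cells", values_to = "cell_id") |>
    select("cell_id", "group_id", "paired_identifier", "size")
}

#' @export
print.clonotype_calls <- function(x, ...) {
  cat("<clonotype_calls> ", nrow(x$calls), "chain calls across",
      nrow(x$cells), "cells;", sum(x$cells$paired), "paired\n")
  invisible(x)
}
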