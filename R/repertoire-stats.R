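#' Clonal size distribution of a grouped repertoire
#'
#' @param groups A [group_clonotypes()] result (optionally with a `pool`
#'   column to keep pools separate).
#' @return The groups tibble sorted by decreasing size, with class
#'   `clonal_sizes`; [glance()] returns the number of clonotypes, singletons,
#'   repeated clonotypes and cells.
#' @export
clonal_size_distribution <- function(groups) {
  out <- as_tibble(groups) |> arrange(desc(.data$size), .data$paired_identifier)
  class(out) <- c("clonal_sizes", class(out))
  out
}

#' @export
glance.clonal_sizes <- function(x, ...) {
  tibble(
    n_clonotypes = nrow(x),
    n_singletons = sum(x$size == 1L),
    n_repeated = sum(x$size > 1L),
    n_cells = sum(x$size)
  )
}

#' Clonotypes shared between two pools
#'
#' Exact set intersection on paired identifiers; both pools must have been
#' grouped against the same recombinome for identifiers to be comparable.
#'
#' @param groups_a,groups_b [group_clonotypes()] results.
#' @return Sorted character vector of shared paired identifiers.
#' @export
shared_clonotypes <- function(groups_a, groups_b) {
  sort(intersect(groups_a$paired_identifier, groups_b$paired_identifier))
}

#' Per-pool usage of a V or J element
#'
#' Counts chains (not cells: dual-alpha cells contribute two alpha chains)
#' carrying a given germline element in each pool, with the pool's total
#' chains of that chain type as denominator.
#'
#' @param calls Tibble of per-chain clonotype calls (columns `pool`, `chain`,
#'   `v_name`, `j_name`), e.g. the `calls` tibble of [call_cell_clonotype()]
#'   joined to cell pool labels.
#' @param element Element name, e.g. `"TRAV5D-4"`.
#' @param chain `"alpha"` or `"beta"`.
#' @param segment_class `"V"` or `"J"`.
#' @return Tibble of class `usage_table`: `element`, `pool`, `used`, `total`.
#' @export
vj_usage <- function(calls, element, chain, segment_class = c("V", "J")) {
  segment_class <- match.arg(segment_class)
  calls <- as_tibble(calls)
  assert_that(all(c("pool", "chain", "v_name", "j_name") %in% names(calls)),
              "calls need columns pool, chain, v_name, j_name",
              class = "tr1kit_input_error")
  col <- if (segment_class == "V") "v_name" else "j_name"
  pool_calls <- filter(calls, .data$chain == !!chain)
  assert_that(nrow(pool_calls) > 0, "no chains of the requested type",
              class = "tr1kit_input_error")
  assert_that(element %in% pool_calls[[col]],
              paste0("unknown element '", element, "' for ", chain, " ", segment_class),
              class = "tr1kit_lookup_error")
  out <- pool_calls |>
    group_by(.data$pool) |>
    summarise(used = sum(.data[[col]] == element), total = n(), .groups = "drop") |>
    mutate(element = element, .before = 1L)
  class(out) <- c("usage_table", class(out))
  out
}

#' Chi-square test of element usage independence across pools
#'
#' Pearson chi-square (no continuity correction) on the 2 x k used/not-used
#' table, df = k - 1. When any expected count falls below 5 and there are
#' exactly two pools, Fisher's exact test is used instead.
#'
#' @param usage A `usage_table` tibble (columns `pool`, `used`, `total`).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#'
#' @examples
#' chi_square_independence(
#'   dplyr::filter(insb_vj_usage(), element == "TRAV5D-4")
#' )
#' @export
chi_square_independence <- function(usage) {
  usage <- as_tibble(usage)
  assert_that(nrow(usage) >= 2, "need at least two pools",
              class = "tr1kit_input_error")
  assert_that(all(usage$total > 0), "every pool must have a positive total",
              class = "tr1kit_input_error")
  assert_that(all(usage$used <= usage$total), "used cannot exceed total",
              class = "tr1kit_input_error")
  tab <- rbind(used = usage$used, not_used = usage$total - usage$used)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) && ncol(tab) == 2L) {
    ft <- stats::fisher.test(tab)
    return(tibble(statistic = NA_real_, df = NA_integer_,
                  p_value = ft$p.value, method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, method = "pearson")
}

#' CDR3 length summary per pool and chain
#'
#' @param cdr3 Tibble with columns `pool`, `chain`, `cdr3_aa` (`NA` rows are
#'   dropped).
#' @return Tibble: `pool`, `chain`, `n`, `mean_length`, `sem`. The standard
#'   error of a single observation is reported as 0.
#' @export
cdr3_length_summary <- function(cdr3) {
  cdr3 <- as_tibble(cdr3) |> filter(!is.na(.data$cdr3_aa))
  assert_that(nrow(cdr3) > 0, "no CDR3 sequences supplied",
              class = "tr1kit_input_error")
  cdr3 |>
    mutate(len = nchar(.data$cdr3_aa)) |>
    group_by(.data$pool, .data$chain) |>
    summarise(
      n = n(),
      mean_length = mean(.data$len),
      sem = if (n() > 1L) stats::sd(.data$len) / sqrt(n()) else 0,
      .groups = "drop"
    )
}

#' Positional residue enrichment over the CDR3 N-terminus
#'
#' For each pool, the frequency of each amino acid at CDR3 positions
#' 1..`n_positions` (position 1 = the conserved cysteine) is divided by its
#' background frequency at the same position. The default background pools
#' all supplied pools together; alternatives are per-pool (identity) and
#' uniform (1/20). CDR3s shorter than `n_positions` contribute only to the
#' positions they cover.
#'
#' @param cdr3 Tibble with columns `pool` and `cdr3_aa`.
#' @param n_positions Number of N-terminal positions analysed (default 6).
#' @param background `"combined"`, `"pool"` or `"uniform"`.
#' @return Tibble: `pool`, `position`, `residue`, `pool_freq`,
#'   `background_freq`, `enrichment`.
#' @export
positional_residue_enrichment <- function(cdr3, n_positions = 6L,
                                          background = c("combined", "pool", "uniform")) {
  background <- match.arg(background)
  cdr3 <- as_tibble(cdr3) |> filter(!is.na(.data$cdr3_aa))
  assert_that(nrow(cdr3) > 0, "no CDR3 sequences supplied",
              class = "tr1kit_input_error")

  long <- cdr3 |>
    mutate(residues = str_split(str_sub(.data$cdr3_aa, 1L, n_positions), "")) |>
    select("pool", "residues") |>
    tidyr::unnest_longer("residues", values_to = "residue", indices_to = "position") |>
    filter(.data$residue %in% AA_ALPHABET)

  pool_freq <- long |>
    group_by(.data$pool, .data$position, .data$residue) |>
    summarise(count = n(), .groups = "drop_last") |>
    mutate(pool_freq = .data$count / sum(.data$count)) |>
    ungroup()

  bg <- switch(background,
    combined = long |>
      group_by(.data$position, .data$residue) |>
      summarise(bg_count = n(), .groups = "drop_last") |>
      mutate(background_freq = .data$bg_count / sum(.data$bg_count)) |>
      ungroup() |>
      select("position", "residue", "background_freq"),
    uniform = tidyr::crossing(position = seq_len(n_positions),
                              residue = AA_ALPHABET) |>
      mutate(background_freq = 1 / length(AA_ALPHABET)),
    pool = pool_freq |> select("pool", "position", "residue",
                               background_freq = "pool_freq")
  )

  by_cols <- if (background == "pool") c("pool", "position", "residue") else c("position", "residue")
  pool_freq |>
    left_join(bg, by = by_cols) |>
    mutate(enrichment = .data$pool_freq / .data$background_freq) |>
    select("pool", "position", "residue", "pool_freq", "background_freq", "enrichment") |>
    arrange(.data$pool, .data$position, desc(.data$enrichment))
}

#' Fraction of clonotypes with a charged residue at CDR3 position 2 or 3
#'
#' The fraction of distinct clonotype CDR3beta sequences carrying aspartate
#' (D) or glutamate (E) at position 2 or 3, counting from the conserved
#' cysteine (position 1). Sequences shorter than 3 residues are excluded from
#' the denominator (a message reports how many).
#'
#' @param cdr3 Character vector of CDR3beta amino-acid sequences (one per
#'   clonotype; duplicates are collapsed).
#' @return One-row tibble: `n_clonotypes`, `n_charged`, `fraction`,
#'   `n_excluded`.
#' @export
charged_p2p3_fraction <- function(cdr3) {
  cdr3 <- unique(cdr3[!is.na(cdr3)])
  assert_that(length(cdr3) > 0, "no CDR3 sequences supplied",
              class = "tr1kit_input_error")
  short <- nchar(cdr3) < 3L
  if (any(short)) {
    rlang::inform(sprintf("%d CDR3 sequence(s) shorter than 3 residues excluded",
                          sum(short)))
  }
  kept <- cdr3[!short]
  assert_that(length(kept) > 0, "all CDR3 sequences shorter than 3 residues",
              class = "tr1kit_input_error")
  charged <- str_sub(kept, 2L, 2L) %in% c("D", "E") |
    str_sub(kept, 3L, 3L) %in% c("D", "E")
  tibble(
    n_clonotypes = length(kept),
    n_charged = sum(charged),
    fraction = mean(charged),
    n_excluded = sum(short)
  )
}

#' Published V/J element usage counts for insulin-register-specific pools
#'
#' Chain-level usage of the skewed germline elements TRAV5D-4, TRAJ18 and
#' TRBV1 in CD4+ T-cell pools specific for the three insulin B:9-23 binding
#' registers (R1, R2, R3) and in the tetramer-negative conventional pool, as
#' reported for pMHCII-nanomedicine-treated NOD mice. Denominators are total
#' chains of the matching type in each pool.
#'
#' @return A `usage_table`-compatible tibble: `element`, `chain`,
#'   `segment_class`, `pool`, `used`, `total`.
#' @export
insb_vj_usage <- function() {
  tibble::tribble(
    ~element,   ~chain,  ~segment_class, ~pool,   ~used, ~total,
    "TRAV5D-4", "alpha", "V",            "R2",     52L,  129L,
    "TRAV5D-4", "alpha", "V",            "R3",     77L,  181L,
    "TRAV5D-4", "alpha", "V",            "R1",     27L,  154L,
    "TRAV5D-4", "alpha", "V",            "Tconv",  14L,  131L,
    "TRAJ18",   "alpha", "J",            "R2",     24L,  129L,
    "TRAJ18",   "alpha", "J",            "R3",     48L,  181L,
    "TRAJ18",   "alpha", "J",            "R1",     14L,  154L,
    "TRAJ18",   "alpha", "J",            "Tconv",  10L,  131L,
    "TRBV1",    "beta",  "V",            "R2",     22L,  110L,
    "TRBV1",    "beta",  "V",            "R3",     98L,  146L,
    "TRBV1",    "beta",  "V",            "R1",      7L,  140L,
    "TRBV1",    "beta",  "V",            "Tconv",  12L,  117L
  )
}
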