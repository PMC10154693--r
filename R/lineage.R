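#' Cross-tabulate repeated clonotypes against expression clusters
#'
#' Counts, for every repeated clonotype (size > 1), how many of its member
#' cells fall in each expression cluster. Member cells without a cluster label
#' are dropped with a warning.
#'
#' @param groups A [group_clonotypes()] result.
#' @param labels A [cluster_cells()] result or tibble (`cell_id`, `cluster`).
#' @return Tibble of class `clonotype_cluster_table`: `group_id`,
#'   `paired_identifier`, one `cluster_<id>` count column per cluster and
#'   `n_cells` (labelled member cells). Attribute `cluster_sizes` holds the
#'   total labelled cells per cluster (all cells, not just repeated
#'   clonotypes). Empty (with a warning) when no clonotype is repeated.
#' @export
clonotype_cluster_table <- function(groups, labels) {
  labels <- as_tibble(labels)
  members <- clonotype_members(groups) |> filter(.data$size > 1L)
  if (nrow(members) == 0L) {
    warn("no repeated clonotypes; returning an empty table")
    out <- tibble(group_id = character(), paired_identifier = character(),
                  n_cells = integer())
    attr(out, "cluster_sizes") <- table(labels$cluster)
    class(out) <- c("clonotype_cluster_table", class(out))
    return(out)
  }
  joined <- left_join(members, labels, by = "cell_id")
  if (anyNA(joined$cluster)) {
    warn(sprintf("%d member cell(s) lack cluster labels and were dropped",
                 sum(is.na(joined$cluster))))
    joined <- filter(joined, !is.na(.data$cluster))
  }
  clusters <- sort(unique(labels$cluster))
  out <- joined |>
    count(.data$group_id, .data$paired_identifier, .data$cluster) |>
    mutate(cluster = factor(.data$cluster, levels = clusters)) |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "n",
                       names_prefix = "cluster_", values_fill = 0L,
                       names_expand = TRUE) |>
    mutate(n_cells = rowSums(across(starts_with("cluster_")))) |>
    arrange(desc(.data$n_cells), .data$group_id)
  attr(out, "cluster_sizes") <- stats::setNames(
    as.integer(table(factor(labels$cluster, levels = clusters))),
    as.character(clusters)
  )
  class(out) <- c("clonotype_cluster_table", class(out))
  out
}

#' Summarise clonotype sharing between the TFH-like and TR1-like clusters
#'
#' Classifies every repeated clonotype by its membership in clusters 1 and 2:
#' shared by both, only cluster 1, or only cluster 2. Clonotypes with no cell
#' in either cluster are excluded and counted in the `n_excluded` attribute.
#'
#' @param table A [clonotype_cluster_table()] result.
#' @param cluster_a,cluster_b The two clusters compared (defaults 1 and 2).
#' @return Tibble of class `sharing_summary`: `category` (`"shared"`,
#'   `"only_1"`, `"only_2"`), `n_clonotypes`, `n_cells` (all labelled cells of
#'   those clonotypes) and `fraction` (over the three categories).
#' @export
sharing_summary <- function(table, cluster_a = 1L, cluster_b = 2L) {
  col_a <- paste0("cluster_", cluster_a)
  col_b <- paste0("cluster_", cluster_b)
  assert_that(all(c(col_a, col_b) %in% names(table)),
              "table lacks the requested cluster columns",
              class = "tr1kit_input_error")
  classified <- as_tibble(table) |>
    mutate(category = case_when(
      .data[[col_a]] > 0L & .data[[col_b]] > 0L ~ "shared",
      .data[[col_a]] > 0L ~ paste0("only_", cluster_a),
      .data[[col_b]] > 0L ~ paste0("only_", cluster_b),
      TRUE ~ NA_character_
    ))
  n_excluded <- sum(is.na(classified$category))
  classified <- filter(classified, !is.na(.data$category))
  cats <- c("shared", paste0("only_", cluster_a), paste0("only_", cluster_b))
  out <- classified |>
    mutate(category = factor(.data$category, levels = cats)) |>
    group_by(.data$category, .drop = FALSE) |>
    summarise(n_clonotypes = n(), n_cells = sum(.data$n_cells), .groups = "drop") |>
    mutate(fraction = if (sum(.data$n_clonotypes) > 0)
      .data$n_clonotypes / sum(.data$n_clonotypes) else 0)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("sharing_summary", class(out))
  out
}

#' Test whether clonotype cluster splits parallel cluster sizes
#'
#' For each repeated clonotype with cells in cluster `cluster_a` or
#' `cluster_b`, a two-sided exact binomial test of its split against the null
#' proportion `size_b / (size_a + size_b)` given by the overall cluster sizes
#' (cells in other clusters are excluded from the null). The summary fraction
#' of clonotypes with `p >= alpha` quantifies how broadly the repertoire is
#' consistent with proportional allocation.
#'
#' @param table A [clonotype_cluster_table()] result.
#' @param cluster_sizes Named vector of total cells per cluster; defaults to
#'   the attribute recorded by [clonotype_cluster_table()].
#' @param cluster_a,cluster_b Clusters compared (defaults 1 and 2).
#' @param alpha Consistency threshold (default 0.05).
#' @return Tibble of class `tr1_proportionality` (`group_id`, `n_a`, `n_b`,
#'   `p_value`, `consistent`); [glance()] reports `n_clonotypes`,
#'   `fraction_consistent` and the null proportion.
#' @export
proportionality_check <- function(table, cluster_sizes = NULL,
                                  cluster_a = 1L, cluster_b = 2L, alpha = 0.05) {
  cluster_sizes <- cluster_sizes %||% attr(table, "cluster_sizes")
  assert_that(!is.null(cluster_sizes), "cluster_sizes required",
              class = "tr1kit_input_error")
  size_a <- cluster_sizes[[as.character(cluster_a)]]
  size_b <- cluster_sizes[[as.character(cluster_b)]]
  assert_that(size_a > 0 && size_b > 0, "both cluster sizes must be positive",
              class = "tr1kit_input_error")
  p_null <- size_b / (size_a + size_b)

  col_a <- paste0("cluster_", cluster_a)
  col_b <- paste0("cluster_", cluster_b)
  rows <- as_tibble(table) |>
    filter(.data[[col_a]] + .data[[col_b]] > 0L)
  out <- rows |>
    mutate(
      n_a = .data[[col_a]], n_b = .data[[col_b]],
      p_value = map_dbl(row_number(), function(i) {
        stats::binom.test(rows[[col_b]][i], rows[[col_a]][i] + rows[[col_b]][i],
                          p = p_null)$p.value
      }),
      consistent = .data$p_value >= alpha
    ) |>
    select("group_id", "n_a", "n_b", "p_value", "consistent")
  attr(out, "p_null") <- p_null
  attr(out, "alpha") <- alpha
  class(out) <- c("tr1_proportionality", class(out))
  out
}

#' @export
glance.tr1_proportionality <- function(x, ...) {
  tibble(
    n_clonotypes = nrow(x),
    fraction_consistent = if (nrow(x) > 0) mean(x$consistent) else NA_real_,
    p_null = attr(x, "p_null"),
    alpha = attr(x, "alpha")
  )
}
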