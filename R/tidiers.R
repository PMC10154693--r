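#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.tr1_de <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.tr1_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log_fc > 0),
    n_down = sum(x$significant & x$log_fc < 0),
    n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
    lfc_threshold = attr(x, "lfc_threshold"),
    alpha = attr(x, "alpha")
  )
}

#' @export
tidy.tr1_concordance <- function(x, ...) as_tibble(x)

#' @export
glance.tr1_concordance <- function(x, ...) as_tibble(x)

#' @export
tidy.sharing_summary <- function(x, ...) as_tibble(x)

#' @export
glance.sharing_summary <- function(x, ...) {
  tibble(
    n_clonotypes = sum(x$n_clonotypes),
    n_cells = sum(x$n_cells),
    shared_fraction = x$fraction[x$category == "shared"],
    n_excluded = attr(x, "n_excluded") %||% 0L
  )
}

#' @export
tidy.signature_overlap <- function(x, ...) x$percentages

#' @export
glance.signature_overlap <- function(x, ...) {
  if (is.null(x$test)) return(tibble(p_value = NA_real_, method = NA_character_))
  x$test
}

#' @export
tidy.usage_table <- function(x, ...) as_tibble(x)
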