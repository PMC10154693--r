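#' Luciferase stimulation index
#'
#' Relative luminescence of a stimulated sample, first normalised to the
#' unstimulated reading of the same reporter line and then to the equally
#' normalised negative-control condition:
#' `SI = (rlu_sample / rlu_unstim) / (rlu_negctrl / rlu_negctrl_unstim)`.
#' The negative-control condition itself therefore has SI 1 by construction,
#' and the index is invariant to rescaling all four readings.
#'
#' @param rlu_sample,rlu_unstim,rlu_negctrl,rlu_negctrl_unstim Positive
#'   relative luminescence readings (vectorised).
#' @return Numeric stimulation index (dimensionless, >= 0).
#'
#' @examples
#' stimulation_index(2000, 100, 200, 100)  # 10
#' @export
stimulation_index <- function(rlu_sample, rlu_unstim, rlu_negctrl, rlu_negctrl_unstim) {
  vals <- c(rlu_sample, rlu_unstim, rlu_negctrl, rlu_negctrl_unstim)
  assert_that(all(is.finite(vals)) && all(vals > 0),
              "all RLU readings must be positive", class = "tr1kit_input_error")
  (rlu_sample / rlu_unstim) / (rlu_negctrl / rlu_negctrl_unstim)
}

#' Binary reactivity pattern of TCR reporter lines against pMHCIIs
#'
#' Thresholds a complete stimulation-index table into binary agonist calls
#' (`SI >= threshold`) and reports, per TCR line, the set of pMHCIIs it
#' reacts to.
#'
#' @param si_table Tibble with columns `tcr_line`, `pmhc`, `si`; every
#'   (line, pMHCII) combination must be present and non-missing.
#' @param threshold Agonist threshold on the stimulation index (default 3).
#' @return List of class `reactivity_table`: `table` (the input plus
#'   `reactive`) and `report` (per line: `n_reactive`, list-column
#'   `reactive_pmhc`); the threshold is kept as an attribute.
#' @export
reactivity_pattern <- function(si_table, threshold = 3) {
  si_table <- as_tibble(si_table)
  assert_that(all(c("tcr_line", "pmhc", "si") %in% names(si_table)),
              "si_table needs columns tcr_line, pmhc, si",
              class = "tr1kit_input_error")
  assert_that(!anyNA(si_table$si), "si_table has missing entries",
              class = "tr1kit_input_error")
  full <- tidyr::crossing(tcr_line = unique(si_table$tcr_line),
                          pmhc = unique(si_table$pmhc))
  assert_that(nrow(anti_join(full, si_table, by = c("tcr_line", "pmhc"))) == 0,
              "si_table is not a complete line x pMHCII grid",
              class = "tr1kit_input_error")

  tab <- si_table |> mutate(reactive = .data$si >= threshold)
  report <- tab |>
    group_by(.data$tcr_line) |>
    summarise(
      n_reactive = sum(.data$reactive),
      reactive_pmhc = list(sort(.data$pmhc[.data$reactive])),
      .groups = "drop"
    )
  structure(list(table = tab, report = report, threshold = threshold),
            class = "reactivity_table")
}

#' @export
print.reactivity_table <- function(x, ...) {
  cat("<reactivity_table> threshold SI >=", x$threshold, "\n")
  print(x$report)
  invisible(x)
}
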