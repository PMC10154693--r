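#' Build a recombinome of all V x J combinations
#'
#' Concatenates every V segment with every J segment of the same chain,
#' separated by a run of `N` spacer bases, producing the synthetic reference
#' ("recombinome") that TCR contigs are aligned against. The spacer absorbs
#' junctional insertions of any length up to its own, so a contig spanning the
#' junction can align its V and J portions to one entry.
#'
#' @param germline Germline segment tibble (columns `name`, `chain`,
#'   `segment_class`, `sequence`).
#' @param spacer_len Number of `N` bases between V and J (default 50, the
#'   junction-length cap of the emulated assembler).
#'
#' @return Tibble of class `recombinome` with columns `entry_id`
#'   (`"Vname|Jname"`), `chain`, `v_name`, `j_name`, `sequence`, `v_end` and
#'   `j_start` (0-based half-open offsets of the V end and J start within the
#'   entry); the spacer length is kept in attribute `spacer_len`.
#'
#' @examples
#' germ <- generate_germline_reference(2, 2, 1, 1, seed = 1)
#' build_recombinome(germ, spacer_len = 10)
#' @export
build_recombinome <- function(germline, spacer_len = 50L) {
  validate_germline(germline)
  assert_that(spacer_len >= 0, "spacer_len must be non-negative")

  per_chain <- function(ch) {
    v <- filter(germline, .data$chain == ch, .data$segment_class == "V")
    j <- filter(germline, .data$chain == ch, .data$segment_class == "J")
    if (nrow(v) == 0L && nrow(j) == 0L) return(NULL)
    assert_that(nrow(v) > 0L && nrow(j) > 0L,
                paste0("chain '", ch, "' needs at least one V and one J segment"),
                class = "tr1kit_config_error")
    tidyr::crossing(
      v |> select(v_name = "name", v_seq = "sequence"),
      j |> select(j_name = "name", j_seq = "sequence")
    ) |>
      mutate(
        chain = ch,
        entry_id = paste(.data$v_name, .data$j_name, sep = "|"),
        sequence = paste0(.data$v_seq, strrep("N", spacer_len), .data$j_seq),
        v_end = nchar(.data$v_seq),
        j_start = nchar(.data$v_seq) + spacer_len
      ) |>
      select("entry_id", "chain", "v_name", "j_name", "sequence", "v_end", "j_start")
  }

  out <- bind_rows(per_chain("alpha"), per_chain("beta"))
  assert_that(nrow(out) > 0, "germline contained no usable chain",
              class = "tr1kit_config_error")
  attr(out, "spacer_len") <- as.integer(spacer_len)
  class(out) <- c("recombinome", class(out))
  out
}

#' Write recombinome entries as FASTA for inspection
#'
#' @param recombinome A [build_recombinome()] result.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_recombinome_fasta <- function(recombinome, path) {
  write_fasta(tibble(id = recombinome$entry_id, sequence = recombinome$sequence), path)
}
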