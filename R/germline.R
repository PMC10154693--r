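#' Generate a synthetic germline V/J segment reference
#'
#' Builds a randomised but structurally faithful set of TCR germline segments
#' for both chains: V segments are open reading frames ending in the conserved
#' cysteine codon (`TGT`/`TGC`) that anchors the CDR3, and J segments carry the
#' conserved phenylalanine/tryptophan codon followed by in-frame downstream
#' sequence. Segment names follow mouse IMGT nomenclature and always include
#' the elements whose usage is skewed in insulin-register-specific repertoires
#' (`TRAV5D-4`, `TRAJ18`, `TRBV1`), so downstream usage summaries can refer to
#' them by name.
#'
#' @param n_v_alpha,n_j_alpha,n_v_beta,n_j_beta Number of segments per
#'   (chain, class); all must be >= 1.
#' @param seed Integer seed; the reference is a pure function of the arguments.
#'
#' @return A tibble with columns `name`, `chain` (`"alpha"`/`"beta"`),
#'   `segment_class` (`"V"`/`"J"`) and `sequence`.
#'
#' @examples
#' germ <- generate_germline_reference(4, 3, 4, 3, seed = 1)
#' dplyr::count(germ, chain, segment_class)
#' @export
generate_germline_reference <- function(n_v_alpha, n_j_alpha, n_v_beta, n_j_beta,
                                        seed = 1L) {
  counts <- c(n_v_alpha, n_j_alpha, n_v_beta, n_j_beta)
  assert_that(all(is.finite(counts)) && all(counts >= 1),
              "all segment counts must be positive integers")

  segment_names <- function(class, chain, n) {
    lead <- switch(paste(chain, class),
      "alpha V" = "TRAV5D-4", "alpha J" = "TRAJ18",
      "beta V"  = "TRBV1",    "beta J"  = "TRBJ2-1"
    )
    prefix <- paste0("TR", if (chain == "alpha") "A" else "B", class)
    c(lead, sprintf("%s%d", prefix, seq_len(max(n - 1L, 0L)) + 1L))[seq_len(n)]
  }

  make_v <- function() {
    # body of sense codons, terminal conserved Cys codon, frame starts at nt 1;
    # kept longer than the recombinome spacer so a V match always out-scores
    # sliding the V into the spacer
    n_codons <- sample(20:31, 1L)
    paste0(paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = ""),
           sample(c("TGT", "TGC"), 1L))
  }
  make_j <- function() {
    # two sense codons (excluding F/W so the conserved codon is the first
    # anchor), the conserved F/W codon, then the in-frame remainder of the
    # exon at realistic length (J exons run ~55-60 nt)
    paste0(
      paste(sample(setdiff(SENSE_CODONS, c("TTT", "TTC", "TGG")), 2L,
                   replace = TRUE), collapse = ""),
      sample(c("TTT", "TTC", "TGG"), 1L),
      paste(sample(SENSE_CODONS, sample(15:17, 1L), replace = TRUE), collapse = "")
    )
  }

  with_seed(seed, {
    spec <- tibble(
      chain = rep(c("alpha", "alpha", "beta", "beta"), counts),
      segment_class = rep(c("V", "J", "V", "J"), counts)
    )
    seqs <- character(nrow(spec))
    repeat {
      todo <- which(seqs == "" | duplicated(seqs))
      if (length(todo) == 0L) break
      seqs[todo] <- vapply(
        spec$segment_class[todo],
        function(cl) if (cl == "V") make_v() else make_j(),
        character(1)
      )
    }
    spec |>
      mutate(
        name = c(
          segment_names("V", "alpha", counts[1]), segment_names("J", "alpha", counts[2]),
          segment_names("V", "beta", counts[3]), segment_names("J", "beta", counts[4])
        ),
        sequence = seqs
      ) |>
      select(name, chain, segment_class, sequence)
  })
}

validate_germline <- function(germline) {
  assert_that(is.data.frame(germline) && nrow(germline) > 0,
              "germline reference must be a non-empty data frame",
              class = "tr1kit_config_error")
  needed <- c("name", "chain", "segment_class", "sequence")
  assert_that(all(needed %in% names(germline)),
              paste("germline reference needs columns:", paste(needed, collapse = ", ")),
              class = "tr1kit_config_error")
  invisible(germline)
}
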