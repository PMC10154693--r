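#' Default alignment scoring for recombinome assignment
#'
#' Semi-global scoring: the contig aligns globally, the recombinome entry has
#' free ends. Matches score +1, mismatches -1; a gap of length L costs
#' `gap_open + L * gap_extend`. The spacer base `N` is neutral (0 against
#' anything), so junctional insertions align across the spacer at no cost
#' beyond the unconsumed spacer positions.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (costs are
#'   given as positive numbers).
#' @return A named list.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  assert_that(match > 0 && mismatch <= 0 && gap_open >= 0 && gap_extend >= 0,
              "scoring must have positive match, non-positive mismatch, non-negative gap costs")
  list(match = match, mismatch = mismatch, gap_open = gap_open, gap_extend = gap_extend)
}

substitution_matrix <- function(scoring) {
  letters <- c(DNA_BASES, "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- scoring$match
  mat["N", ] <- 0
  mat[, "N"] <- 0
  mat
}

# Score a set of contigs against one entry (vectorised over contigs).
score_against <- function(contig_set, entry_seq, mat, scoring) {
  Biostrings::pairwiseAlignment(
    pattern = contig_set, subject = entry_seq, type = "global-local",
    substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    scoreOnly = TRUE
  )
}

# Map contig coordinates of the V and J matches out of one full alignment.
alignment_intervals <- function(aln, v_end, j_start) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # global-local: aligned strings cover the matched subject substring only
  s_off <- Biostrings::start(Biostrings::subject(aln)) - 1L
  p_pos <- cumsum(p != "-")                 # 1-based contig position per column
  s_pos <- s_off + cumsum(s != "-")         # 1-based entry position per column
  both <- p != "-" & s != "-"
  v_cols <- both & s_pos <= v_end
  j_cols <- both & s_pos > j_start
  list(
    v_start = if (any(v_cols)) min(p_pos[v_cols]) - 1L else NA_integer_,
    v_end   = if (any(v_cols)) max(p_pos[v_cols]) else NA_integer_,
    j_start = if (any(j_cols)) min(p_pos[j_cols]) - 1L else NA_integer_,
    j_end   = if (any(j_cols)) max(p_pos[j_cols]) else NA_integer_
  )
}

#' Assign V and J segments to TCR contigs by recombinome alignment
#'
#' Aligns each contig (and its reverse complement, keeping the better
#' orientation) against every recombinome entry of its chain, semi-globally
#' (contig global, entry free-ended), and reports the best-scoring entry's V
#' and J with match intervals in contig coordinates (0-based, half-open).
#' Ties are broken by the longer V match, then the lexicographically smallest
#' entry id. An assignment with best score below `min_score` is flagged
#' `passed = FALSE`.
#'
#' @param contigs A tibble with columns `contig_id`, `sequence` and optionally
#'   `chain` (restricting candidate entries) and `cell_id`; or a character
#'   vector of sequences.
#' @param recombinome A [build_recombinome()] result.
#' @param scoring An [alignment_scoring()] list.
#' @param min_score Minimum alignment score to accept an assignment.
#'
#' @return A tibble with one row per contig: `contig_id`, `chain`, `v_name`,
#'   `j_name`, `score`, `strand` (`"+"`/`"-"`), `v_start`, `v_end`,
#'   `j_start`, `j_end` (contig coordinates) and `passed`.
#'
#' @examples
#' germ <- generate_germline_reference(2, 2, 2, 2, seed = 1)
#' rec <- build_recombinome(germ, spacer_len = 20)
#' v <- germ$sequence[germ$name == "TRAV5D-4"]
#' j <- germ$sequence[germ$name == "TRAJ18"]
#' assign_segments(paste0(v, "GGCAGCGAT", j), rec)
#' @export
assign_segments <- function(contigs, recombinome,
                            scoring = alignment_scoring(), min_score = 10) {
  if (is.character(contigs)) {
    contigs <- tibble(
      contig_id = names(contigs) %||% paste0("contig", seq_along(contigs)),
      sequence = unname(contigs)
    )
  }
  contigs <- as_tibble(contigs)
  assert_that(nrow(contigs) > 0 && all(nzchar(contigs$sequence)),
              "contigs must be non-empty sequences", class = "tr1kit_input_error")
  assert_that(all(grepl("^[ACGTN]+$", toupper(contigs$sequence))),
              "contig alphabet must be A/C/G/T/N", class = "tr1kit_input_error")
  if (!"chain" %in% names(contigs)) contigs$chain <- NA_character_
  contigs$sequence <- toupper(contigs$sequence)

  mat <- substitution_matrix(scoring)
  out <- vector("list", length(unique(contigs$chain)))

  for (ch in unique(contigs$chain)) {
    idx <- which(if (is.na(ch)) is.na(contigs$chain) else contigs$chain %in% ch)
    entries <- if (is.na(ch)) recombinome else filter(recombinome, .data$chain == ch)
    assert_that(nrow(entries) > 0, paste("no recombinome entries for chain", ch),
                class = "tr1kit_config_error")
    fwd <- Biostrings::DNAStringSet(contigs$sequence[idx])
    rev <- Biostrings::reverseComplement(fwd)

    # score every contig against every entry, both orientations
    scores <- array(NA_real_, dim = c(length(idx), nrow(entries), 2L))
    for (e in seq_len(nrow(entries))) {
      scores[, e, 1L] <- score_against(fwd, entries$sequence[e], mat, scoring)
      scores[, e, 2L] <- score_against(rev, entries$sequence[e], mat, scoring)
    }

    rows <- purrr::map(seq_along(idx), function(i) {
      sc <- matrix(scores[i, , ], ncol = 2L)
      best <- max(sc)
      cand <- which(sc == best, arr.ind = TRUE)
      # resolve ties: longest V match, then smallest entry_id
      pick <- NULL
      for (k in seq_len(nrow(cand))) {
        e <- cand[k, 1L]; o <- cand[k, 2L]
        seq_k <- if (o == 1L) fwd[i] else rev[i]
        aln <- Biostrings::pairwiseAlignment(
          pattern = seq_k, subject = entries$sequence[e], type = "global-local",
          substitutionMatrix = mat,
          gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
        )
        iv <- alignment_intervals(aln, entries$v_end[e], entries$j_start[e])
        v_len <- if (is.na(iv$v_start)) 0L else iv$v_end - iv$v_start
        cand_row <- list(entry = e, orient = o, iv = iv, v_len = v_len,
                         entry_id = entries$entry_id[e])
        if (is.null(pick) || cand_row$v_len > pick$v_len ||
            (cand_row$v_len == pick$v_len && cand_row$entry_id < pick$entry_id)) {
          pick <- cand_row
        }
      }
      e <- pick$entry
      ok <- best >= min_score && !is.na(pick$iv$v_start) && !is.na(pick$iv$j_start) &&
        pick$iv$v_end <= pick$iv$j_start
      tibble(
        contig_id = contigs$contig_id[idx[i]],
        chain = entries$chain[e],
        v_name = entries$v_name[e], j_name = entries$j_name[e],
        score = best, strand = if (pick$orient == 1L) "+" else "-",
        v_start = pick$iv$v_start, v_end = pick$iv$v_end,
        j_start = pick$iv$j_start, j_end = pick$iv$j_end,
        passed = ok
      )
    })
    out[[match(ch, unique(contigs$chain))]] <- bind_rows(rows)
  }

  res <- bind_rows(out)
  res[match(contigs$contig_id, res$contig_id), ]
}

#' Extract the junctional nucleotide sequence
#'
#' Returns the contig bases between the end of the V match and the start of
#' the J match (`[v_end, j_start)`, 0-based half-open); the empty string when
#' the matches abut. The contig must be supplied in the orientation the
#' assignment was made on (`strand == "-"` assignments are reverse-complemented
#' internally).
#'
#' @param contig Contig nucleotide sequence (single string).
#' @param assignment One-row tibble from [assign_segments()] with
#'   `passed = TRUE`.
#' @return The junction nucleotide string.
#' @export
extract_junction <- function(contig, assignment) {
  assert_that(nrow(assignment) == 1L && isTRUE(assignment$passed),
              "junction extraction requires a passed assignment",
              class = "tr1kit_state_error")
  seq <- toupper(contig)
  if (assignment$strand == "-") seq <- revcomp(seq)
  if (assignment$j_start <= assignment$v_end) return("")
  substr(seq, assignment$v_end + 1L, assignment$j_start)
}

#' Translate the CDR3 of an assigned contig
#'
#' The CDR3 runs from the conserved V-terminal cysteine codon (the last codon
#' of the matched V segment; reading frame fixed by the V) through the first
#' phenylalanine/tryptophan codon inside the J match. A stop codon in the
#' span, a frame that runs off the contig, or a missing F/W anchor makes the
#' chain unproductive.
#'
#' @param contig Contig nucleotide sequence (single string).
#' @param assignment One-row tibble from [assign_segments()] with
#'   `passed = TRUE`.
#' @return A list with `cdr3_aa` (amino-acid string, `NA` if unproductive)
#'   and `productive` (logical).
#' @export
translate_cdr3 <- function(contig, assignment) {
  assert_that(nrow(assignment) == 1L && isTRUE(assignment$passed),
              "CDR3 translation requires a passed assignment",
              class = "tr1kit_state_error")
  seq <- toupper(contig)
  if (assignment$strand == "-") seq <- revcomp(seq)
  v_end <- assignment$v_end
  assert_that(v_end >= 3L, "V match too short to anchor a cysteine codon",
              class = "tr1kit_annotation_error")
  cys <- substr(seq, v_end - 2L, v_end)
  assert_that(cys %in% c("TGT", "TGC"),
              "V segment lacks the conserved cysteine codon anchor",
              class = "tr1kit_annotation_error")

  aa <- character(0)
  pos <- v_end - 2L  # 1-based start of the cysteine codon
  repeat {
    if (pos + 2L > nchar(seq)) return(list(cdr3_aa = NA_character_, productive = FALSE))
    codon <- substr(seq, pos, pos + 2L)
    if (codon %in% STOP_CODONS) return(list(cdr3_aa = NA_character_, productive = FALSE))
    aa <- c(aa, CODON_TABLE[[codon]] %||% "X")
    # the F/W anchor must lie within the J match (codon start past j_start)
    if (codon %in% c("TTT", "TTC", "TGG") && (pos - 1L) >= assignment$j_start) {
      return(list(cdr3_aa = paste(aa, collapse = ""), productive = TRUE))
    }
    if ((pos - 1L) >= assignment$j_end) {
      return(list(cdr3_aa = NA_character_, productive = FALSE))
    }
    pos <- pos + 3L
  }
}
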