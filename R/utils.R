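# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap list_rbind
#' @importFrom stringr str_sub str_length str_split str_detect str_c
#' @importFrom methods as
NULL

# Restore the caller's RNG state on exit so generators are pure in (config, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed), seed >= 0)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_that <- function(cond, msg, class = "tr1kit_parameter_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
  invisible(TRUE)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Non-stop sense codons, used when a generated reading frame must stay open.
SENSE_CODONS <- {
  all64 <- as.vector(outer(
    as.vector(outer(DNA_BASES, DNA_BASES, paste0)), DNA_BASES, paste0
  ))
  setdiff(all64, STOP_CODONS)
}

# Standard genetic code, written out so translation does not depend on the
# alignment stack it is tested against.
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

AA_ALPHABET <- sort(unique(CODON_TABLE[CODON_TABLE != "*"]))

translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

codons_of <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
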