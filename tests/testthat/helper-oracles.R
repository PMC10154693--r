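# Independent oracles and fixture builders shared across tests.

# Affine-gap semi-global alignment score (pattern global, subject free-ended),
# written as a plain Gotoh recursion independent of the alignment stack the
# package uses. 'N' on either side scores 0; a gap of length L costs
# open + L * ext.
oracle_align_score <- function(pattern, subject, match = 1, mismatch = -1,
                               open = 2, ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(p); m <- length(s)
  neg <- -1e9

  m_prev <- rep(0, m + 1)        # M[0, j] = 0: free subject prefix
  x_prev <- rep(neg, m + 1)
  y_prev <- rep(neg, m + 1)
  best_final <- neg

  for (i in seq_len(n)) {
    sub_scores <- ifelse(p[i] == "N" | s == "N", 0,
                         ifelse(p[i] == s, match, mismatch))
    m_cur <- c(neg, pmax(m_prev[-(m + 1)], x_prev[-(m + 1)], y_prev[-(m + 1)]) +
                 sub_scores)
    x_cur <- pmax(m_prev - open - ext, x_prev - ext, y_prev - open - ext)
    # Y via cummax: Y[j] = max_{k<j} (max(M,X,Y-from-M)[k] + ext*k) - open - ext*j
    h <- pmax(m_cur, x_cur)
    idx <- 0:m
    y_cur <- c(neg, cummax(h[-(m + 1)] + ext * idx[-(m + 1)])) - open - ext * idx
    y_cur[1] <- neg
    m_prev <- m_cur; x_prev <- x_cur; y_prev <- y_cur
  }
  max(m_prev, x_prev)            # free subject suffix
}

# Best (v_name, j_name) per contig under exhaustive oracle scoring.
oracle_assign <- function(contig, recombinome) {
  scores <- vapply(recombinome$sequence, function(s) oracle_align_score(contig, s),
                   numeric(1), USE.NAMES = FALSE)
  best <- which.max(scores)
  list(v_name = recombinome$v_name[best], j_name = recombinome$j_name[best],
       score = scores[best],
       ties = sum(scores == scores[best]) > 1L)
}

# Small cached germline used by many alignment/clonotype tests.
test_germline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_germline_reference(3, 2, 3, 2, seed = 101)
    cache
  }
})

# A hand-built germline with fully known sequences, for boundary arithmetic.
fixed_germline <- function() {
  v60 <- paste0(strrep("GCT", 19), "TGT")              # 60 nt, ends in Cys
  j20 <- paste0("GAC", "ACA", "TTT", strrep("GGA", 3), "AC")  # 20 nt, F codon
  tibble::tibble(
    name = c("TRAV5D-4", "TRAJ18", "TRBV1", "TRBJ2-1"),
    chain = c("alpha", "alpha", "beta", "beta"),
    segment_class = c("V", "J", "V", "J"),
    sequence = c(v60, j20, v60, j20)
  )
}

# Translation oracle via Biostrings, independent of the package codon table.
oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L * 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n))))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
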