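#' Read and write FASTA
#'
#' Sequences are uppercased on read. `read_contig_fasta()` additionally parses
#' the `cellID|chain|index` header convention used for per-cell TCR contigs.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble (`id`, `sequence`); `read_contig_fasta()`:
#'   tibble (`contig_id`, `cell_id`, `chain`, `contig_index`, `sequence`).
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path),
              class = "tr1kit_io_error")
  set <- Biostrings::readDNAStringSet(path)
  tibble(id = names(set), sequence = unname(toupper(as.character(set))))
}

#' @rdname read_fasta
#' @param records Tibble with columns `id` and `sequence`.
#' @export
write_fasta <- function(records, path) {
  records <- as_tibble(records)
  assert_that(all(c("id", "sequence") %in% names(records)),
              "records need columns id and sequence", class = "tr1kit_input_error")
  set <- Biostrings::DNAStringSet(toupper(records$sequence))
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_contig_fasta <- function(path) {
  recs <- read_fasta(path)
  parts <- str_split(recs$id, stringr::fixed("|"))
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed contig header '%s' (record %d): expected cellID|chain|index",
                  recs$id[bad[1]], bad[1]),
          class = "tr1kit_parse_error")
  }
  recs |>
    mutate(
      contig_id = .data$id,
      cell_id = map_chr(parts, 1L),
      chain = map_chr(parts, 2L),
      contig_index = as.integer(map_chr(parts, 3L))
    ) |>
    select("contig_id", "cell_id", "chain", "contig_index", "sequence")
}

#' Read and write gene-by-cell count matrices (Matrix Market)
#'
#' The `.mtx` file stores the sparse coordinate matrix (1-based indices,
#' duplicate entries summed per the standard); `genes.tsv` and `barcodes.tsv`
#' carry the row and column names, one per line.
#'
#' @param mtx_path,genes_path,cells_path File paths.
#' @return A `dgCMatrix` with dimnames.
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  for (p in c(mtx_path, genes_path, cells_path)) {
    assert_that(file.exists(p), paste("no such file:", p), class = "tr1kit_io_error")
  }
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) abort(paste("bad Matrix Market file:", conditionMessage(e)),
                                          class = "tr1kit_format_error"))
  m <- methods::as(m, "CsparseMatrix")
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  assert_that(length(genes) == nrow(m),
              sprintf("genes file has %d entries but matrix has %d rows",
                      length(genes), nrow(m)),
              class = "tr1kit_format_error")
  assert_that(length(cells) == ncol(m),
              sprintf("barcodes file has %d entries but matrix has %d columns",
                      length(cells), ncol(m)),
              class = "tr1kit_format_error")
  dimnames(m) <- list(genes, cells)
  m
}

#' @rdname read_counts
#' @param counts Genes x cells matrix (dense or sparse) with dimnames.
#' @export
write_counts <- function(counts, mtx_path, genes_path, cells_path) {
  sp <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                    "CsparseMatrix")
  Matrix::writeMM(sp, mtx_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), cells_path)
  invisible(mtx_path)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              check.names = FALSE, ...))
}

file_manifest <- function(paths, out_path = NULL) {
  manifest <- tibble(
    file = basename(paths),
    bytes = file.size(paths),
    md5 = unname(tools::md5sum(paths))
  )
  if (!is.null(out_path)) {
    jsonlite::write_json(manifest, out_path, dataframe = "rows", pretty = TRUE)
  }
  manifest
}

#' Write a synthetic fixture bundle to disk
#'
#' Serialises a simulated repertoire and expression data set in the pipeline's
#' interchange formats: germline and contig FASTA (contig ids
#' `cellID|chain|index`), cell metadata and truth tables as TSV, counts as
#' Matrix Market plus gene/barcode index files, and a JSON manifest with MD5
#' checksums of every file.
#'
#' @param truth A `repertoire_truth` from [simulate_repertoire()] (or `NULL`).
#' @param expr An `expression_truth` from [simulate_expression()] (or `NULL`).
#' @param out_dir Output directory (created if needed).
#' @return Tibble manifest (`file`, `bytes`, `md5`), invisibly.
#' @export
write_fixture_bundle <- function(truth, expr, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), paste("cannot create directory:", out_dir),
              class = "tr1kit_io_error")
  paths <- character(0)
  add <- function(p) { paths <<- c(paths, p); p }

  if (!is.null(truth)) {
    write_fasta(tibble(id = truth$germline$name, sequence = truth$germline$sequence),
                add(file.path(out_dir, "germline.fasta")))
    contigs <- if (nrow(truth$contigs) > 0) truth$contigs else
      tibble(contig_id = character(), sequence = character())
    write_fasta(tibble(id = contigs$contig_id, sequence = contigs$sequence),
                add(file.path(out_dir, "contigs.fasta")))
    write_tsv_file(truth$cells, add(file.path(out_dir, "cell_metadata.tsv")))
    write_tsv_file(truth$clones, add(file.path(out_dir, "clones.tsv")))
    write_tsv_file(truth$clone_chains, add(file.path(out_dir, "clone_chains.tsv")))
  }
  if (!is.null(expr)) {
    write_counts(expr$counts,
                 add(file.path(out_dir, "counts.mtx")),
                 add(file.path(out_dir, "genes.tsv")),
                 add(file.path(out_dir, "barcodes.tsv")))
    write_tsv_file(expr$cells, add(file.path(out_dir, "expression_cells.tsv")))
    write_tsv_file(expr$genes, add(file.path(out_dir, "expression_genes.tsv")))
  }
  manifest <- file_manifest(paths, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Parse a germline FASTA into a segment table
#'
#' Chain and segment class are inferred from IMGT-style names (`TRAV`/`TRAJ`
#' for alpha V/J, `TRBV`/`TRBJ` for beta V/J).
#'
#' @param path Germline FASTA path.
#' @return Germline tibble (`name`, `chain`, `segment_class`, `sequence`).
#' @export
parse_germline_fasta <- function(path) {
  recs <- read_fasta(path)
  bad <- !grepl("^TR[AB][VJ]", recs$id)
  if (any(bad)) {
    abort(sprintf("cannot infer chain/class from germline name '%s'",
                  recs$id[which(bad)[1]]),
          class = "tr1kit_parse_error")
  }
  recs |>
    mutate(
      name = .data$id,
      chain = ifelse(substr(.data$id, 3L, 3L) == "A", "alpha", "beta"),
      segment_class = substr(.data$id, 4L, 4L)
    ) |>
    select("name", "chain", "segment_class", "sequence")
}
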