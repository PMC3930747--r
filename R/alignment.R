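#' Alignment matrix container
#'
#' A multiple sequence alignment stored as an M x L character matrix of
#' one-letter amino-acid symbols (gap `"-"`), together with a designated
#' query sequence and a map from alignment columns to reference positions
#' in the query's ungapped numbering.
#'
#' @param seqs character matrix (sequences x columns) of one-letter
#'   symbols, or a character vector of equal-length strings.
#' @param ids sequence labels; defaults to rownames or `seq_001`...
#' @param query_id label of the reference (query) sequence.
#' @return An object of class `alignment_matrix` with fields `seqs`,
#'   `ids`, `query_id` and `column_map` (integer per column, `NA` where
#'   the query has a gap).
#' @export
alignment_matrix <- function(seqs, ids = NULL, query_id = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (length(unique(nchar(seqs))) != 1) {
      abort("all sequences must have equal aligned length")
    }
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  seqs <- as.matrix(seqs)
  if (is.null(ids)) ids <- rownames(seqs) %||% sprintf("seq_%03d", seq_len(nrow(seqs)))
  if (length(ids) != nrow(seqs)) abort("one id per sequence required")
  rownames(seqs) <- NULL
  n_norm <- 0
  norm <- .normalise_aa(seqs)
  n_norm <- attr(norm, "n_normalised")
  seqs <- matrix(norm, nrow = nrow(seqs))
  if (is.null(query_id)) query_id <- ids[1]
  if (!query_id %in% ids) abort(sprintf("query '%s' not found in alignment", query_id))
  aln <- structure(
    list(seqs = seqs, ids = ids, query_id = query_id, column_map = NULL),
    class = "alignment_matrix",
    n_normalised = n_norm
  )
  map_columns_to_reference(aln, query_id)
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf(
    "<alignment_matrix> %d sequences x %d columns, query '%s' (%d mapped positions)\n",
    nrow(x$seqs), ncol(x$seqs), x$query_id, sum(!is.na(x$column_map))
  ))
  invisible(x)
}

#' Map alignment columns to reference (query) positions
#'
#' Assigns reference positions 1..K, in order, to the columns where the
#' query sequence has a non-gap symbol; K is the query's ungapped length.
#' All downstream per-position statistics are reported in this numbering.
#'
#' @param aln an [alignment_matrix()].
#' @param query_id label of the query sequence.
#' @return The alignment with an updated `column_map` and `query_id`.
#' @examples
#' aln <- alignment_matrix(c(q = "AC-GT", s = "ACAGT"))
#' aln$column_map # 1 2 NA 3 4
#' @export
map_columns_to_reference <- function(aln, query_id = aln$query_id) {
  if (!query_id %in% aln$ids) {
    abort(sprintf("query '%s' not found in alignment", query_id))
  }
  qrow <- aln$seqs[match(query_id, aln$ids), ]
  cmap <- rep(NA_integer_, length(qrow))
  nz <- which(qrow != .gap_symbol)
  cmap[nz] <- seq_along(nz)
  aln$query_id <- query_id
  aln$column_map <- cmap
  aln
}

#' Read an aligned FASTA file
#'
#' Reads an aligned (equal-length) protein FASTA into an
#' [alignment_matrix()]. Symbols outside the 20 standard amino acids
#' (including the ambiguity codes B, Z, X) are normalised to the gap
#' symbol; the number of normalised cells is recorded in the load report.
#'
#' @param path FASTA file with aligned sequences.
#' @param query_id query label; defaults to the first record.
#' @return An [alignment_matrix()] with a `"load_report"` attribute
#'   (sequence count, column count, normalised-symbol count).
#' @export
read_msa_fasta <- function(path, query_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(sprintf("no sequences found in '%s'", path))
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1) {
    off <- names(aa)[which(w != w[1])[1]]
    abort(sprintf("ragged alignment in '%s': record '%s' has length %d, expected %d",
      path, off, w[which(w != w[1])[1]], w[1]))
  }
  ids <- sub("\\s.*$", "", names(aa))
  mat <- do.call(rbind, strsplit(as.character(aa), ""))
  aln <- alignment_matrix(mat, ids = ids, query_id = query_id %||% ids[1])
  attr(aln, "load_report") <- tibble(
    n_sequences = nrow(aln$seqs), n_columns = ncol(aln$seqs),
    n_normalised_symbols = attr(aln, "n_normalised") %||% 0L
  )
  aln
}

#' Write an alignment to FASTA
#'
#' @param aln an [alignment_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(aln, path) {
  seqs <- apply(aln$seqs, 1, paste, collapse = "")
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- aln$ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## query sequence of an alignment as an ungapped character vector
query_sequence <- function(aln) {
  qrow <- aln$seqs[match(aln$query_id, aln$ids), ]
  qrow[qrow != .gap_symbol]
}
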