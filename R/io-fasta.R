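#' Read protein sequences from a FASTA file
#'
#' Sequences are validated against the 20 canonical one-letter amino-acid
#' codes; anything else (including B, Z, X placeholders) is rejected with the
#' offending position, so downstream distance-statistics lookups never see an
#' unknown type.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id`, `seq`
#'   (the residue string) and `n` (residue count), in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) abort("no FASTA records found")
  ids <- names(set)
  seqs <- unname(as.character(set))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) {
      abort(sprintf("record '%s' has an empty sequence", ids[i]))
    }
    check_residues(strsplit(seqs[i], "")[[1]])
  }
  tibble(id = ids, seq = seqs, n = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()] up to line wrapping.
#'
#' @param records Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::AAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file; rows may contain the gap
#'   symbol `-`.
#' @return A tibble with columns `id` and `seq`; all rows have equal length,
#'   recorded in the `n_cols` attribute.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 2) abort("an alignment needs at least 2 rows")
  ids <- names(set)
  seqs <- unname(as.character(set))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    bad <- ids[widths != widths[1]]
    abort(sprintf(
      "ragged alignment: rows %s differ in length from row '%s'",
      paste(sprintf("'%s'", bad), collapse = ", "), ids[1]
    ))
  }
  for (i in seq_along(seqs)) {
    check_residues(strsplit(seqs[i], "")[[1]], allow_gap = TRUE)
  }
  aln <- tibble(id = ids, seq = seqs)
  attr(aln, "n_cols") <- widths[1]
  aln
}

#' @rdname read_alignment
#' @param alignment Tibble with `id` and `seq` columns (equal-length rows).
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  if (length(unique(nchar(alignment$seq))) != 1) {
    abort("alignment rows must have equal length")
  }
  write_fasta(alignment, path)
}

# alignment as a character matrix (rows = ids, cols = alignment columns)
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seq, ""))
  rownames(m) <- alignment$id
  m
}
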