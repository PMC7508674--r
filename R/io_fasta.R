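#' Read a FASTA file
#'
#' Strict FASTA reader used throughout the package. Sequences are uppercased,
#' the header token before the first whitespace becomes the record id, and
#' record order is preserved. Empty records and duplicate ids are rejected
#' with an error naming the offending record.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return data.frame with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(Biostrings::width(set) == 0L)) {
    bad <- ids[Biostrings::width(set) == 0L][1L]
    stop("empty sequence: ", bad)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate id: ", ids[duplicated(ids)][1L])
  }
  data.frame(id = ids, seq = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a FASTA file (60-column wrapped)
#'
#' @param ids Character vector of record ids.
#' @param seqs Character vector of sequences (same length as `ids`).
#' @param path Output path.
#' @param width Line-wrap width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, width = 60L) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Turn FASTA records into a contig table
#'
#' @param fasta data.frame from [read_fasta()].
#' @param library Library-of-origin tag (e.g. `"rna_random"`,
#'   `"rna_switch"`, `"dna"`).
#' @return data.frame with columns `contig_id`, `bases`, `library`, `length`.
#' @export
as_contigs <- function(fasta, library = NA_character_) {
  stopifnot(all(nchar(fasta$seq) >= 1L))
  data.frame(contig_id = fasta$id, bases = fasta$seq, library = library,
             length = nchar(fasta$seq), row.names = NULL,
             stringsAsFactors = FALSE)
}
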