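#' Read a FASTQ file (4-line records, Sanger Phred+33)
#'
#' Only the Sanger Phred+33 quality encoding is accepted. Mate pairing is
#' inferred from `/1` `/2` id suffixes: both mates of a pair share the
#' `mate_id` key (the id without the suffix).
#'
#' @param path Path to an uncompressed FASTQ file.
#' @param library Optional library tag stored with every read.
#' @return data.frame with columns `read_id`, `bases`, `qual` (Phred+33
#'   string), `mate_id`, `library`.
#' @export
read_fastq <- function(path, library = NA_character_) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ record count not a multiple of 4 in ", path)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(hdr, 1L, 1L) != "@")) {
    stop("malformed FASTQ header (missing '@') at record ",
         which(substr(hdr, 1L, 1L) != "@")[1L])
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch for read ", ids[bad[1L]])
  }
  mate_id <- ifelse(grepl("/[12]$", ids), sub("/[12]$", "", ids),
                    NA_character_)
  data.frame(read_id = ids, bases = seq, qual = qual, mate_id = mate_id,
             library = library, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$bases
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return List of integer vectors (one per string); Phred = ord(char) - 33.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of Phred scores (>= 0).
#' @return Single quality string.
#' @export
phred_string <- function(scores) {
  stopifnot(all(scores >= 0L))
  intToUtf8(as.integer(scores) + 33L)
}
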