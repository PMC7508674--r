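# Quality trimming and exact k-mer DNA subtraction. The subtraction mirrors
# the computational-subtraction step of bulk RNA-virome surveys: every unique
# 30-mer of the DNA library is indexed and any RNA read (or its mate) sharing
# one exact k-mer is excluded before assembly.

#' Trim low-quality read ends
#'
#' Removes the longest prefix and suffix such that the first and last
#' retained bases have quality >= `min_q`. Interior low-quality bases are
#' kept. A read may trim to empty.
#'
#' @param reads data.frame of reads (see [read_fastq()]).
#' @param min_q Phred threshold (default 20).
#' @return The reads with `bases` and `qual` trimmed.
#' @export
trim_read_ends <- function(reads, min_q = 20L) {
  scores <- phred_scores(reads$qual)
  bounds <- vapply(scores, function(q) {
    ok <- which(q >= min_q)
    if (!length(ok)) c(0L, -1L) else c(ok[1L], ok[length(ok)])
  }, integer(2))
  reads$bases <- substr(reads$bases, bounds[1L, ], bounds[2L, ])
  reads$qual <- substr(reads$qual, bounds[1L, ], bounds[2L, ])
  reads
}

# All k-length windows of each sequence, excluding windows with non-ACGT
# characters; returns list(kmer = chr, seq_idx = int).
kmer_windows <- function(seqs, k) {
  n <- nchar(seqs)
  counts <- pmax(n - k + 1L, 0L)
  idx <- rep(seq_along(seqs), counts)
  starts <- unlist(lapply(counts, function(m) seq_len(m)), use.names = FALSE)
  if (!length(starts)) return(list(kmer = character(0), seq_idx = integer(0)))
  km <- substr(rep(seqs, counts), starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", km)
  list(kmer = km[keep], seq_idx = idx[keep])
}

#' Canonicalize k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer
#' and its reverse complement (strand-collapsed), reflecting that cDNA
#' libraries sample both strands.
#'
#' @param kmers Character vector of ACGT k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(kmers)
  rc <- revcomp(kmers)
  pmin(kmers, rc)
}

#' Build an exact k-mer index from DNA reads
#'
#' Collects the canonical form of every N-free length-`k` window of every
#' sequence.
#'
#' @param seqs Character vector of sequences, or a reads data.frame with a
#'   `bases` column.
#' @param k k-mer length (default 30).
#' @param stranded If TRUE, k-mers are indexed as-is (no canonicalization).
#' @param source Library tag recorded on the index.
#' @return List of class `kmer_index` with `k`, `keys` (unique k-mers),
#'   `stranded`, `source`.
#' @export
build_kmer_index <- function(seqs, k = 30L, stranded = FALSE,
                             source = NA_character_) {
  stopifnot(k >= 1L)
  if (is.data.frame(seqs)) seqs <- seqs$bases
  w <- kmer_windows(seqs, k)
  keys <- if (stranded) w$kmer else canonical_kmers(w$kmer)
  structure(list(k = as.integer(k), keys = unique(keys), stranded = stranded,
                 source = source),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k=%d, %d unique %s k-mers (source: %s)\n",
              x$k, length(x$keys),
              if (x$stranded) "stranded" else "canonical", x$source))
  invisible(x)
}

#' Subtract reads matching a DNA k-mer index
#'
#' A read is removed iff any (canonical) k-mer of the read -- or of its mate,
#' for paired data -- is present in the index. Reads shorter than `k` are
#' kept; input order is preserved.
#'
#' @param reads data.frame of RNA reads (see [read_fastq()]); mates are
#'   linked by `mate_id`.
#' @param index A `kmer_index` from [build_kmer_index()].
#' @return List with `kept` (data.frame), `removed_count`,
#'   `removed_fraction`, `removed_ids`.
#' @export
subtract_reads <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  w <- kmer_windows(reads$bases, index$k)
  km <- if (index$stranded) w$kmer else canonical_kmers(w$kmer)
  hit_read <- rep(FALSE, nrow(reads))
  if (length(km)) {
    hits <- km %in% index$keys
    if (any(hits)) {
      hit_read[unique(w$seq_idx[hits])] <- TRUE
    }
  }
  # propagate removal to mates
  key <- ifelse(is.na(reads$mate_id), paste0(".solo.", seq_len(nrow(reads))),
                reads$mate_id)
  pair_hit <- tapply(hit_read, key, any)
  removed <- as.vector(pair_hit[key])
  list(kept = reads[!removed, , drop = FALSE],
       removed_count = sum(removed),
       removed_fraction = if (nrow(reads)) sum(removed) / nrow(reads) else 0,
       removed_ids = reads$read_id[removed])
}
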