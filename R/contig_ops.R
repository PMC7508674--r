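# Contig-set unification by shared 15-mer content, plus the long-ORF screen
# used to look for highly divergent RdRPs.

#' Fraction of a contig's 15-mers shared with a reference index
#'
#' The denominator is the contig's own set of distinct canonical N-free
#' k-mers.
#'
#' @param query_seq Query contig sequence (single string).
#' @param index `kmer_index` built from the reference contig set (k = 15 for
#'   contig unification).
#' @return Shared fraction in `[0, 1]`.
#' @export
shared_kmer_fraction <- function(query_seq, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (nchar(query_seq) < index$k) stop("contig shorter than k")
  w <- kmer_windows(query_seq, index$k)
  km <- unique(if (index$stranded) w$kmer else canonical_kmers(w$kmer))
  if (!length(km)) stop("contig has no N-free k-mers")
  sum(km %in% index$keys) / length(km)
}

#' Unify two contig sets by shared-k-mer exclusion
#'
#' Keeps all of `primary_set` and every contig of `secondary_set` whose
#' shared 15-mer fraction against the primary set is `<= threshold`
#' (exclusion requires strictly greater than the threshold).
#'
#' @param primary_set,secondary_set Contig data.frames (see [as_contigs()]).
#' @param k k-mer length (default 15).
#' @param threshold Exclusion threshold on the shared fraction (default 0.90).
#' @return The unified contig data.frame, with an attribute `decisions`: a
#'   data.frame (contig_id, shared_fraction, excluded) for the secondary set.
#' @export
unify_contig_sets <- function(primary_set, secondary_set, k = 15L,
                              threshold = 0.90) {
  if (is.null(secondary_set) || nrow(secondary_set) == 0L) {
    attr(primary_set, "decisions") <-
      data.frame(contig_id = character(0), shared_fraction = numeric(0),
                 excluded = logical(0))
    return(primary_set)
  }
  if (is.null(primary_set) || nrow(primary_set) == 0L) {
    attr(secondary_set, "decisions") <-
      data.frame(contig_id = secondary_set$contig_id,
                 shared_fraction = 0, excluded = FALSE)
    return(secondary_set)
  }
  idx <- build_kmer_index(primary_set$bases, k = k)
  frac <- vapply(secondary_set$bases, shared_kmer_fraction, numeric(1),
                 index = idx, USE.NAMES = FALSE)
  excluded <- frac > threshold
  out <- rbind(primary_set, secondary_set[!excluded, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "decisions") <- data.frame(
    contig_id = secondary_set$contig_id, shared_fraction = frac,
    excluded = excluded, stringsAsFactors = FALSE)
  out
}

#' Screen long contigs for long open reading frames
#'
#' Translates every contig strictly longer than `min_contig_nt` stop-to-stop
#' in 6 frames (standard code) and reports every stop-free segment strictly
#' longer than `min_orf_aa`.
#'
#' @param contigs Contig data.frame.
#' @param min_contig_nt Contig length cutoff, exclusive (default 1200).
#' @param min_orf_aa ORF length cutoff in aa, exclusive (default 400).
#' @return data.frame (contig_id, frame, orf_start, orf_end, orf_len) with
#'   0-based half-open aa coordinates in the frame translation.
#' @export
screen_long_orfs <- function(contigs, min_contig_nt = 1200L,
                             min_orf_aa = 400L) {
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    if (contigs$length[i] <= min_contig_nt) next
    frames <- six_frame_translate(contigs$bases[i], table_id = "1")
    for (fr in frames) {
      seg <- fr$segments
      long <- seg[seg$end - seg$start > min_orf_aa, , drop = FALSE]
      if (nrow(long)) {
        out[[length(out) + 1L]] <- data.frame(
          contig_id = contigs$contig_id[i], frame = fr$frame,
          orf_start = long$start, orf_end = long$end,
          orf_len = long$end - long$start, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(0), frame = integer(0),
                      orf_start = integer(0), orf_end = integer(0),
                      orf_len = integer(0)))
  }
  do.call(rbind, out)
}
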