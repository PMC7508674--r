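# CRISPR-spacer protospacer matching (90% identity / 90% coverage, both
# inclusive) and per-contig RPKM abundance with distribution summaries.

#' Match CRISPR spacers against contigs
#'
#' Both strands are searched with local alignment. Identity is identical
#' pairs over aligned columns; coverage is the number of aligned spacer
#' positions over the spacer length. A match is reported iff
#' identity >= `min_identity` and coverage >= `min_coverage` (inclusive).
#'
#' @param spacers data.frame with `id` and `seq` (20-75 nt each).
#' @param contigs Contig data.frame.
#' @param min_identity,min_coverage Inclusive thresholds (default 0.90).
#' @param match,mismatch,gap_open,gap_ext Local-alignment scoring.
#' @return data.frame: spacer_id, contig_id, strand, identity,
#'   spacer_coverage, start, end (forward-strand contig span, 0-based
#'   half-open).
#' @export
match_spacers <- function(spacers, contigs, min_identity = 0.90,
                          min_coverage = 0.90, match = 2, mismatch = -3,
                          gap_open = 5, gap_ext = 2) {
  stopifnot(all(nchar(spacers$seq) >= 20L), all(nchar(spacers$seq) <= 75L))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    sp <- spacers$seq[i]
    slen <- nchar(sp)
    for (j in seq_len(nrow(contigs))) {
      for (strand in c("+", "-")) {
        qry <- if (strand == "+") sp else revcomp(sp)
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(qry), Biostrings::DNAString(contigs$bases[j]),
          type = "local", substitutionMatrix = sub_mat,
          gapOpening = gap_open, gapExtension = gap_ext)
        ncols <- nchar(as.character(Biostrings::alignedPattern(pa)))
        if (ncols == 0L) next
        identity <- Biostrings::nmatch(pa) / ncols
        sp_aligned <- Biostrings::width(Biostrings::pattern(pa))
        coverage <- sp_aligned / slen
        if (identity >= min_identity && coverage >= min_coverage) {
          rng <- Biostrings::subject(pa)
          out[[length(out) + 1L]] <- data.frame(
            spacer_id = spacers$id[i], contig_id = contigs$contig_id[j],
            strand = strand, identity = identity,
            spacer_coverage = coverage,
            start = Biostrings::start(rng) - 1L,
            end = Biostrings::end(rng), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(spacer_id = character(0), contig_id = character(0),
                      strand = character(0), identity = numeric(0),
                      spacer_coverage = numeric(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, out)
}

#' Per-contig RPKM abundance
#'
#' RPKM = mapped reads / (contig length in kb) / (total library reads in
#' millions). Each mate counts as one read; unmapped reads contribute only to
#' the library total. When a SAM data.frame is supplied, the covered fraction
#' is the union of aligned reference spans over the contig length.
#'
#' @param mapping Either a SAM data.frame from [read_sam()] or a named
#'   integer vector of mapped-read counts per contig.
#' @param contig_lengths Named vector of contig lengths (nt).
#' @param total_reads Total reads in the library (N); defaults to
#'   `nrow(mapping)` for SAM input.
#' @return data.frame: contig_id, length_nt, mapped_reads, total_reads,
#'   rpkm, fold_over_median, covered_fraction (NA without SAM input). The
#'   median is taken over positive RPKMs.
#' @export
compute_rpkm <- function(mapping, contig_lengths, total_reads = NULL) {
  if (is.data.frame(mapping)) {
    if (is.null(total_reads)) total_reads <- nrow(mapping)
    mapped <- mapping[mapping$mapped, , drop = FALSE]
    unknown <- setdiff(unique(mapped$rname), names(contig_lengths))
    if (length(unknown)) {
      stop("contig in mapping absent from lengths: ", unknown[1])
    }
    counts <- table(factor(mapped$rname, levels = names(contig_lengths)))
    m <- as.integer(counts)
    covered <- vapply(names(contig_lengths), function(cid) {
      rows <- mapped[mapped$rname == cid, , drop = FALSE]
      if (!nrow(rows)) return(0)
      ir <- IRanges::reduce(IRanges::IRanges(start = rows$pos,
                                             width = rows$aligned_len))
      min(sum(IRanges::width(ir)), contig_lengths[cid]) /
        contig_lengths[cid]
    }, numeric(1))
  } else {
    if (is.null(total_reads)) stop("total_reads required for count input")
    unknown <- setdiff(names(mapping), names(contig_lengths))
    if (length(unknown)) {
      stop("contig in mapping absent from lengths: ", unknown[1])
    }
    m <- as.integer(mapping[names(contig_lengths)])
    m[is.na(m)] <- 0L
    covered <- rep(NA_real_, length(contig_lengths))
  }
  stopifnot(total_reads > 0)
  rpkm <- m / (contig_lengths / 1000) / (total_reads / 1e6)
  med <- median(rpkm[rpkm > 0])
  data.frame(contig_id = names(contig_lengths),
             length_nt = as.integer(contig_lengths), mapped_reads = m,
             total_reads = total_reads, rpkm = as.numeric(rpkm),
             fold_over_median = if (is.finite(med) && med > 0)
               as.numeric(rpkm / med) else 0,
             covered_fraction = as.numeric(covered),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a contig-abundance distribution
#'
#' Reports the median of positive RPKMs, the modal peak (center of the
#' highest Freedman-Diaconis bin of log2 RPKM, back-transformed), a
#' log-normal fit (mean and sd of ln RPKM), and the right-skew excess: the
#' observed count above the fit's 99.9th percentile over the expected count.
#'
#' @param records data.frame from [compute_rpkm()] (needs >= 2 positive
#'   RPKMs).
#' @return List: n_positive, median, modal_peak, lognormal_meanlog,
#'   lognormal_sdlog, skew_excess_observed, skew_excess_expected,
#'   skew_excess_ratio, top_fold_over_median (sorted decreasing, first 20).
#' @export
summarize_abundance <- function(records) {
  r <- records$rpkm[records$rpkm > 0]
  if (length(r) < 2L) stop("need at least 2 positive abundance records")
  lx <- log2(r)
  h <- graphics::hist(lx, breaks = "FD", plot = FALSE)
  peak_bin <- which.max(h$counts)
  modal_peak <- 2^h$mids[peak_bin]
  mu <- mean(log(r))
  sigma <- sd(log(r))
  cutoff <- stats::qlnorm(0.999, mu, sigma)
  observed <- sum(r > cutoff)
  expected <- 0.001 * length(r)
  fom <- sort(records$fold_over_median, decreasing = TRUE)
  list(n_positive = length(r), median = median(r), modal_peak = modal_peak,
       lognormal_meanlog = mu, lognormal_sdlog = sigma,
       skew_excess_observed = observed, skew_excess_expected = expected,
       skew_excess_ratio = observed / expected,
       top_fold_over_median = head(fom, 20L))
}
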