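# Six-frame stop-to-stop translation and PSSM-based detection of the RdRP
# core. The scanner performs a local profile-to-sequence alignment with
# affine gaps over every stop-free segment of all six frame translations;
# a hit covering at least 75% of the profile columns is a full-length core.

#' Six-frame end-to-end translation with stop-to-stop segmentation
#'
#' Frames +1..+3 read the forward strand at offsets 0, 1, 2; frames -1..-3
#' read the reverse complement at offsets 0, 1, 2. Trailing 1-2 nt are
#' dropped. Stops are marked `*`; segments are the maximal stop-free runs.
#'
#' @param bases Contig sequence (single string, length >= 3).
#' @param table_id Genetic-code table id (default "1", standard).
#' @return List of 6 elements, each `list(frame, aa, segments)` where
#'   `segments` is a data.frame of 0-based half-open aa spans (`start`,
#'   `end`) in the frame translation.
#' @export
six_frame_translate <- function(bases, table_id = "1") {
  n <- nchar(bases)
  if (n < 3L) stop("contig shorter than 3 nt")
  lapply(c(1L, 2L, 3L, -1L, -2L, -3L), frame_translation, bases = bases,
         table_id = table_id)
}

#' Translate one reading frame with stop-to-stop segmentation
#'
#' @param bases Contig sequence (length >= 3).
#' @param frame One of +1..+3 (forward strand, offsets 0-2) or -1..-3
#'   (reverse complement, offsets 0-2).
#' @param table_id Genetic-code table id.
#' @return `list(frame, aa, segments)` as in [six_frame_translate()].
#' @export
frame_translation <- function(bases, frame, table_id = "1") {
  n <- nchar(bases)
  if (n < 3L) stop("contig shorter than 3 nt")
  code <- Biostrings::getGeneticCode(as.character(table_id))
  strand_seq <- if (frame > 0L) bases else revcomp(bases)
  o <- abs(frame) - 1L
  ncod <- (n - o) %/% 3L
  aa <- if (ncod >= 1L) {
    starts <- o + 1L + 3L * (seq_len(ncod) - 1L)
    res <- unname(code[substring(strand_seq, starts, starts + 2L)])
    res[is.na(res)] <- "X"  # codons containing non-ACGT characters
    paste(res, collapse = "")
  } else ""
  segs <- gregexpr("[^*]+", aa)[[1]]
  segments <- if (length(segs) == 1L && segs[1L] == -1L) {
    data.frame(start = integer(0), end = integer(0))
  } else {
    data.frame(start = as.integer(segs) - 1L,
               end = as.integer(segs) - 1L + attr(segs, "match.length"))
  }
  list(frame = as.integer(frame), aa = aa, segments = segments)
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Column scores are log-odds of observed residue frequency (with a
#' background-proportional pseudocount) against fixed background amino-acid
#' frequencies, in half-bit units. Columns with more than 50% gaps are
#' dropped.
#'
#' @param seqs Character vector of aligned protein sequences (equal lengths,
#'   `-` for gaps), at least 2.
#' @param pseudocount Total pseudocount mass added per column (default 1).
#' @param background Named amino-acid frequency vector (defaults to the
#'   bundled Robinson-Robinson-style frequencies).
#' @param sub_motifs Optional named list of 0-based half-open column spans
#'   (e.g. `list(A = c(80, 88), B = ..., C = ...)`), in original alignment
#'   coordinates, labelling the conserved motifs.
#' @return Object of class `rdrp_profile`: list with `length`, `scores`
#'   (length x 20 matrix, half-bits), `background`, `sub_motifs` (mapped to
#'   kept-column coordinates), `kept_columns`.
#' @export
build_profile <- function(seqs, pseudocount = 1,
                          background = AA_BACKGROUND, sub_motifs = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(seqs))) != 1L) stop("ragged alignment")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap_frac <- colMeans(mat == "-")
  kept <- which(gap_frac <= 0.5)
  if (!length(kept)) stop("no columns left after gap filtering")
  scores <- matrix(0, nrow = length(kept), ncol = 20L,
                   dimnames = list(NULL, AA_ALPHABET))
  for (ci in seq_along(kept)) {
    col <- mat[, kept[ci]]
    col <- col[col %in% AA_ALPHABET]
    ncol_ <- length(col)
    cnt <- table(factor(col, levels = AA_ALPHABET))
    f <- (as.numeric(cnt) + pseudocount * background[AA_ALPHABET]) /
      (ncol_ + pseudocount)
    scores[ci, ] <- 2 * log2(f / background[AA_ALPHABET])
  }
  motifs_kept <- NULL
  if (!is.null(sub_motifs)) {
    colmap <- match(seq_along(gap_frac) - 1L, kept - 1L)
    motifs_kept <- lapply(sub_motifs, function(span) {
      cols <- colmap[(span[1] + 1L):span[2]]
      cols <- cols[!is.na(cols)]
      if (!length(cols)) stop("sub-motif entirely in dropped columns")
      c(min(cols) - 1L, max(cols))
    })
  }
  structure(list(length = length(kept), scores = scores,
                 background = background[AA_ALPHABET],
                 sub_motifs = motifs_kept,
                 kept_columns = kept - 1L),
            class = "rdrp_profile")
}

#' @export
print.rdrp_profile <- function(x, ...) {
  cat(sprintf("RdRP PSSM: %d columns, half-bit log-odds%s\n", x$length,
              if (!is.null(x$sub_motifs))
                paste0(", motifs ", paste(names(x$sub_motifs), collapse = "/"))
              else ""))
  invisible(x)
}

aa_indices <- function(protein) {
  match(strsplit(protein, "")[[1]], AA_ALPHABET) - 1L
}

# Run the affine-gap local profile alignment against one protein string.
# Returns 0-based half-open spans; score in half-bits.
profile_align <- function(profile, protein, gap_open = 11, gap_ext = 1) {
  idx <- aa_indices(protein)
  idx[is.na(idx)] <- -1L
  r <- profile_sw_cpp(profile$scores, idx, gap_open, gap_ext)
  list(score = r$score,
       p_start = r$p_start - 1L, p_end = r$p_end,
       t_start = r$t_start - 1L, t_end = r$t_end)
}

#' Scan a contig for the RdRP core
#'
#' Aligns the profile locally (affine gaps, open 11 / extend 1 in half-bits)
#' against every stop-to-stop segment of all six frame translations. Coverage
#' is the number of profile columns consumed (aligned or deleted) over the
#' profile length; a hit with coverage >= 0.75 is flagged full-length.
#' Reverse-frame hits are mapped back to forward-strand coordinates.
#'
#' @param bases Contig sequence.
#' @param profile `rdrp_profile` object.
#' @param table_id Genetic-code table for translation (default "1").
#' @param contig_id Id recorded in the calls.
#' @param gap_open,gap_ext Affine gap penalties (half-bits).
#' @param min_bits_per_col Reporting threshold in bits per profile column
#'   (default 0.02).
#' @param stop_tolerant If TRUE each frame translation is scanned end-to-end
#'   as a single segment with stops scored like unknown residues, so a call
#'   can span in-frame stop codons (needed to census stop codons inside
#'   cores of alternative-code viruses). Default FALSE: scan stop-free
#'   segments only.
#' @return List with `best` (single-row data.frame or NULL) and `calls`
#'   (data.frame of all calls above threshold). Columns: `contig_id`,
#'   `frame`, `prot_start`, `prot_end` (aa, frame translation, 0-based
#'   half-open), `nt_start`, `nt_end` (forward strand, 0-based half-open),
#'   `score` (half-bits), `coverage`, `cols`, `full_length`.
#' @export
scan_contig <- function(bases, profile, table_id = "1", contig_id = NA,
                        gap_open = 11, gap_ext = 1, min_bits_per_col = 0.02,
                        stop_tolerant = FALSE) {
  stopifnot(inherits(profile, "rdrp_profile"))
  n <- nchar(bases)
  frames <- six_frame_translate(bases, table_id)
  rows <- list()
  for (fr in frames) {
    segs <- if (stop_tolerant && nchar(fr$aa) > 0L) {
      data.frame(start = 0L, end = nchar(fr$aa))
    } else fr$segments
    o <- abs(fr$frame) - 1L
    for (si in seq_len(nrow(segs))) {
      seg_aa <- substr(fr$aa, segs$start[si] + 1L, segs$end[si])
      al <- profile_align(profile, seg_aa, gap_open, gap_ext)
      if (al$score <= 0) next
      prot_start <- segs$start[si] + al$t_start
      prot_end <- segs$start[si] + al$t_end
      if (fr$frame > 0L) {
        nt_start <- o + 3L * prot_start
        nt_end <- o + 3L * prot_end
      } else {
        nt_start <- n - (o + 3L * prot_end)
        nt_end <- n - (o + 3L * prot_start)
      }
      cols <- al$p_end - al$p_start
      rows[[length(rows) + 1L]] <-
        list(fr$frame, prot_start, prot_end, nt_start, nt_end, al$score,
             cols)
    }
  }
  if (!length(rows)) return(list(best = NULL, calls = empty_calls()))
  m <- do.call(rbind, lapply(rows, unlist))
  calls <- data.frame(
    contig_id = contig_id, frame = as.integer(m[, 1]),
    prot_start = as.integer(m[, 2]), prot_end = as.integer(m[, 3]),
    nt_start = as.integer(m[, 4]), nt_end = as.integer(m[, 5]),
    score = m[, 6], coverage = m[, 7] / profile$length,
    cols = as.integer(m[, 7]),
    full_length = m[, 7] / profile$length >= 0.75,
    stringsAsFactors = FALSE)
  best <- calls[which.max(calls$score), , drop = FALSE]
  threshold <- min_bits_per_col * 2 * profile$length
  calls <- calls[calls$score >= threshold, , drop = FALSE]
  rownames(calls) <- NULL
  rownames(best) <- NULL
  list(best = best, calls = calls)
}

empty_calls <- function() {
  data.frame(contig_id = character(0), frame = integer(0),
             prot_start = integer(0), prot_end = integer(0),
             nt_start = integer(0), nt_end = integer(0),
             score = numeric(0), coverage = numeric(0), cols = integer(0),
             full_length = logical(0), stringsAsFactors = FALSE)
}

#' Scan a set of contigs, one best call per contig
#'
#' @param contigs Contig data.frame.
#' @param profile `rdrp_profile`.
#' @param ... Passed to [scan_contig()].
#' @return data.frame of best calls (contigs without a positive-scoring hit
#'   are absent).
#' @export
scan_contigs <- function(contigs, profile, ...) {
  best <- lapply(seq_len(nrow(contigs)), function(i) {
    scan_contig(contigs$bases[i], profile, contig_id = contigs$contig_id[i],
                ...)$best
  })
  best <- best[!vapply(best, is.null, logical(1))]
  if (!length(best)) return(empty_calls())
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out
}

#' Write a PSSM as a TSV file
#'
#' Dialect: comment lines carry the background frequencies and motif spans;
#' then a header row and one row per profile column with 20 score fields.
#'
#' @param profile `rdrp_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rdrp_pssm v1 (half-bit log-odds)", con)
  writeLines(paste0("# background: ",
                    paste(sprintf("%s:%.6f", names(profile$background),
                                  profile$background), collapse = " ")), con)
  if (!is.null(profile$sub_motifs)) {
    writeLines(paste0("# sub_motifs: ",
                      paste(sprintf("%s:%d-%d", names(profile$sub_motifs),
                                    vapply(profile$sub_motifs, `[`, 0L, 1),
                                    vapply(profile$sub_motifs, `[`, 0L, 2)),
                            collapse = " ")), con)
  }
  writeLines(paste(c("column", AA_ALPHABET), collapse = "\t"), con)
  for (i in seq_len(profile$length)) {
    writeLines(paste(c(i - 1L, sprintf("%.6f", profile$scores[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#'
#' @param path Path to the TSV file.
#' @return `rdrp_profile` object.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  bg_line <- meta[grepl("^# background:", meta)]
  if (!length(bg_line)) stop("missing background line")
  bg_pairs <- strsplit(strsplit(sub("^# background: ", "", bg_line), " ")[[1]], ":")
  background <- setNames(as.numeric(vapply(bg_pairs, `[`, "", 2)),
                         vapply(bg_pairs, `[`, "", 1))
  sub_motifs <- NULL
  sm_line <- meta[grepl("^# sub_motifs:", meta)]
  if (length(sm_line)) {
    sm_pairs <- strsplit(strsplit(sub("^# sub_motifs: ", "", sm_line), " ")[[1]], "[:-]")
    sub_motifs <- setNames(
      lapply(sm_pairs, function(p) as.integer(p[2:3])),
      vapply(sm_pairs, `[`, "", 1))
  }
  header <- strsplit(body[1], "\t")[[1]]
  stopifnot(identical(header[-1], AA_ALPHABET))
  rows <- strsplit(body[-1], "\t")
  scores <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  colnames(scores) <- AA_ALPHABET
  structure(list(length = nrow(scores), scores = scores,
                 background = background[AA_ALPHABET],
                 sub_motifs = sub_motifs,
                 kept_columns = seq_len(nrow(scores)) - 1L),
            class = "rdrp_profile")
}
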