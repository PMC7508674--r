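# Detection of permuted RdRPs (motif order C-A-B instead of the canonical
# A-B-C) and restoration of canonical order: the fragment from the start of
# motif C up to (but excluding) motif A is excised and reinserted immediately
# after motif B, realizing the canonical location of the catalytic loop.

# Gapless placements of a motif sub-profile along a protein: score of offset
# o is the sum of the motif's column scores at the aligned residues.
motif_placements <- function(protein, scores) {
  idx <- aa_indices(protein)
  lm <- nrow(scores)
  n <- length(idx)
  if (n < lm) return(data.frame(start = integer(0), score = numeric(0)))
  offs <- 0:(n - lm)
  sc <- vapply(offs, function(o) {
    cols <- idx[(o + 1L):(o + lm)]
    s <- 0
    for (i in seq_len(lm)) {
      s <- s + if (is.na(cols[i])) -4 else scores[i, cols[i] + 1L]
    }
    s
  }, numeric(1))
  data.frame(start = offs, score = sc)
}

motif_score_floor <- function(scores) {
  0.5 * sum(apply(scores, 1L, max))
}

#' Annotate RdRP motifs A, B, C on a protein
#'
#' Each sub-motif of the profile is placed independently (gapless, top-5
#' offsets per motif); the best-scoring non-overlapping triple gives the
#' spans. A motif whose placed score falls below its floor (half the motif's
#' maximum attainable score) yields a "motif not found" annotation. The
#' protein is permuted iff motif C starts before motif A.
#'
#' @param protein Protein string.
#' @param profile `rdrp_profile` with `sub_motifs` spans for A, B, C.
#' @return List with `found` (logical), `positions` (named list of 0-based
#'   half-open spans), `scores` (per-motif), `floors`, `permuted`.
#' @export
annotate_motifs <- function(protein, profile) {
  stopifnot(inherits(profile, "rdrp_profile"), !is.null(profile$sub_motifs))
  motifs <- profile$sub_motifs[c("A", "B", "C")]
  sub_scores <- lapply(motifs, function(span) {
    profile$scores[(span[1] + 1L):span[2], , drop = FALSE]
  })
  floors <- vapply(sub_scores, motif_score_floor, numeric(1))
  lens <- vapply(sub_scores, nrow, integer(1))
  if (nchar(protein) < sum(lens)) {
    return(list(found = FALSE, positions = NULL, scores = NULL,
                floors = floors, permuted = NA))
  }
  cand <- lapply(names(motifs), function(m) {
    pl <- motif_placements(protein, sub_scores[[m]])
    pl <- pl[order(-pl$score, pl$start), , drop = FALSE]
    head(pl, 5L)
  })
  names(cand) <- names(motifs)
  best <- NULL
  best_total <- -Inf
  for (ia in seq_len(nrow(cand$A))) {
    for (ib in seq_len(nrow(cand$B))) {
      for (ic in seq_len(nrow(cand$C))) {
        st <- c(cand$A$start[ia], cand$B$start[ib], cand$C$start[ic])
        en <- st + unname(lens)
        ord <- order(st)
        if (any(en[ord][-3] > st[ord][-1])) next  # overlap
        total <- cand$A$score[ia] + cand$B$score[ib] + cand$C$score[ic]
        if (total > best_total) {
          best_total <- total
          best <- list(st = st, en = en,
                       sc = c(cand$A$score[ia], cand$B$score[ib],
                              cand$C$score[ic]))
        }
      }
    }
  }
  if (is.null(best) || any(best$sc < floors)) {
    return(list(found = FALSE, positions = NULL,
                scores = if (is.null(best)) NULL else
                  setNames(best$sc, c("A", "B", "C")),
                floors = floors, permuted = NA))
  }
  positions <- list(A = c(best$st[1], best$en[1]),
                    B = c(best$st[2], best$en[2]),
                    C = c(best$st[3], best$en[3]))
  list(found = TRUE, positions = positions,
       scores = setNames(best$sc, c("A", "B", "C")), floors = floors,
       permuted = positions$C[1] < positions$A[1])
}

#' Restore canonical A-B-C motif order in a permuted RdRP
#'
#' Excises the fragment from the start of motif C up to the residue before
#' motif A (linker residues between the catalytic loop and motif A travel
#' with the fragment) and reinserts it immediately after the end of motif B.
#'
#' @param protein Permuted protein string.
#' @param annotation Output of [annotate_motifs()] with `permuted = TRUE`.
#' @return List with `original`, `restored`, `moved_span` (0-based half-open
#'   span of the excised fragment in `original`), `insertion_point` (0-based
#'   position in the residual sequence where the fragment was inserted).
#' @export
restore_canonical_order <- function(protein, annotation) {
  if (!isTRUE(annotation$found)) stop("motifs not found")
  if (!isTRUE(annotation$permuted)) stop("nothing to restore")
  c1 <- annotation$positions$C[1]
  a1 <- annotation$positions$A[1]
  b2 <- annotation$positions$B[2]
  frag <- substr(protein, c1 + 1L, a1)
  residual <- paste0(substr(protein, 1L, c1), substring(protein, a1 + 1L))
  frag_len <- a1 - c1
  insertion <- b2 - frag_len  # motif B's end in residual coordinates
  restored <- paste0(substr(residual, 1L, insertion), frag,
                     substring(residual, insertion + 1L))
  list(original = protein, restored = restored,
       moved_span = c(c1, a1), insertion_point = insertion)
}
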