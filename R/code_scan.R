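# Stop-codon census of RdRP cores under the standard genetic code and
# selection of the alternative code that yields the longest protein
# containing the core. Cores whose standard translation is stop-free keep the
# standard code without scanning alternatives.

core_codons <- function(bases, nt_start, nt_end, frame) {
  len <- nt_end - nt_start
  if (len %% 3L != 0L) stop("core span not divisible by 3")
  core <- substr(bases, nt_start + 1L, nt_end)
  if (frame < 0L) core <- revcomp(core)
  substring(core, seq(1L, len, by = 3L), seq(3L, len, by = 3L))
}

#' Count in-frame stop codons within an RdRP core
#'
#' @param bases Contig sequence.
#' @param call One RdRP call (row of [scan_contigs()] output, or any list
#'   with `nt_start`, `nt_end`, `frame`).
#' @param table_id Genetic-code table id.
#' @return Number of codons within the core span that are stops under the
#'   table.
#' @export
count_core_stops <- function(bases, call, table_id = "1") {
  codons <- core_codons(bases, call$nt_start, call$nt_end, call$frame)
  code <- get_code_table(table_id)
  sum(codons %in% code$stops)
}

# Longest stop-free aa run (under `code`) in the call's frame translation
# that fully contains the core's aa span; 0 if a stop falls inside the core.
longest_protein_with_core <- function(bases, call, table_id) {
  n <- nchar(bases)
  o <- abs(call$frame) - 1L
  if (call$frame > 0L) {
    aa_start <- (call$nt_start - o) %/% 3L
    aa_end <- (call$nt_end - o) %/% 3L
  } else {
    aa_start <- (n - call$nt_end - o) %/% 3L
    aa_end <- (n - call$nt_start - o) %/% 3L
  }
  fr <- frame_translation(bases, call$frame, table_id)
  segs <- fr$segments
  hit <- segs$start <= aa_start & segs$end >= aa_end
  if (!any(hit)) return(0L)
  seg <- segs[hit, , drop = FALSE]
  as.integer(seg$end[1] - seg$start[1])
}

#' Select the genetic code yielding the longest protein containing the core
#'
#' If the core contains no stop codons under the standard code, the standard
#' table is assigned without scanning alternatives. Otherwise every bundled
#' table is tried in the call's frame; the table maximizing the length of the
#' stop-free protein segment containing the core wins, with ties broken by
#' standard table first, then ascending numeric table id. If no table gives a
#' stop-free core the contig is flagged unresolvable.
#'
#' @param bases Contig sequence.
#' @param call One RdRP call.
#' @param tables Character vector of candidate table ids (default: all
#'   bundled tables).
#' @param contig_id Id recorded in the result.
#' @return List with `contig_id`, `standard_stop_count`, `chosen_table`,
#'   `best_protein_len`, `unresolvable`, and `per_table` (data.frame:
#'   table_id, core_stops, protein_len).
#' @export
select_code <- function(bases, call, tables = genetic_code_tables()$table_id,
                        contig_id = NA) {
  std_stops <- count_core_stops(bases, call, "1")
  if (std_stops == 0L) {
    return(list(contig_id = contig_id, standard_stop_count = 0L,
                chosen_table = "1",
                best_protein_len = longest_protein_with_core(bases, call, "1"),
                unresolvable = FALSE,
                per_table = data.frame(table_id = "1", core_stops = 0L,
                                       protein_len = longest_protein_with_core(
                                         bases, call, "1"),
                                       stringsAsFactors = FALSE)))
  }
  tables <- unique(as.character(tables))
  per <- data.frame(
    table_id = tables,
    core_stops = vapply(tables, function(tb)
      as.integer(count_core_stops(bases, call, tb)), integer(1),
      USE.NAMES = FALSE),
    protein_len = vapply(tables, function(tb)
      longest_protein_with_core(bases, call, tb), integer(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  if (all(per$core_stops > 0L)) {
    return(list(contig_id = contig_id, standard_stop_count = std_stops,
                chosen_table = NA_character_, best_protein_len = 0L,
                unresolvable = TRUE, per_table = per))
  }
  ord <- order(-per$protein_len, per$table_id != "1",
               as.numeric(per$table_id))
  chosen <- per$table_id[ord[1]]
  list(contig_id = contig_id, standard_stop_count = std_stops,
       chosen_table = chosen, best_protein_len = per$protein_len[ord[1]],
       unresolvable = FALSE, per_table = per)
}

#' Stop-codon census over a set of RdRP calls
#'
#' @param contigs Contig data.frame.
#' @param calls data.frame of best calls (one row per contig; see
#'   [scan_contigs()]).
#' @param tables Candidate table ids for [select_code()].
#' @return List with `n`, `zero_stop_fraction`, `max_stops`,
#'   `n_alternative`, `n_unresolvable`, and `assignments` (data.frame:
#'   contig_id, standard_stops, chosen_table, best_protein_len,
#'   unresolvable).
#' @export
stop_census <- function(contigs, calls,
                        tables = genetic_code_tables()$table_id) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    bases <- contigs$bases[match(calls$contig_id[i], contigs$contig_id)]
    a <- select_code(bases, calls[i, ], tables = tables,
                     contig_id = calls$contig_id[i])
    data.frame(contig_id = a$contig_id, standard_stops = a$standard_stop_count,
               chosen_table = a$chosen_table,
               best_protein_len = a$best_protein_len,
               unresolvable = a$unresolvable, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  list(n = nrow(assignments),
       zero_stop_fraction = mean(assignments$standard_stops == 0L),
       max_stops = max(assignments$standard_stops),
       n_alternative = sum(!is.na(assignments$chosen_table) &
                             assignments$chosen_table != "1"),
       n_unresolvable = sum(assignments$unresolvable),
       assignments = assignments)
}
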