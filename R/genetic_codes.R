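#' Bundled genetic-code tables
#'
#' The package uses the NCBI translation-table collection shipped with
#' Biostrings. Table "1" is the standard code; the remaining tables are the
#' known variants, several of which reassign one or more standard stop codons
#' to sense (e.g. the ciliate-type TAA/TAG -> Gln of table 6).
#'
#' @return A data.frame with columns `table_id` (character NCBI id), `name`,
#'   and `reassigns_stop` (TRUE if some standard-code stop codon is sense in
#'   the table). The number of non-standard tables is visible as
#'   `sum(tbl$table_id != "1")`.
#' @export
genetic_code_tables <- function() {
  tab <- Biostrings::GENETIC_CODE_TABLE
  data.frame(
    table_id = tab$id,
    name = tab$name,
    reassigns_stop = vapply(tab$id, function(id) {
      length(reassigned_stop_codons(id)) > 0L
    }, logical(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Fetch one genetic-code table
#'
#' @param table_id NCBI translation-table id (character or integer).
#' @return A list with `table_id`, `codon_to_aa` (named character vector over
#'   all 64 codons, `*` for stops) and `stops` (codon set mapped to `*`).
#' @export
get_code_table <- function(table_id) {
  id <- as.character(table_id)
  code <- Biostrings::getGeneticCode(id)
  list(table_id = id, codon_to_aa = code, stops = names(code)[code == "*"])
}

#' Standard-code stop codons that are sense in another table
#'
#' @param table_id NCBI table id.
#' @return Character vector of codons that translate to `*` under table 1 but
#'   to an amino acid under `table_id` (empty for the standard code itself).
#' @export
reassigned_stop_codons <- function(table_id) {
  std <- Biostrings::getGeneticCode("1")
  alt <- Biostrings::getGeneticCode(as.character(table_id))
  names(std)[std == "*" & alt != "*"]
}

#' Ids of all stop-reassigning tables
#'
#' @return Character vector of non-standard table ids in which at least one
#'   standard stop codon is sense. These are the tables an alternative-code
#'   virus can be simulated with (a planted reassigned stop codon is what
#'   makes the code identifiable).
#' @export
stop_reassigning_tables <- function() {
  tbl <- genetic_code_tables()
  tbl$table_id[tbl$table_id != "1" & tbl$reassigns_stop]
}

#' Tables uniquely identifiable by the longest-protein rule
#'
#' A table is uniquely identifiable when every other bundled table has at
#' least one of its stop codons among this table's reassigned standard stops:
#' a core carrying all the reassigned codons is then stop-free under the true
#' table only, so the longest-protein selection recovers it with certainty.
#' Tables whose stop sets coincide with or nest inside another table's (for
#' example the many mitochondrial codes that all stop at TAA/TAG) cannot be
#' told apart by any stop-codon census and are excluded. With the bundled
#' NCBI collection this yields the ciliate-type TAA/TAG-reassigning table and
#' its TAG-only counterpart.
#'
#' @return Character vector of table ids (default generator code pool).
#' @export
identifiable_code_pool <- function() {
  ids <- genetic_code_tables()$table_id
  stops_of <- lapply(ids, function(id) get_code_table(id)$stops)
  names(stops_of) <- ids
  keep <- vapply(ids, function(id) {
    planted <- reassigned_stop_codons(id)
    if (!length(planted)) return(FALSE)
    others <- setdiff(ids, id)
    all(vapply(others, function(o) {
      length(intersect(stops_of[[o]], planted)) > 0L
    }, logical(1)))
  }, logical(1))
  ids[keep]
}
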