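#' Read a SAM file (minimal dialect)
#'
#' Abundance needs only read identity, mapping status, reference and the
#' reference span, so this reader consumes qname, flag, rname, pos and CIGAR
#' and ignores everything else. Header (`@`) lines are skipped. No BAM/index
#' support.
#'
#' @param path Path to a tab-separated SAM file (header optional).
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos` (1-based
#'   as in SAM), `cigar`, `aligned_len` (reference-consuming length from the
#'   CIGAR), `mapped` (logical: rname present and flag bit 0x4 unset).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), aligned_len = integer(),
                      mapped = logical(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 6L)
  if (length(short)) stop("SAM line ", short[1L], " has fewer than 6 fields")
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  cigar <- vapply(fields, `[[`, "", 6L)
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             cigar = cigar, aligned_len = cigar_reference_length(cigar),
             mapped = rname != "*" & bitwAnd(flag, 4L) == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reference-consuming length of CIGAR strings
#'
#' Sums the lengths of M, =, X, D and N operations.
#'
#' @param cigar Character vector of CIGAR strings (`*` gives 0).
#' @return Integer vector of reference lengths.
#' @export
cigar_reference_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg)) {
      stop("malformed CIGAR: ", cg)
    }
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    kinds <- substr(ops, nchar(ops), nchar(ops))
    sum(lens[kinds %in% c("M", "=", "X", "D", "N")])
  }, integer(1), USE.NAMES = FALSE)
}
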