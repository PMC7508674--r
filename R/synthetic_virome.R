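# Ground-truthed synthetic +RNA virome generator. Genomes carry an RdRP-like
# core protein derived from a fixed consensus: three conserved motif blocks
# (A, B, C), conserved 3-residue terminal anchors, and a divergence process on
# everything else. A configurable fraction of genomes carries the C-A-B motif
# permutation, and a configurable fraction uses a stop-reassigning genetic
# code with planted reassigned codons.

# Robinson-Robinson style amino-acid background frequencies.
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

AA_BACKGROUND <- c(
  A = 0.079, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.064
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# 260-residue consensus core. Motif A at [80,88), motif B at [148,156),
# motif C at [156,162) -- C abuts B because the permuted catalytic loop
# (motif C plus the following 16 residues) is excised from immediately after
# B and reinserted there by the restore operation; any B-C linker would break
# the exact round trip. Terminal anchors [0,3) and [257,260) are conserved.
RDRP_CONSENSUS <- paste0(
  "YMSQPKRAPITRMSTMCATDYAWHLKEYTQRQEILQLGYPEELCEHFPCPVVENLRIGS",
  "KICRDQGSQIGLAGTGRLVKLDYSKWDSTLSILGMMRVKRPPGGEMHRRKLDQRTKKLV",
  "PQVEDDREYHGRYDPMQDQARPALTNRQGMSGQPGTLLSGDDSLDGKGTVAGREETEAQ",
  "DNNYFVSRRYNASGNAALLKARRFKQTATHTSSKPVLTQDVKYTGKHSQSGLSVASLWN",
  "LFKELDLGKTAATMVGSKLNAKDP"
)

#' Constants of the synthetic RdRP core
#'
#' @return List with the consensus core protein, the 0-based half-open motif
#'   spans (A, B, C), the span of the permutable catalytic-loop fragment
#'   (motif C plus 16 trailing residues), and the conserved position set
#'   (motifs plus 3-residue terminal anchors), 0-based.
#' @export
rdrp_generator_constants <- function() {
  motifs <- list(A = c(80L, 88L), B = c(148L, 156L), C = c(156L, 162L))
  frag <- c(156L, 178L)
  conserved <- sort(unique(c(0:2, 80:87, 148:161, 257:259)))
  list(consensus = RDRP_CONSENSUS, motifs = motifs, frag_span = frag,
       conserved = conserved, core_length_aa = nchar(RDRP_CONSENSUS))
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Permutation order on the 260 core positions (1-based): fragment
# [156,178) moves in front of motif A at position 80.
core_permutation_order <- function() {
  k <- rdrp_generator_constants()
  frag <- (k$frag_span[1] + 1L):k$frag_span[2]
  a1 <- k$motifs$A[1]
  c(seq_len(a1), frag, (a1 + 1L):k$frag_span[1], (k$frag_span[2] + 1L):260L)
}

#' Generate synthetic RdRP-bearing +RNA genomes with ground truth
#'
#' Each genome embeds one RdRP core (780 nt, 260 aa) derived from the bundled
#' consensus by per-site substitution at rate `divergence`; motif blocks A, B,
#' C and the 3-residue terminal anchors are never mutated. Genomes flagged
#' altcode are back-translated with a stop-reassigning table and carry at
#' least 5 planted in-frame codons that are stops in the standard code;
#' permuted genomes have the catalytic-loop fragment (motif C + 16 residues)
#' moved in front of motif A at the protein level before back-translation.
#' Codons are chosen uniformly among the synonymous codons of the genome's
#' table. All cores lie on forward frames; flanking sequence is random.
#'
#' @param n Number of genomes.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param p_permuted Probability a genome is motif-permuted.
#' @param p_altcode Probability a genome uses an alternative genetic code.
#' @param code_pool Table ids used for altcode genomes; must all reassign a
#'   standard stop codon (the standard table is rejected when
#'   `p_altcode > 0`). Defaults to [identifiable_code_pool()]: for every
#'   reassigned stop codon of the genome's table, at least 5 occurrences are
#'   planted in the core, which makes the true table the unique stop-free
#'   (hence longest-protein) candidate.
#' @param divergence Per-site substitution probability outside conserved
#'   blocks.
#' @param length_range Genome length range in nt (default 2500-12000).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance-weight
#'   parameters (default meanlog 3, sdlog 1).
#' @return List with `genomes` (data.frame: genome_id, bases, length,
#'   code_table_id, permuted, core_start, core_end (0-based half-open nt),
#'   core_frame, abundance_weight, core_protein (canonical order),
#'   core_protein_arranged (as encoded)) and `params` (full parameter echo).
#' @export
generate_genomes <- function(n, seed, p_permuted = 0, p_altcode = 0,
                             code_pool = identifiable_code_pool(),
                             divergence = 0.1,
                             length_range = c(2500L, 12000L),
                             abundance_meanlog = 3, abundance_sdlog = 1) {
  stopifnot(n >= 1, p_permuted >= 0, p_permuted <= 1,
            p_altcode >= 0, p_altcode <= 1,
            divergence >= 0, divergence <= 1)
  if (p_altcode > 0) {
    if ("1" %in% code_pool) {
      stop("code_pool must not contain the standard table when p_altcode > 0")
    }
    no_reassign <- vapply(code_pool, function(id) {
      length(reassigned_stop_codons(id)) == 0L
    }, logical(1))
    if (any(no_reassign)) {
      stop("code_pool tables without stop reassignment: ",
           paste(code_pool[no_reassign], collapse = ", "))
    }
  }
  set.seed(seed)
  k <- rdrp_generator_constants()
  cons <- strsplit(k$consensus, "")[[1]]
  mutable <- setdiff(seq_along(cons), k$conserved + 1L)
  perm_order <- core_permutation_order()
  core_len_nt <- 3L * length(cons)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    is_alt <- runif(1) < p_altcode
    is_perm <- runif(1) < p_permuted
    table_id <- if (is_alt) sample(code_pool, 1L) else "1"
    code <- get_code_table(table_id)

    prot <- cons
    mut <- mutable[runif(length(mutable)) < divergence]
    if (length(mut)) {
      prot[mut] <- vapply(prot[mut], function(a) {
        sample(setdiff(AA_ALPHABET, a), 1L)
      }, character(1))
    }

    # plant >= 5 in-frame occurrences of every reassigned stop codon of the
    # genome's table; with the identifiable pool this blocks all other tables
    planted <- character(0)
    if (is_alt) {
      for (rc in reassigned_stop_codons(table_id)) {
        target_aa <- unname(code$codon_to_aa[rc])
        avail <- setdiff(mutable[prot[mutable] == target_aa],
                         as.integer(names(planted)))
        if (length(avail) < 5L) {
          free <- setdiff(mutable, c(as.integer(names(planted)), avail))
          force_at <- sample(free, 5L - length(avail))
          prot[force_at] <- target_aa
          avail <- c(avail, force_at)
        }
        at <- if (length(avail) == 5L) avail else sample(avail, 5L)
        planted[as.character(at)] <- rc
      }
    }

    codons <- vapply(seq_along(prot), function(p) {
      rc <- unname(planted[as.character(p)])
      if (!is.na(rc)) return(rc)
      cands <- names(code$codon_to_aa)[code$codon_to_aa == prot[p]]
      if (!length(cands)) {
        stop("table ", table_id, " has no codon for residue ", prot[p])
      }
      if (length(cands) == 1L) cands else sample(cands, 1L)
    }, character(1))

    if (is_perm) {
      codons_arr <- codons[perm_order]
      prot_arr <- prot[perm_order]
    } else {
      codons_arr <- codons
      prot_arr <- prot
    }
    core_nt <- paste(codons_arr, collapse = "")

    glen <- sample(length_range[1]:length_range[2], 1L)
    core_start <- sample(50L:(glen - core_len_nt - 50L), 1L)
    bases <- paste0(random_dna(core_start), core_nt,
                    random_dna(glen - core_start - core_len_nt))

    rows[[i]] <- data.frame(
      genome_id = sprintf("g%04d", i),
      bases = bases,
      length = glen,
      code_table_id = table_id,
      permuted = is_perm,
      core_start = core_start,
      core_end = core_start + core_len_nt,
      core_frame = (core_start %% 3L) + 1L,
      abundance_weight = rlnorm(1, abundance_meanlog, abundance_sdlog),
      core_protein = paste(prot, collapse = ""),
      core_protein_arranged = paste(prot_arr, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  genomes <- do.call(rbind, rows)
  params <- list(n = n, seed = seed, p_permuted = p_permuted,
                 p_altcode = p_altcode, code_pool = code_pool,
                 divergence = divergence, length_range = length_range,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog)
  list(genomes = genomes, params = params)
}

apply_read_errors <- function(bases, error_rate) {
  if (error_rate <= 0) return(bases)
  alphabet <- c("A", "C", "G", "T")
  vapply(bases, function(b) {
    n <- nchar(b)
    nerr <- rbinom(1L, n, error_rate)
    if (nerr == 0L) return(b)
    pos <- sample.int(n, nerr)
    ch <- strsplit(b, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(orig) {
      sample(setdiff(alphabet, orig), 1L)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate sequencing reads from synthetic genomes
#'
#' Reads are allocated multinomially with probability proportional to
#' `abundance_weight x length`; fragments start uniformly and come from
#' either strand. Per-base substitution errors occur at `error_rate`; every
#' base gets the quality `round(-10 log10(error_rate))`, capped at Q40 (the
#' cap is also used when `error_rate = 0`). A contaminant fraction of reads
#' is drawn from `contaminant_genomes` (e.g. the DNA virome used for
#' subtraction tests). For paired output `total_reads` counts fragments; each
#' fragment emits mates `/1` and `/2` in FR orientation.
#'
#' @param genomes data.frame from [generate_genomes()] (`$genomes`), or any
#'   data.frame with `genome_id`, `bases`, `length` and optionally
#'   `abundance_weight`.
#' @param total_reads Number of fragments (paired) or reads (single-end).
#' @param seed Integer RNG seed.
#' @param read_len Read length in nt (default 150).
#' @param paired Paired-end if TRUE (default).
#' @param insert_mean,insert_sd Fragment-length distribution for paired mode.
#' @param error_rate Per-base substitution probability.
#' @param contaminant_genomes Optional data.frame like `genomes`.
#' @param contaminant_fraction Fraction of fragments drawn from the
#'   contaminant set.
#' @param library Library tag recorded on every read.
#' @return List with `reads` (data.frame: read_id, bases, qual, mate_id,
#'   library), `truth` (read_id, source_id, is_contaminant, frag_start
#'   (0-based on the source), frag_len, strand) and `params`.
#' @export
simulate_reads <- function(genomes, total_reads, seed, read_len = 150L,
                           paired = TRUE, insert_mean = 300, insert_sd = 30,
                           error_rate = 0.005, contaminant_genomes = NULL,
                           contaminant_fraction = 0,
                           library = NA_character_) {
  if (total_reads <= 0) stop("total_reads must be positive")
  stopifnot(read_len <= min(genomes$length))
  if (contaminant_fraction > 0 && is.null(contaminant_genomes)) {
    stop("contaminant_fraction > 0 requires contaminant_genomes")
  }
  set.seed(seed)

  n_contam <- if (contaminant_fraction > 0) {
    rbinom(1L, total_reads, contaminant_fraction)
  } else 0L
  n_viral <- total_reads - n_contam

  weight_of <- function(g) {
    w <- if ("abundance_weight" %in% names(g)) g$abundance_weight else 1
    w * g$length
  }
  alloc <- c(
    if (n_viral > 0) as.vector(stats::rmultinom(1, n_viral, weight_of(genomes)))
    else rep(0L, nrow(genomes)),
    if (n_contam > 0)
      as.vector(stats::rmultinom(1, n_contam, weight_of(contaminant_genomes)))
    else if (!is.null(contaminant_genomes)) rep(0L, nrow(contaminant_genomes))
    else integer(0)
  )
  src <- rbind(
    genomes[, c("genome_id", "bases", "length")],
    if (!is.null(contaminant_genomes))
      contaminant_genomes[, c("genome_id", "bases", "length")]
  )
  is_contam_src <- c(rep(FALSE, nrow(genomes)),
                     rep(TRUE, if (is.null(contaminant_genomes)) 0
                         else nrow(contaminant_genomes)))

  qv <- if (error_rate <= 0) 40L else min(40L, as.integer(round(-10 * log10(error_rate))))
  qstr <- strrep(intToUtf8(qv + 33L), read_len)

  per_source <- vector("list", nrow(src))
  frag_base <- 0L
  for (s in seq_len(nrow(src))) {
    m <- alloc[s]
    if (m == 0L) next
    gseq <- src$bases[s]; glen <- src$length[s]
    fid <- sprintf("read%07d", frag_base + seq_len(m))
    frag_base <- frag_base + m
    minus <- runif(m) < 0.5
    strand <- ifelse(minus, "-", "+")
    if (paired) {
      ins <- pmin(glen, pmax(read_len,
                             as.integer(round(rnorm(m, insert_mean,
                                                    insert_sd)))))
      start <- vapply(ins, function(x)
        sample.int(glen - x + 1L, 1L) - 1L, integer(1))
      frag <- substr(rep(gseq, m), start + 1L, start + ins)
      frag[minus] <- revcomp(frag[minus])
      r1 <- substr(frag, 1L, read_len)
      r2 <- revcomp(substr(frag, ins - read_len + 1L, ins))
      per_source[[s]] <- data.frame(
        read_id = c(rbind(paste0(fid, "/1"), paste0(fid, "/2"))),
        bases = c(rbind(r1, r2)),
        mate_id = rep(fid, each = 2L),
        source_id = src$genome_id[s], is_contaminant = is_contam_src[s],
        frag_start = rep(start, each = 2L), frag_len = rep(ins, each = 2L),
        strand = rep(strand, each = 2L), stringsAsFactors = FALSE)
    } else {
      start <- sample.int(glen - read_len + 1L, m, replace = TRUE) - 1L
      r <- substr(rep(gseq, m), start + 1L, start + read_len)
      r[minus] <- revcomp(r[minus])
      per_source[[s]] <- data.frame(
        read_id = fid, bases = r, mate_id = NA_character_,
        source_id = src$genome_id[s], is_contaminant = is_contam_src[s],
        frag_start = start, frag_len = read_len, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  all_rows <- do.call(rbind, per_source[!vapply(per_source, is.null,
                                                logical(1))])
  reads <- data.frame(read_id = all_rows$read_id,
                      bases = apply_read_errors(all_rows$bases, error_rate),
                      qual = qstr, mate_id = all_rows$mate_id,
                      library = library, stringsAsFactors = FALSE)
  truth <- all_rows[, c("read_id", "source_id", "is_contaminant",
                        "frag_start", "frag_len", "strand")]
  rownames(truth) <- NULL
  params <- list(total_reads = total_reads, seed = seed, read_len = read_len,
                 paired = paired, insert_mean = insert_mean,
                 insert_sd = insert_sd, error_rate = error_rate,
                 contaminant_fraction = contaminant_fraction,
                 quality = qv)
  list(reads = reads, truth = truth, params = params)
}

#' Write a synthetic virome to disk
#'
#' Emits `genomes.fasta`, `reads_1.fastq`/`reads_2.fastq` (or `reads.fastq`
#' for single-end), `truth_genomes.tsv`, `truth_reads.tsv` and `params.json`.
#'
#' @param gen Output of [generate_genomes()].
#' @param sim Output of [simulate_reads()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_virome <- function(gen, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(gen$genomes$genome_id, gen$genomes$bases,
              file.path(dir, "genomes.fasta"))
  reads <- sim$reads
  if (all(grepl("/1$|/2$", reads$read_id))) {
    write_fastq(reads[grepl("/1$", reads$read_id), ],
                file.path(dir, "reads_1.fastq"))
    write_fastq(reads[grepl("/2$", reads$read_id), ],
                file.path(dir, "reads_2.fastq"))
  } else {
    write_fastq(reads, file.path(dir, "reads.fastq"))
  }
  truth_g <- gen$genomes[, setdiff(names(gen$genomes), "bases")]
  write.table(truth_g, file.path(dir, "truth_genomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(gen$params, sim$params),
                       file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
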