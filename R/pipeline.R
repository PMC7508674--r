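# End-to-end orchestration: read trimming -> DNA subtraction -> contig-set
# unification -> RdRP scanning -> genetic-code assignment -> de-permutation
# -> clustering -> tree and clade calls -> abundance. Assembly is an external
# hand-off: the pipeline consumes contigs, it does not assemble reads.

#' Pipeline configuration with the survey's default thresholds
#'
#' Every numeric rule of the analysis lives here: k = 30 subtraction k-mers,
#' Q20 end trimming, 15-mer contig dedup at 0.90, full-length coverage 0.75,
#' clustering identities 0.50 and 0.75, clade rules (90% metagenome fraction
#' or depth < 1.0), spacer criteria 90/90, long-contig/long-ORF screen
#' (>1200 nt, >400 aa).
#'
#' @param ... Overrides for any default field.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    k_subtract = 30L, min_q = 20L, k_dedup = 15L, dedup_threshold = 0.90,
    coverage_full_length = 0.75, identity_cluster = 0.75,
    similarity_cluster = 0.50, clade_min_metagenome_fraction = 0.90,
    clade_max_depth = 1.0, spacer_identity = 0.90, spacer_coverage = 0.90,
    long_contig_nt = 1200L, long_orf_aa = 400L, seed = 1L,
    outdir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field: ", unknown[1])
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  in01 <- c("dedup_threshold", "coverage_full_length", "identity_cluster",
            "similarity_cluster", "clade_min_metagenome_fraction",
            "spacer_identity", "spacer_coverage")
  for (f in in01) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config field ", f, " out of [0,1]: ", cfg[[f]])
    }
  }
  stopifnot(cfg$k_subtract >= 1, cfg$k_dedup >= 1, cfg$min_q >= 0,
            cfg$clade_max_depth > 0, cfg$long_contig_nt >= 0,
            cfg$long_orf_aa >= 0)
  invisible(cfg)
}

stage_log <- function(stage, n_in, n_out, t0) {
  message(sprintf("[%s] in=%d out=%d elapsed=%.2fs", stage, n_in, n_out,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full discovery pipeline
#'
#' Stages run in fixed order; identical config and inputs give identical
#' outputs. Reads are trimmed, DNA-matching reads subtracted, contig sets
#' unified, contigs scanned for RdRP cores against the profile, genetic codes
#' assigned by stop census, permuted cores restored, full-length core
#' proteins clustered at the similarity and identity thresholds, a
#' neighbor-joining tree built over cluster representatives (plus any
#' reference proteins) and clades delineated, and abundance computed if a
#' mapping is supplied.
#'
#' @param config `pipeline_config`.
#' @param rna_reads RNA reads data.frame ([read_fastq()] format).
#' @param dna_reads DNA-library reads for subtraction (optional).
#' @param contigs_primary Contig data.frame (assembly hand-off).
#' @param contigs_secondary Optional second contig set, deduplicated against
#'   the primary set.
#' @param profile `rdrp_profile` used for scanning (with sub-motifs for
#'   de-permutation).
#' @param reference_proteins Optional data.frame (`id`, `seq`) of reference
#'   RdRPs included in the tree as non-metagenome leaves.
#' @param mapping Optional SAM data.frame or named count vector for
#'   abundance.
#' @param total_reads Library size for abundance when `mapping` is a count
#'   vector.
#' @param spacers Optional spacer data.frame (`id`, `seq`).
#' @return List of class `pipeline_report`; see fields in the source and the
#'   package vignette.
#' @export
run_pipeline <- function(config, rna_reads, dna_reads = NULL,
                         contigs_primary, contigs_secondary = NULL,
                         profile, reference_proteins = NULL, mapping = NULL,
                         total_reads = NULL, spacers = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  report <- list(config = unclass(config))
  t0 <- as.numeric(Sys.time())

  # 1. trim + subtract
  reads <- trim_read_ends(rna_reads, min_q = config$min_q)
  reads <- reads[nchar(reads$bases) > 0L, , drop = FALSE]
  if (!is.null(dna_reads) && nrow(dna_reads) > 0L) {
    idx <- build_kmer_index(dna_reads, k = config$k_subtract, source = "dna")
    sub <- subtract_reads(reads, idx)
  } else {
    sub <- list(kept = reads, removed_count = 0L, removed_fraction = 0,
                removed_ids = character(0))
  }
  report$reads_in <- nrow(rna_reads)
  report$reads_removed <- sub$removed_count
  report$removed_fraction <- sub$removed_fraction
  stage_log("subtract", nrow(rna_reads), nrow(sub$kept), t0)

  # 2. contig unification (assembly is external)
  contigs <- unify_contig_sets(contigs_primary, contigs_secondary,
                               k = config$k_dedup,
                               threshold = config$dedup_threshold)
  report$contigs_in <- nrow(contigs_primary) +
    if (is.null(contigs_secondary)) 0L else nrow(contigs_secondary)
  report$contigs_unified <- nrow(contigs)
  stage_log("unify", report$contigs_in, nrow(contigs), t0)

  # 3. RdRP scan (stop-tolerant so calls can span reassigned stop codons)
  calls <- scan_contigs(contigs, profile, stop_tolerant = TRUE)
  full <- calls[calls$full_length, , drop = FALSE]
  report$rdrp_calls <- nrow(calls)
  report$full_length_count <- nrow(full)
  stage_log("rdrpscan", nrow(contigs), nrow(calls), t0)

  # 4. genetic-code census
  census <- if (nrow(calls)) stop_census(contigs, calls) else NULL
  report$zero_stop_fraction <- if (is.null(census)) NA_real_ else
    census$zero_stop_fraction
  report$max_stops <- if (is.null(census)) NA_integer_ else census$max_stops
  report$alt_code_count <- if (is.null(census)) 0L else census$n_alternative
  stage_log("codescan", nrow(calls), report$alt_code_count, t0)

  # 5. core proteins (re-translated with assigned codes) + de-permutation
  proteins <- extract_core_proteins(contigs, calls, census)
  depermuted <- 0L
  if (nrow(proteins)) {
    for (i in seq_len(nrow(proteins))) {
      ann <- annotate_motifs(proteins$seq[i], profile)
      if (isTRUE(ann$found) && isTRUE(ann$permuted)) {
        proteins$seq[i] <- restore_canonical_order(proteins$seq[i],
                                                   ann)$restored
        depermuted <- depermuted + 1L
      }
    }
  }
  report$permuted_count <- depermuted
  stage_log("depermute", nrow(proteins), depermuted, t0)

  # 6. clustering of full-length cores at both thresholds
  full_prot <- proteins[proteins$id %in% full$contig_id, , drop = FALSE]
  cl_sim <- if (nrow(full_prot) > 0L)
    greedy_cluster(full_prot, config$similarity_cluster) else NULL
  cl_id <- if (nrow(full_prot) > 0L)
    greedy_cluster(full_prot, config$identity_cluster) else NULL
  report$cluster_count_similarity <- if (is.null(cl_sim)) 0L else
    length(cl_sim$clusters)
  report$cluster_count_identity <- if (is.null(cl_id)) 0L else
    length(cl_id$clusters)
  stage_log("cluster", nrow(full_prot), report$cluster_count_identity, t0)

  # 7. tree + clade delineation over representatives and references
  clades <- NULL
  if (!is.null(cl_id) && length(cl_id$clusters) >= 3L) {
    reps <- vapply(cl_id$clusters, `[[`, "", "representative")
    tree_prot <- full_prot[full_prot$id %in% reps, , drop = FALSE]
    origin <- setNames(rep("metagenome", nrow(tree_prot)), tree_prot$id)
    if (!is.null(reference_proteins) && nrow(reference_proteins) > 0L) {
      tree_prot <- rbind(tree_prot,
                         reference_proteins[, c("id", "seq")])
      origin <- c(origin, setNames(rep("reference",
                                       nrow(reference_proteins)),
                                   reference_proteins$id))
    }
    if (nrow(tree_prot) >= 4L) {
      D <- protein_distances(tree_prot)
      tree <- nj_tree(D)
      clades <- delineate_clades(tree, origin,
                                 min_frac = config$clade_min_metagenome_fraction,
                                 max_depth = config$clade_max_depth)
    }
  }
  report$clade_calls <- if (is.null(clades)) 0L else nrow(clades$calls)
  stage_log("cladecall", report$cluster_count_identity, report$clade_calls, t0)

  # 8. abundance + spacers
  if (!is.null(mapping)) {
    lens <- setNames(contigs$length, contigs$contig_id)
    ab <- compute_rpkm(mapping, lens, total_reads = total_reads)
    report$abundance <- summarize_abundance(ab)
    report$abundance_table <- ab
  }
  if (!is.null(spacers) && nrow(spacers) > 0L) {
    sm <- match_spacers(spacers, contigs,
                        min_identity = config$spacer_identity,
                        min_coverage = config$spacer_coverage)
    report$spacer_matches <- nrow(sm)
    report$spacer_table <- sm
  }

  report$kept_reads <- sub$kept
  report$contigs <- contigs
  report$calls <- calls
  report$census <- census
  report$proteins <- proteins
  report$clusters_identity <- cl_id
  report$clusters_similarity <- cl_sim
  report$clades <- clades
  check_report_arithmetic(report)
  if (!is.null(config$outdir)) write_pipeline_report(report, config$outdir)
  structure(report, class = "pipeline_report")
}

# Core proteins in canonical reading: the stop-to-stop translation of the
# core span in the call's frame, using each contig's assigned genetic code.
extract_core_proteins <- function(contigs, calls, census) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  tbl <- if (!is.null(census)) {
    setNames(census$assignments$chosen_table, census$assignments$contig_id)
  } else NULL
  seqs <- vapply(seq_len(nrow(calls)), function(i) {
    cid <- calls$contig_id[i]
    bases <- contigs$bases[match(cid, contigs$contig_id)]
    table_id <- if (!is.null(tbl) && !is.na(tbl[cid])) tbl[cid] else "1"
    codons <- core_codons(bases, calls$nt_start[i], calls$nt_end[i],
                          calls$frame[i])
    code <- get_code_table(table_id)
    paste(code$codon_to_aa[codons], collapse = "")
  }, character(1))
  data.frame(id = calls$contig_id, seq = seqs, stringsAsFactors = FALSE)
}

check_report_arithmetic <- function(report) {
  stopifnot(report$reads_removed >= 0,
            report$full_length_count <= report$rdrp_calls,
            report$alt_code_count <= report$rdrp_calls)
  if (!is.null(report$clusters_identity)) {
    sizes <- vapply(report$clusters_identity$clusters,
                    function(cl) length(cl$members), integer(1))
    stopifnot(sum(sizes) == report$full_length_count)
  }
  invisible(TRUE)
}

#' Write the consolidated pipeline report
#'
#' Emits `report.json` (counts and config), `calls.tsv`, `proteins.fasta`,
#' `clusters.tsv`, and, when computed, `abundance.tsv` and
#' `spacer_matches.tsv`. Coordinate columns in TSVs are 1-based inclusive
#' (stated in each header comment); in-memory objects stay 0-based half-open.
#'
#' @param report `pipeline_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalar_fields <- c("reads_in", "reads_removed", "removed_fraction",
                     "contigs_in", "contigs_unified", "rdrp_calls",
                     "full_length_count", "zero_stop_fraction", "max_stops",
                     "alt_code_count", "permuted_count",
                     "cluster_count_similarity", "cluster_count_identity",
                     "clade_calls", "spacer_matches")
  scalars <- report[intersect(scalar_fields, names(report))]
  jsonlite::write_json(list(config = report$config, counts = scalars),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  calls <- report$calls
  if (!is.null(calls) && nrow(calls)) {
    out <- calls
    # 1-based inclusive in exported tables
    out$prot_start <- out$prot_start + 1L
    out$nt_start <- out$nt_start + 1L
    con <- file(file.path(dir, "calls.tsv"), "w")
    writeLines("# coordinates 1-based inclusive", con)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(report$proteins) && nrow(report$proteins)) {
    write_fasta(report$proteins$id, report$proteins$seq,
                file.path(dir, "proteins.fasta"))
  }
  if (!is.null(report$clusters_identity)) {
    cl <- report$clusters_identity
    df <- data.frame(
      representative = rep(vapply(cl$clusters, `[[`, "", "representative"),
                           vapply(cl$clusters, function(x)
                             length(x$members), integer(1))),
      member = unlist(lapply(cl$clusters, `[[`, "members")),
      stringsAsFactors = FALSE)
    write.table(df, file.path(dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$abundance_table)) {
    write.table(report$abundance_table, file.path(dir, "abundance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$spacer_table)) {
    write.table(report$spacer_table, file.path(dir, "spacer_matches.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("RNA-virome pipeline report\n")
  cat(sprintf("  reads: %d in, %d removed by DNA subtraction (%.1f%%)\n",
              x$reads_in, x$reads_removed, 100 * x$removed_fraction))
  cat(sprintf("  contigs: %d in, %d after unification\n", x$contigs_in,
              x$contigs_unified))
  cat(sprintf("  RdRP calls: %d (%d full-length)\n", x$rdrp_calls,
              x$full_length_count))
  if (!is.na(x$zero_stop_fraction)) {
    cat(sprintf("  standard-code stop-free cores: %.3f (max stops %d, %d alt-code)\n",
                x$zero_stop_fraction, x$max_stops, x$alt_code_count))
  }
  cat(sprintf("  permuted cores restored: %d\n", x$permuted_count))
  cat(sprintf("  clusters: %d at %.2f, %d at %.2f; clade calls: %d\n",
              x$cluster_count_similarity, x$config$similarity_cluster,
              x$cluster_count_identity, x$config$identity_cluster,
              x$clade_calls))
  invisible(x)
}
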