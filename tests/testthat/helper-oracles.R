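# Independent oracles and fixture builders used across the suite. Oracles
# deliberately share no code with the package implementation paths they
# check.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Profile built from generator core proteins (ungapped equal-length
# alignment), with the generator's motif spans attached.
generator_profile <- function(gen, n_seqs = 50L) {
  seqs <- head(gen$genomes$core_protein, n_seqs)
  build_profile(seqs, sub_motifs = rdrp_generator_constants()$motifs)
}

# Slow reverse complement via explicit base mapping.
slow_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force subtraction oracle: a read is removed iff any length-k window
# of the read or of its mate (windows collected by explicit loops, strand
# collapsed by direct string comparison) occurs among the windows of any DNA
# sequence.
oracle_windows <- function(seq, k, stranded = FALSE) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (s in 1:(n - k + 1)) {
    w <- substr(seq, s, s + k - 1)
    if (grepl("[^ACGT]", w)) next
    if (!stranded) {
      rc <- slow_revcomp(w)
      if (rc < w) w <- rc
    }
    out <- c(out, w)
  }
  out
}

oracle_subtract <- function(reads, dna_seqs, k, stranded = FALSE) {
  dna_set <- unique(unlist(lapply(dna_seqs, oracle_windows, k = k,
                                  stranded = stranded)))
  read_hit <- vapply(reads$bases, function(b) {
    any(oracle_windows(b, k, stranded) %in% dna_set)
  }, logical(1), USE.NAMES = FALSE)
  key <- ifelse(is.na(reads$mate_id), paste0("solo", seq_len(nrow(reads))),
                reads$mate_id)
  removed <- ave(read_hit, key, FUN = any) > 0
  reads$read_id[removed]
}

# Full-matrix three-state affine DP written plainly (no rolling arrays, no
# start-coordinate propagation): returns only the best local score.
oracle_profile_sw <- function(scores, target_idx, gap_open = 11,
                              gap_ext = 1, unknown = -4) {
  L <- nrow(scores)
  n <- length(target_idx)
  M <- matrix(-Inf, L + 1, n + 1)
  D <- matrix(-Inf, L + 1, n + 1)
  I <- matrix(-Inf, L + 1, n + 1)
  best <- 0
  for (i in 1:L) {
    for (j in 1:n) {
      aa <- target_idx[j]
      sub <- if (is.na(aa) || aa < 0) unknown else scores[i, aa + 1]
      M[i + 1, j + 1] <- sub + max(0, M[i, j], D[i, j], I[i, j])
      D[i + 1, j + 1] <- max(M[i, j + 1] - (gap_open + gap_ext),
                             D[i, j + 1] - gap_ext)
      I[i + 1, j + 1] <- max(M[i + 1, j] - (gap_open + gap_ext),
                             I[i + 1, j] - gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Brute-force clade-delineation oracle: enumerate every internal node,
# compute its metagenome fraction and depth by explicit leaf walks, accept
# nodes satisfying a rule with no rule-satisfying proper ancestor.
oracle_clades <- function(tree, origin, min_frac = 0.90, max_depth = 1.0) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  internals <- (n_tip + 1L):n_node
  parent_of <- integer(n_node)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  tips_under <- function(v) {
    if (v <= n_tip) return(v)
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, tips_under))
  }
  dist_to <- function(v, tip) {
    # path length v -> tip by climbing from tip
    d <- 0
    u <- tip
    while (u != v) {
      e <- which(tree$edge[, 2] == u)
      d <- d + tree$edge.length[e]
      u <- tree$edge[e, 1]
    }
    d
  }
  satisfies <- vapply(internals, function(v) {
    tips <- tips_under(v)
    frac <- mean(origin[tree$tip.label[tips]] == "metagenome")
    depth <- max(vapply(tips, function(tp) dist_to(v, tp), numeric(1)))
    frac >= min_frac || depth < max_depth
  }, logical(1))
  names(satisfies) <- internals
  accepted <- vapply(internals, function(v) {
    if (!satisfies[as.character(v)]) return(FALSE)
    u <- v
    root <- n_tip + 1L
    while (u != root) {
      u <- parent_of[u]
      if (satisfies[as.character(u)]) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(internals[accepted])
}

# Synthetic protein families: high identity within, low between.
make_families <- function(n_fam, fam_size, len = 120L, n_mut = 6L) {
  seqs <- character(0)
  ids <- character(0)
  fam <- integer(0)
  for (f in seq_len(n_fam)) {
    base <- random_protein(len)
    for (j in seq_len(fam_size)) {
      ch <- strsplit(base, "")[[1]]
      at <- sample(len, n_mut)
      ch[at] <- vapply(ch[at], function(a) sample(setdiff(AA20, a), 1),
                       character(1))
      seqs <- c(seqs, paste(ch, collapse = ""))
      ids <- c(ids, sprintf("f%02d_m%02d", f, j))
      fam <- c(fam, f)
    }
  }
  data.frame(id = ids, seq = seqs, family = fam, stringsAsFactors = FALSE)
}

# Contig data.frame from a generated virome.
gen_contigs <- function(gen, library = "rna_random") {
  as_contigs(data.frame(id = gen$genomes$genome_id, seq = gen$genomes$bases),
             library = library)
}
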