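test_that("shared 15-mer fraction counts distinct canonical query k-mers", {
  set.seed(11)
  ref <- random_dna_str(300)
  idx <- build_kmer_index(ref, k = 15)
  expect_equal(shared_kmer_fraction(ref, idx), 1.0)  # self-containment

  # disjoint case (verified disjoint by construction under this seed)
  set.seed(12)
  other <- random_dna_str(100)
  frac_other <- shared_kmer_fraction(other, idx)
  expect_equal(frac_other, 0.0)

  # 100 nt query whose first 50 nt are copied from the reference: windows
  # starting at 0..35 lie fully in the copied prefix -> 36 shared of 86
  # distinct windows (seed chosen so all windows are distinct and the random
  # suffix shares nothing)
  set.seed(1)
  ref1 <- random_dna_str(300)
  qry <- paste0(substr(ref1, 1, 50), random_dna_str(50))
  idx1 <- build_kmer_index(ref1, k = 15)
  expect_equal(shared_kmer_fraction(qry, idx1), 36 / 86)

  expect_error(shared_kmer_fraction("ACGT", idx), "contig shorter than k")
})

test_that("contig unification excludes on strictly greater than the threshold", {
  set.seed(21)
  primary <- as_contigs(data.frame(id = c("p1", "p2"),
                                   seq = c(random_dna_str(400),
                                           random_dna_str(300))),
                        library = "rna_random")
  dup <- data.frame(id = "dup", seq = primary$bases[1])
  novel <- data.frame(id = "nov", seq = random_dna_str(250))
  secondary <- as_contigs(rbind(dup, novel), library = "rna_switch")
  out <- unify_contig_sets(primary, secondary)
  expect_setequal(out$contig_id, c("p1", "p2", "nov"))
  dec <- attr(out, "decisions")
  expect_true(dec$excluded[dec$contig_id == "dup"])
  expect_equal(dec$shared_fraction[dec$contig_id == "dup"], 1.0)

  # disjoint sets concatenate
  out2 <- unify_contig_sets(primary, as_contigs(novel, "rna_switch"))
  expect_equal(nrow(out2), 3L)

  # a contig sharing exactly 90.0% is retained (rule is strictly greater):
  # 114 nt query, first 104 nt copied -> 90 of 100 windows shared (seed
  # chosen so windows are distinct and the suffix shares nothing)
  set.seed(3)
  ref <- random_dna_str(300)
  boundary <- paste0(substr(ref, 1, 104), random_dna_str(10))
  pri <- as_contigs(data.frame(id = "ref", seq = ref))
  sec <- as_contigs(data.frame(id = "b", seq = boundary))
  idx <- build_kmer_index(ref, k = 15)
  expect_equal(shared_kmer_fraction(boundary, idx), 0.90)
  out3 <- unify_contig_sets(pri, sec)
  expect_true("b" %in% out3$contig_id)

  # idempotence: re-unifying adds nothing
  added <- out$contig_id[!(out$contig_id %in% primary$contig_id)]
  again <- unify_contig_sets(primary,
                             out[match(added, out$contig_id), , drop = FALSE])
  expect_setequal(again$contig_id, out$contig_id)
})

test_that("unification decisions equal all-pairs brute force on small sets", {
  set.seed(31)
  pri_seqs <- replicate(6, random_dna_str(sample(120:300, 1)))
  # secondary: some copies with mutations, some novel
  sec_seqs <- c(
    vapply(pri_seqs[1:3], function(s) {
      ch <- strsplit(s, "")[[1]]
      at <- sample(length(ch), 3)
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE),
    replicate(3, random_dna_str(200)))
  primary <- as_contigs(data.frame(id = sprintf("p%d", 1:6), seq = pri_seqs))
  secondary <- as_contigs(data.frame(id = sprintf("s%d", 1:6),
                                     seq = sec_seqs))
  out <- unify_contig_sets(primary, secondary)

  # oracle: distinct canonical windows of each secondary contig vs the union
  # of primary windows, by explicit enumeration
  prim_set <- unique(unlist(lapply(pri_seqs, oracle_windows, k = 15)))
  keep_oracle <- vapply(sec_seqs, function(s) {
    w <- unique(oracle_windows(s, 15))
    (sum(w %in% prim_set) / length(w)) <= 0.90
  }, logical(1), USE.NAMES = FALSE)
  expect_setequal(out$contig_id,
                  c(primary$contig_id, secondary$contig_id[keep_oracle]))
})

test_that("long-ORF screen applies strict length cutoffs", {
  # 1200 nt contig is excluded (strictly greater required)
  set.seed(41)
  c1200 <- as_contigs(data.frame(id = "x", seq = random_dna_str(1200)))
  expect_equal(nrow(screen_long_orfs(c1200)), 0L)

  # repeated TAA: frame +1 is all stops and yields nothing there (shifted
  # frames read sense codons ATA/AAT, so they do produce long runs)
  taa <- as_contigs(data.frame(
    id = "taa", seq = paste(rep("TAA", 1000), collapse = "")))
  taa_hits <- screen_long_orfs(taa)
  expect_false(1L %in% taa_hits$frame)

  # stop-dense random contigs: no frame sustains a >400 aa run
  set.seed(42)
  rand3k <- as_contigs(data.frame(id = "r", seq = random_dna_str(3000)))
  expect_equal(nrow(screen_long_orfs(rand3k)), 0L)

  # planted 401-codon stop-free ORF inside stop-bounded flanks
  orf_prot <- random_protein(401)
  orf_nt <- paste(vapply(strsplit(orf_prot, "")[[1]], function(a) {
    cands <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    sample(cands, 1)
  }, character(1)), collapse = "")
  seqs <- paste0(random_dna_str(120), "TAA", orf_nt, "TAA",
                 random_dna_str(120))
  planted <- as_contigs(data.frame(id = "orf", seq = seqs))
  hits <- screen_long_orfs(planted)
  hit1 <- hits[hits$frame == 1, ]
  expect_equal(nrow(hit1), 1L)
  # 0-based aa span within frame +1: ORF starts after 120 + 3 nt
  expect_equal(hit1$orf_start, 41L)
  expect_equal(hit1$orf_len, 401L)
})
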