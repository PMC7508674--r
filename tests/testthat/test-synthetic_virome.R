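test_that("genome generation is seed-deterministic and respects flags", {
  g1 <- generate_genomes(25, seed = 101, p_permuted = 0.3, p_altcode = 0.2,
                         divergence = 0.1)
  g2 <- generate_genomes(25, seed = 101, p_permuted = 0.3, p_altcode = 0.2,
                         divergence = 0.1)
  expect_identical(g1$genomes, g2$genomes)
  expect_identical(g1$params, g2$params)

  # p_altcode = 0: every core stop-free under the standard code
  g0 <- generate_genomes(15, seed = 102, p_altcode = 0, divergence = 0.15)
  stops <- vapply(seq_len(15), function(i) {
    row <- g0$genomes[i, ]
    count_core_stops(row$bases,
                     list(nt_start = row$core_start, nt_end = row$core_end,
                          frame = row$core_frame), "1")
  }, numeric(1))
  expect_equal(stops, rep(0, 15))

  expect_error(generate_genomes(5, seed = 1, p_altcode = 0.5,
                                code_pool = c("1", "6")),
               "must not contain the standard table")
})

test_that("every generated core is stop-free under its own table and altcode codons are planted", {
  gen <- generate_genomes(40, seed = 103, p_altcode = 0.5, divergence = 0.15)
  g <- gen$genomes
  for (i in seq_len(nrow(g))) {
    call <- list(nt_start = g$core_start[i], nt_end = g$core_end[i],
                 frame = g$core_frame[i])
    expect_equal(count_core_stops(g$bases[i], call, g$code_table_id[i]), 0)
    if (g$code_table_id[i] != "1") {
      # >= 5 in-frame occurrences of every reassigned stop codon
      core <- substr(g$bases[i], g$core_start[i] + 1L, g$core_end[i])
      codons <- substring(core, seq(1, nchar(core), 3),
                          seq(3, nchar(core), 3))
      for (rc in reassigned_stop_codons(g$code_table_id[i])) {
        expect_gte(sum(codons == rc), 5)
      }
    }
  }
  # permuted genomes encode motif order C < A < B, canonical A < B < C
  k <- rdrp_generator_constants()
  cons <- k$consensus
  motif_str <- function(m) substr(cons, k$motifs[[m]][1] + 1, k$motifs[[m]][2])
  for (i in seq_len(nrow(g))) {
    arr <- g$core_protein_arranged[i]
    pos <- vapply(c("A", "B", "C"), function(m)
      regexpr(motif_str(m), arr, fixed = TRUE)[[1]], numeric(1))
    if (g$permuted[i]) expect_true(pos["C"] < pos["A"] && pos["A"] < pos["B"])
    else expect_true(pos["A"] < pos["B"] && pos["B"] < pos["C"])
  }
})

test_that("permuted fraction matches its binomial sampling distribution", {
  gen <- generate_genomes(500, seed = 104, p_permuted = 0.3, divergence = 0.05)
  x <- sum(gen$genomes$permuted)
  ci <- qbinom(c(0.005, 0.995), 500, 0.3)
  expect_gte(x, ci[1])
  expect_lte(x, ci[2])
})

test_that("read simulation honours abundance weights, errors and contamination", {
  gen <- generate_genomes(2, seed = 105, divergence = 0.05,
                          length_range = c(4000L, 4001L))
  g <- gen$genomes
  g$abundance_weight <- c(9, 1)
  g$length <- rep(4000L, 2)
  g$bases <- substr(g$bases, 1, 4000)

  # error_rate = 0: every read is an exact substring of its source or its
  # reverse complement
  sim0 <- simulate_reads(g, 300, seed = 1, error_rate = 0)
  src <- setNames(g$bases, g$genome_id)
  ok <- vapply(seq_len(nrow(sim0$reads)), function(i) {
    s <- src[sim0$truth$source_id[match(sim0$reads$read_id[i],
                                        sim0$truth$read_id)]]
    grepl(sim0$reads$bases[i], s, fixed = TRUE) ||
      grepl(revcomp(sim0$reads$bases[i]), s, fixed = TRUE)
  }, logical(1))
  expect_true(all(ok))

  # 9:1 weights, equal lengths: fragment split within exact binomial 99% CI
  sim <- simulate_reads(g, 10000, seed = 2, error_rate = 0)
  n1 <- sum(sim$truth$source_id == g$genome_id[1]) / 2  # fragments
  ci <- qbinom(c(0.005, 0.995), 10000, 0.9)
  expect_gte(n1, ci[1])
  expect_lte(n1, ci[2])

  # contamination fraction within binomial 99% CI
  dna <- generate_genomes(3, seed = 106, divergence = 0.3)
  simc <- simulate_reads(g, 10000, seed = 3, error_rate = 0,
                         contaminant_genomes = dna$genomes,
                         contaminant_fraction = 0.5)
  ncont <- sum(simc$truth$is_contaminant) / 2
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(ncont, ci[1])
  expect_lte(ncont, ci[2])

  # empirical per-base error rate within 3 sigma of the configured rate:
  # reconstruct each error-free read from the recorded fragment coordinates
  rate <- 0.01
  sime <- simulate_reads(g, 2000, seed = 4, error_rate = rate, paired = FALSE)
  n_err <- 0L
  for (i in seq_len(nrow(sime$reads))) {
    tr <- sime$truth[i, ]
    expected <- substr(src[tr$source_id], tr$frag_start + 1,
                       tr$frag_start + tr$frag_len)
    if (tr$strand == "-") expected <- revcomp(expected)
    n_err <- n_err + sum(utf8ToInt(expected) !=
                           utf8ToInt(sime$reads$bases[i]))
  }
  n_bases <- sum(nchar(sime$reads$bases))
  sd3 <- 3 * sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(n_err / n_bases - rate), sd3)

  # quality encodes round(-10 log10(error_rate))
  expect_equal(unique(phred_scores(sime$reads$qual[1])[[1]]), 20L)
  expect_error(simulate_reads(g, 0, seed = 1), "total_reads must be positive")
})

test_that("log abundance weights are compatible with normality", {
  gen <- generate_genomes(250, seed = 107, divergence = 0.02)
  p <- shapiro.test(log(gen$genomes$abundance_weight))$p.value
  expect_gt(p, 0.01)
})

test_that("a synthetic virome writes its standard file set", {
  gen <- generate_genomes(4, seed = 108, divergence = 0.1)
  sim <- simulate_reads(gen$genomes, 50, seed = 1)
  dir <- withr::local_tempdir()
  write_synthetic_virome(gen, sim, dir)
  expect_setequal(list.files(dir),
                  c("genomes.fasta", "reads_1.fastq", "reads_2.fastq",
                    "truth_genomes.tsv", "truth_reads.tsv", "params.json"))
  back <- read_fasta(file.path(dir, "genomes.fasta"))
  expect_equal(back$seq, gen$genomes$bases)
  r1 <- read_fastq(file.path(dir, "reads_1.fastq"))
  expect_true(all(grepl("/1$", r1$read_id)))
})
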