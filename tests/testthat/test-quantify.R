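test_that("spacer matching applies inclusive 90/90 criteria on both strands", {
  set.seed(71)
  contig <- random_dna_str(600)
  sp_exact <- substr(contig, 101, 130)             # exact 30-nt protospacer
  # 3 mismatches spread out: identity 27/30 = 0.90, still reported
  ch <- strsplit(sp_exact, "")[[1]]
  for (p in c(5, 15, 25)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  sp_mm3 <- paste(ch, collapse = "")
  # 4 mismatches: identity 26/30 < 0.90, rejected
  ch[2] <- setdiff(c("A", "C", "G", "T"), ch[2])[1]
  sp_mm4 <- paste(ch, collapse = "")
  sp_rc <- revcomp(substr(contig, 201, 230))       # reverse-strand match
  spacers <- data.frame(id = c("ex", "mm3", "mm4", "rc"),
                        seq = c(sp_exact, sp_mm3, sp_mm4, sp_rc))
  contigs <- as_contigs(data.frame(id = "c1", seq = contig))
  m <- match_spacers(spacers, contigs)

  ex <- m[m$spacer_id == "ex", ]
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$identity, 1.0)
  expect_equal(ex$spacer_coverage, 1.0)
  expect_equal(ex$start, 100L)  # 0-based half-open forward span
  expect_equal(ex$end, 130L)

  mm3 <- m[m$spacer_id == "mm3", ]
  expect_equal(nrow(mm3), 1L)
  expect_equal(mm3$identity, 27 / 30)

  expect_equal(nrow(m[m$spacer_id == "mm4", ]), 0L)

  rc <- m[m$spacer_id == "rc", ]
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 200L)
  expect_equal(rc$end, 230L)

  # matches equal a brute-force sliding-window oracle for gapless spacers
  oracle_hits <- function(sp) {
    hits <- 0L
    for (target in c(sp, revcomp(sp))) {
      tv <- utf8ToInt(target)
      cv <- utf8ToInt(contig)
      for (s in 1:(length(cv) - length(tv) + 1)) {
        mm <- sum(cv[s:(s + length(tv) - 1)] != tv)
        if ((length(tv) - mm) / length(tv) >= 0.90) hits <- hits + 1L
      }
    }
    hits
  }
  for (id in spacers$id) {
    expect_equal(nrow(m[m$spacer_id == id, ]) > 0,
                 oracle_hits(spacers$seq[spacers$id == id]) > 0)
  }
})

test_that("RPKM follows the unit formula and its invariances", {
  lens <- c(a = 1000, b = 2000, c = 500)
  r <- compute_rpkm(c(a = 1000L, b = 500L, c = 0L), lens,
                    total_reads = 1e6)
  expect_equal(r$rpkm[r$contig_id == "a"], 1000)
  expect_equal(compute_rpkm(c(b = 500L), c(b = 2000), 2e6)$rpkm, 125)
  expect_equal(r$rpkm[r$contig_id == "c"], 0)
  expect_equal(r$fold_over_median[r$contig_id == "c"], 0)

  # invariant under duplicating the library
  r2 <- compute_rpkm(c(a = 2000L, b = 1000L, c = 0L), lens,
                     total_reads = 2e6)
  expect_equal(r2$rpkm, r$rpkm)

  expect_error(compute_rpkm(c(zz = 5L), lens, 100), "absent from lengths")
})

test_that("SAM-based RPKM counts mapped mates and computes covered fraction", {
  f <- withr::local_tempfile()
  lines <- c(
    paste("r1/1", 0, "c1", 1, 60, "100M", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r1/2", 16, "c1", 151, 60, "100M", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r2/1", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"),
    paste("r3/1", 0, "c1", 50, 60, "100M", "*", 0, 0, "*", "*", sep = "\t"))
  writeLines(lines, f)
  sam <- read_sam(f)
  r <- compute_rpkm(sam, c(c1 = 1000), total_reads = nrow(sam))
  expect_equal(r$mapped_reads, 3L)          # each mate counts once
  expect_equal(r$total_reads, 4L)           # unmapped contribute to N only
  expect_equal(r$rpkm, 3 / 1 / (4 / 1e6))
  # union of [1,100], [50,149], [151,250] covers 149 + 100 = 249 bases
  expect_equal(r$covered_fraction, 249 / 1000)
})

test_that("abundance summaries recover log-normal parameters and planted outliers", {
  recs <- data.frame(contig_id = c("a", "b", "c"), rpkm = c(1, 2, 3),
                     fold_over_median = c(0.5, 1, 1.5))
  expect_equal(summarize_abundance(recs)$median, 2.0)

  set.seed(72)
  n <- 10000
  r <- rlnorm(n, meanlog = 3, sdlog = 1)
  recs2 <- data.frame(contig_id = seq_len(n), rpkm = r,
                      fold_over_median = r / median(r))
  s <- summarize_abundance(recs2)
  expect_lt(abs(s$lognormal_meanlog - 3), 3 * 1 / sqrt(n))
  expect_lt(abs(s$lognormal_sdlog - 1), 3 * 1 / sqrt(2 * n))
  # unimodal draw: modal peak within a factor ~2 of exp(mu) = 20.1
  expect_gt(s$modal_peak, exp(3) / 2)
  expect_lt(s$modal_peak, exp(3) * 2)

  expect_error(summarize_abundance(data.frame(rpkm = c(0, 0))),
               "at least 2 positive")

  # planted 800x-median genome: multinomial read allocation reproduces the
  # fold-over-median within sampling error
  set.seed(73)
  n_bg <- 100
  w <- c(rep(1, n_bg), 800)
  lens <- rep(3000, n_bg + 1)
  counts <- as.vector(rmultinom(1, 2e5, w * lens))
  names(counts) <- sprintf("g%03d", seq_along(counts))
  ab <- compute_rpkm(counts, setNames(lens, names(counts)),
                     total_reads = 2e5)
  fom <- ab$fold_over_median[n_bg + 1]
  expect_gt(fom, 800 * 0.9)
  expect_lt(fom, 800 * 1.1)
  expect_equal(max(summarize_abundance(ab)$top_fold_over_median), fom)
})

test_that("mapped read mass is conserved", {
  lens <- c(a = 1000, b = 1500)
  r <- compute_rpkm(c(a = 10L, b = 20L), lens, total_reads = 50)
  expect_lte(sum(r$mapped_reads), unique(r$total_reads))
})
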