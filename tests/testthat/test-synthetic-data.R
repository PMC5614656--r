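# Synthetic transcriptomes, expression laws, the paired-end read
# simulator, and truth-based re-quantification.

test_that("synthetic transcriptome conserves counts and is seed-deterministic", {
  tx <- synthetic_transcriptome(5, M = 2, seed = 101)
  expect_length(tx$sequences, 10L)
  expect_equal(length(unique(tx$annotation$gene_id)), 5L)
  expect_equal(tx$annotation$length,
               unname(Biostrings::width(tx$sequences)))
  tx2 <- synthetic_transcriptome(5, M = 2, seed = 101)
  expect_identical(as.character(tx$sequences), as.character(tx2$sequences))
  expect_error(synthetic_transcriptome(3, length_range = c(100, 200)),
               "read-geometry")
  # uniform base model: GC about one half at a megabase
  big <- synthetic_transcriptome(10, M = 1, length_range = c(1e5, 1e5),
                                 seed = 5)
  gc <- sum(Biostrings::letterFrequency(big$sequences, c("G", "C"))) /
    sum(Biostrings::width(big$sequences))
  expect_equal(gc, 0.5, tolerance = 0.02 / 0.5)
})

test_that("transcript extraction concatenates exons and reverse-complements
           the minus strand", {
  genome <- Biostrings::DNAStringSet(c(
    chrT = paste0("ACGTACGTAC", "GATTACAGAT", "TACAGATTAC",
                  "AGATCCGGAA", "TTCCGGCCAA", "GGTTAACCGG")))
  gtf <- write_gtf_fixture(withr::local_tempfile(fileext = ".gtf"))
  seqs <- extract_transcript_sequences(genome, gtf)
  chr <- as.character(genome[[1]])
  expect_equal(as.character(seqs[["gA.t1"]]),
               paste0(substr(chr, 11, 25), substr(chr, 36, 50)))
  expect_equal(as.character(seqs[["gA.t2"]]), substr(chr, 11, 50))
  expect_equal(as.character(seqs[["gB.t1"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr, 5, 16)))))
  # out-of-bounds exon names the transcript
  bad <- data.frame(seqnames = "chrT", start = 55, end = 600, strand = "+",
                    type = "exon", transcript_id = "gX.t1")
  expect_error(extract_transcript_sequences(genome, bad), "gX.t1")
})

test_that("expression laws have the stated moments and are seeded", {
  ann <- data.frame(transcript_id = sprintf("t%06d", 1:1e5))
  en <- assign_expression(ann, "normal(20,2)", seed = 9)
  expect_equal(mean(en), 20, tolerance = 0.05 / 20)
  expect_equal(sd(en), 2, tolerance = 0.05 / 2)
  expect_true(all(en >= 0))
  ew <- assign_expression(ann, "weibull(0.39,10)", seed = 9)
  expect_equal(mean(ew), 10 * gamma(1 + 1 / 0.39), tolerance = 0.6 / 35.6)
  expect_identical(ew, assign_expression(ann, "weibull(0.39,10)", seed = 9))
  expect_error(assign_expression(ann, "cauchy(0,1)"), "unknown expression law")
})

test_that("read-pair count formula is round-half-up of E*L/200", {
  expect_identical(read_pair_count(20, 1000), 100L)
  expect_identical(read_pair_count(0, 500), 0L)
  expect_identical(read_pair_count(1, 100), 1L)
  expect_identical(read_pair_count(0.99, 100), 0L)   # 0.495 + 0.5 < 1
  expect_identical(read_pair_count(1.01, 100), 1L)
  expect_error(read_pair_count(-1, 100), ">= 0")
})

test_that("read pairs are exact (rev-complemented) substrings with uniform
           interior coverage", {
  cfg <- read_sim_config(seed = 3)
  tx <- synthetic_transcriptome(1, M = 1, length_range = c(1200, 1200),
                                seed = 44)
  s <- as.character(tx$sequences[[1]])
  set.seed(77)
  rp <- simulate_read_pairs(s, R = 200, cfg, transcript_id = "tx1")
  expect_length(rp$read1, 200L)
  expect_length(rp$read2, 200L)
  expect_true(all(vapply(rp$read1, grepl, TRUE, x = s, fixed = TRUE)))
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rp$read2)))
  expect_true(all(vapply(rc2, grepl, TRUE, x = s, fixed = TRUE)))
  # mate geometry: mate 2 fragment end sits insert + read_length after
  # mate 1 start
  expect_true(all(rp$starts >= 1 & rp$starts <= 1200 - 300 + 1))
  expect_equal(substring(s, rp$starts + 200, rp$starts + 299), unname(rc2))

  # flat coverage: fragment starts uniform, binomial envelope per bin
  set.seed(78)
  rp2 <- simulate_read_pairs(s, R = 1e4, cfg)
  bins <- cut(rp2$starts, breaks = seq(0, 901, length.out = 11))
  counts <- as.vector(table(bins))
  expected <- 1e4 / 10
  expect_true(all(abs(counts - expected) <
                    3 * sqrt(1e4 * 0.1 * 0.9)))

  # too-short transcript skipped with warning
  expect_warning(res <- simulate_read_pairs(strrep("A", 200), 5, cfg),
                 "skipped")
  expect_null(res)
})

test_that("a replicated run writes R pairs per transcript and re-quantifies
           to the truth within rounding granularity", {
  out <- withr::local_tempdir()
  tx <- synthetic_transcriptome(20, M = 2, length_range = c(500, 1500),
                                seed = 7)
  cfg <- read_sim_config(replicates = 2, seed = 7)
  res <- simulate_rnaseq(tx, law = "normal(20,2)", config = cfg,
                         out_dir = out, prefix = "toy")
  expect_equal(nrow(res$files), 2L)
  truth1 <- res$truth[res$truth$replicate == 1, ]
  # exact pair counts per transcript, both mates
  requant <- requantify_reads(res$files$mate1[1],
                              setNames(truth1$length, truth1$transcript_id))
  m <- merge(requant, truth1, by = "transcript_id")
  expect_equal(m$pairs.x, m$pairs.y)
  fq2 <- readLines(res$files$mate2[1])
  expect_equal(length(fq2), 4L * sum(truth1$pairs))
  # recovery within the rounding granularity 200/L of the count formula
  expect_true(all(abs(m$E_hat - m$E) <= 100 / m$length + 1e-9))
  # total pairs conserved
  expect_equal(sum(requant$pairs), sum(truth1$pairs))
})

test_that("salmon-dialect synthetic tables round-trip through the parser", {
  path <- file.path(withr::local_tempdir(), "quant.sf")
  et <- expression_table(50, M = 3, law = "weibull(0.39,10)", seed = 13,
                         path = path)
  tab <- read_expression_table(path, "salmon",
                               t2g = read_t2g(paste0(path, ".t2g.tsv")))
  expect_equal(nrow(tab), 150L)
  expect_equal(tab$expression, unname(et$truth))
  expect_equal(sort(unique(tab$gene_id)), sort(names(et$counts)))
})
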