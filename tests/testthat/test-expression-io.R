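# Quantification-table parsing, annotation counts, profile construction
# and grouping.

test_that("cufflinks dialect round-trips FPKM with gene ids", {
  path <- write_cufflinks_fixture(withr::local_tempfile(fileext = ".tsv"))
  tab <- read_expression_table(path, "cufflinks", sample_id = "s1")
  expect_s3_class(tab, "isoform_expr")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$expression, c(6, 3, 1))
  expect_equal(tab$gene_id, c("g1", "g1", "g2"))
})

test_that("salmon dialect ingests TPM and requires a t2g mapping", {
  path <- write_salmon_fixture(withr::local_tempfile(fileext = ".sf"))
  t2g_path <- write_t2g_fixture(withr::local_tempfile(fileext = ".tsv"))
  tab <- read_expression_table(path, "salmon", t2g = t2g_path)
  expect_equal(tab$expression, c(6, 3, 1))
  expect_equal(tab$gene_id, c("g1", "g1", "g2"))
  expect_error(read_expression_table(path, "salmon"), "t2g")

  # header missing TPM is a format error naming the column
  broken <- withr::local_tempfile(fileext = ".sf")
  df <- read.delim(path)
  write.table(df[, setdiff(names(df), "TPM")], broken, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_expression_table(broken, "salmon", t2g = t2g_path), "TPM")
})

test_that("malformed rows are dropped with line numbers; duplicates error", {
  path <- write_cufflinks_fixture(withr::local_tempfile(fileext = ".tsv"),
                                  fpkm = c(6, -3, 1))
  expect_warning(tab <- read_expression_table(path, "cufflinks"), "line")
  expect_equal(nrow(tab), 2L)

  dup <- write_cufflinks_fixture(withr::local_tempfile(fileext = ".tsv"),
                                 tracking_id = c("t1", "t1", "t3"))
  expect_error(read_expression_table(dup, "cufflinks"), "duplicate")
})

test_that("GTF annotation counts transcripts per gene", {
  path <- write_gtf_fixture(withr::local_tempfile(fileext = ".gtf"))
  counts <- isoform_counts_from_gtf(path)
  expect_equal(counts[["gA"]], 2L)
  expect_equal(counts[["gB"]], 1L)
})

test_that("profiles rank frequencies, pad unobserved isoforms and filter", {
  tab <- make_expr_table(c("t1", "t2", "t3"), "g1", c(6, 3, 1))
  p <- build_gene_profiles(tab, c(g1 = 3))
  expect_length(p, 1L)
  expect_equal(p[[1]]$frequencies, c(0.6, 0.3, 0.1))
  expect_equal(p[[1]]$E, 10)

  # single-isoform gene: frequency exactly 1 whenever expressed
  p1 <- build_gene_profiles(make_expr_table("t1", "g1", 5), c(g1 = 1))
  expect_identical(p1[[1]]$frequencies, 1)

  # gene below the expression filter is excluded
  p0 <- build_gene_profiles(make_expr_table("t1", "g1", 0.5), c(g1 = 1))
  expect_length(p0, 0L)

  # annotated-but-unobserved isoforms enter with zero frequency, rank last
  p2 <- build_gene_profiles(make_expr_table(c("t1", "t2"), "g1", c(8, 2)),
                            c(g1 = 4))
  expect_equal(p2[[1]]$M, 4L)
  expect_equal(p2[[1]]$frequencies, c(0.8, 0.2, 0, 0))

  # rank ties break lexicographically by transcript id
  p3 <- build_gene_profiles(make_expr_table(c("tB", "tA"), "g1", c(5, 5)),
                            c(g1 = 2))
  expect_equal(p3[[1]]$ranked_transcripts, c("tA", "tB"))

  # unknown gene dropped and counted
  expect_message(
    p4 <- build_gene_profiles(make_expr_table(c("t1", "tX"), c("g1", "gX"),
                                              c(5, 5)), c(g1 = 1)),
    "unknown gene")
  expect_identical(attr(p4, "dropped"), 1L)
})

test_that("profile invariants: frequencies sum to 1 sorted descending;
           row order does not matter", {
  set.seed(77)
  tab <- make_expr_table(sprintf("t%02d", 1:12),
                         rep(c("gA", "gB", "gC"), times = c(3, 4, 5)),
                         rgamma(12, 2, 0.5))
  counts <- c(gA = 3, gB = 4, gC = 5)
  p <- build_gene_profiles(tab, counts)
  for (prof in p) {
    expect_equal(sum(prof$frequencies), 1, tolerance = 1e-9)
    expect_true(all(diff(prof$frequencies) <= 0))
  }
  shuffled <- tab[sample(nrow(tab)), ]
  p_shuf <- build_gene_profiles(shuffled, counts)
  get_freq <- function(pp) {
    ord <- order(vapply(pp, `[[`, "", "gene_id"))
    lapply(pp[ord], `[[`, "frequencies")
  }
  expect_equal(get_freq(p), get_freq(p_shuf))
})

test_that("grouping pools frequency vectors by annotated isoform count", {
  tab <- make_expr_table(sprintf("t%d", 1:7),
                         c("gA", "gA", "gB", "gB", "gC", "gC", "gC"),
                         c(5, 5, 9, 1, 4, 4, 2))
  groups <- group_by_isoform_count(
    build_gene_profiles(tab, c(gA = 2, gB = 2, gC = 3)))
  expect_named(groups, c("2", "3"))
  expect_equal(nrow(groups[["2"]]), 2L)
  expect_equal(nrow(groups[["3"]]), 1L)
  expect_equal(group_by_isoform_count(structure(list(),
                                                class = "gene_profiles")),
               list())
})

test_that("long-format profile TSV round-trips", {
  tab <- make_expr_table(sprintf("t%d", 1:5),
                         c("gA", "gA", "gA", "gB", "gB"),
                         c(5, 3, 2, 9, 1))
  p <- build_gene_profiles(tab, c(gA = 3, gB = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(p, path)
  p2 <- read_profiles(path)
  ord <- function(pp) order(vapply(pp, `[[`, "", "gene_id"))
  expect_equal(lapply(p[ord(p)], `[[`, "frequencies"),
               lapply(p2[ord(p2)], `[[`, "frequencies"))
  expect_equal(lapply(p[ord(p)], `[[`, "ranked_transcripts"),
               lapply(p2[ord(p2)], `[[`, "ranked_transcripts"))
})
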