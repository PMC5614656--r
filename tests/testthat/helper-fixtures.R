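# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing is read from stored data files.

write_cufflinks_fixture <- function(path,
                                    tracking_id = c("t1", "t2", "t3"),
                                    gene_id = c("g1", "g1", "g2"),
                                    fpkm = c(6, 3, 1)) {
  df <- data.frame(
    tracking_id = tracking_id,
    class_code = "-", nearest_ref_id = "-",
    gene_id = gene_id, gene_short_name = gene_id,
    tss_id = "-", locus = "chr1:1-100", length = 1000L, coverage = 10,
    FPKM = fpkm, FPKM_conf_lo = fpkm, FPKM_conf_hi = fpkm,
    FPKM_status = "OK", stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_salmon_fixture <- function(path,
                                 name = c("t1", "t2", "t3"),
                                 tpm = c(6, 3, 1),
                                 length = 1000L) {
  df <- data.frame(Name = name, Length = length,
                   EffectiveLength = length - 199L, TPM = tpm,
                   NumReads = tpm * 10, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_t2g_fixture <- function(path, transcript_id = c("t1", "t2", "t3"),
                              gene_id = c("g1", "g1", "g2")) {
  write.table(data.frame(transcript_id, gene_id), path, sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  path
}

# Minimal two-gene GTF on one contig (1-based inclusive coordinates).
write_gtf_fixture <- function(path) {
  attr_line <- function(gene, tx) {
    sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  }
  lines <- c(
    paste("chrT", "test", "exon", 11, 25, ".", "+", ".",
          attr_line("gA", "gA.t1"), sep = "\t"),
    paste("chrT", "test", "exon", 36, 50, ".", "+", ".",
          attr_line("gA", "gA.t1"), sep = "\t"),
    paste("chrT", "test", "exon", 11, 50, ".", "+", ".",
          attr_line("gA", "gA.t2"), sep = "\t"),
    paste("chrT", "test", "exon", 5, 16, ".", "-", ".",
          attr_line("gB", "gB.t1"), sep = "\t"))
  writeLines(lines, path)
  path
}

# In-memory expression table rows (already parsed), for profile tests.
make_expr_table <- function(transcript_id, gene_id, expression,
                            sample_id = "s1", condition = "none") {
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             expression = expression, sample_id = sample_id,
             condition = condition, stringsAsFactors = FALSE)
}

# Profiles fixture for switch detection: one gene over subsets/conditions
# with a chosen top transcript in each.
make_switch_profiles <- function(gene_id, subsets, tops_by_condition) {
  profiles <- list()
  for (cond in names(tops_by_condition)) {
    tops <- tops_by_condition[[cond]]
    for (i in seq_along(tops)) {
      if (is.na(tops[i])) next
      profiles[[length(profiles) + 1L]] <- list(
        gene_id = gene_id, sample_id = subsets[i], condition = cond,
        M = 2L, E = 10,
        ranked_transcripts = c(tops[i], paste0(gene_id, ".other")),
        frequencies = c(0.7, 0.3))
    }
  }
  structure(profiles, class = "gene_profiles", dropped = 0L)
}
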