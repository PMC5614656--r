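#' Read an isoform quantification table
#'
#' Parses isoform-level expression output in either the Cufflinks/Cuffdiff
#' dialect (`isoforms.fpkm_tracking`: tab-separated with columns
#' `tracking_id`, `gene_id`, `FPKM`) or the Salmon dialect (`quant.sf`:
#' columns `Name`, `Length`, `EffectiveLength`, `TPM`, `NumReads`). Salmon
#' output carries no gene identifiers, so a transcript-to-gene mapping is
#' required for that dialect. Rows with missing or negative expression are
#' reported with their file line numbers and dropped.
#'
#' @param path Path to the table (TSV with header).
#' @param dialect `"cufflinks"` or `"salmon"`.
#' @param t2g For the Salmon dialect: a data.frame with columns
#'   `transcript_id`, `gene_id`, or a path readable by [read_t2g()].
#' @param sample_id,condition Labels attached to every row (one file is
#'   one sample); used downstream for grouping and switch detection.
#' @return A data.frame of class `isoform_expr` with columns
#'   `transcript_id`, `gene_id`, `expression`, `sample_id`, `condition`.
#'   Expression is FPKM (cufflinks) or TPM (salmon).
#' @export
read_expression_table <- function(path, dialect = c("cufflinks", "salmon"),
                                  t2g = NULL, sample_id = "sample1",
                                  condition = "none") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)

  required <- switch(dialect,
    cufflinks = c("tracking_id", "gene_id", "FPKM"),
    salmon    = c("Name", "Length", "EffectiveLength", "TPM", "NumReads"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("%s table is missing required column(s): %s",
          dialect, paste(missing_cols, collapse = ", "))

  if (dialect == "cufflinks") {
    out <- data.frame(transcript_id = as.character(df$tracking_id),
                      gene_id = as.character(df$gene_id),
                      expression = suppressWarnings(as.numeric(df$FPKM)),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(t2g)) stopf("salmon dialect requires a transcript-to-gene mapping (`t2g`)")
    if (is.character(t2g) && length(t2g) == 1L) t2g <- read_t2g(t2g)
    if (!all(c("transcript_id", "gene_id") %in% names(t2g)))
      stopf("`t2g` must have columns transcript_id and gene_id")
    gene <- t2g$gene_id[match(as.character(df$Name), t2g$transcript_id)]
    out <- data.frame(transcript_id = as.character(df$Name),
                      gene_id = as.character(gene),
                      expression = suppressWarnings(as.numeric(df$TPM)),
                      stringsAsFactors = FALSE)
  }

  bad <- which(!is.finite(out$expression) | out$expression < 0)
  if (length(bad)) {
    warning(sprintf("dropping %d malformed row(s) at file line(s) %s",
                    length(bad),
                    paste(utils::head(bad + 1L, 10), collapse = ", ")),
            call. = FALSE)
    out <- out[-bad, , drop = FALSE]
  }
  dup <- duplicated(out$transcript_id)
  if (any(dup))
    stopf("duplicate transcript id(s) in one sample: %s",
          paste(utils::head(unique(out$transcript_id[dup]), 5), collapse = ", "))

  out$sample_id <- sample_id
  out$condition <- condition
  class(out) <- c("isoform_expr", "data.frame")
  out
}

#' Read a two-column transcript-to-gene mapping
#'
#' Tab-separated, two columns (transcript id, gene id); a header row of
#' `transcript_id<TAB>gene_id` is detected and skipped.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `transcript_id`, `gene_id`.
#' @export
read_t2g <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("t2g mapping must have two columns")
  if (identical(tolower(as.character(df[1, 1:2])), c("transcript_id", "gene_id")))
    df <- df[-1, , drop = FALSE]
  data.frame(transcript_id = as.character(df[[1]]),
             gene_id = as.character(df[[2]]), stringsAsFactors = FALSE)
}

#' Annotated isoform counts per gene from a GTF file
#'
#' Counts distinct transcript ids per gene id in a GTF annotation. The
#' annotated count `M` — not the number of isoforms detected in any one
#' sample — defines the gene's group throughout the package.
#'
#' @param path GTF file path (imported via \pkg{rtracklayer}, 1-based
#'   inclusive coordinates), or a data.frame/vector accepted by
#'   [as_isoform_counts()].
#' @return Named integer vector: gene id to isoform count `M`.
#' @export
isoform_counts_from_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!all(c("gene_id", "transcript_id") %in% names(df)))
    stopf("GTF lacks gene_id/transcript_id attributes")
  df <- unique(df[!is.na(df$transcript_id), c("gene_id", "transcript_id")])
  counts <- table(df$gene_id)
  stats::setNames(as.integer(counts), names(counts))
}

#' Coerce to a gene-to-isoform-count mapping
#'
#' @param x A named integer vector (gene id to `M`), a data.frame with
#'   columns `gene_id` and `M`, or a t2g data.frame (counts derived by
#'   tabulating transcripts per gene).
#' @return Named integer vector.
#' @export
as_isoform_counts <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(stats::setNames(as.integer(x), names(x)))
  if (is.data.frame(x)) {
    if (all(c("gene_id", "M") %in% names(x)))
      return(stats::setNames(as.integer(x$M), as.character(x$gene_id)))
    if (all(c("transcript_id", "gene_id") %in% names(x))) {
      counts <- table(unique(x[c("gene_id", "transcript_id")])$gene_id)
      return(stats::setNames(as.integer(counts), names(counts)))
    }
  }
  stopf("cannot interpret `x` as gene-to-isoform-count mapping")
}

#' Build ranked isoform-frequency profiles per gene and sample
#'
#' For each (gene, sample) pair, collects the expression of all annotated
#' isoforms (isoforms absent from the table enter with expression 0),
#' computes total gene expression `E`, excludes genes with
#' `E <= min_gene_expr` (the conventional FPKM/TPM > 1 filter, applied per
#' sample), and converts expression to descending frequencies
#' `f(1) >= f(2) >= ... >= f(M)` summing to 1. Rank ties are broken
#' lexicographically by transcript id so profiles are reproducible.
#' Transcripts whose gene is absent from the annotation are dropped and
#' counted in the `dropped` attribute.
#'
#' @param table An `isoform_expr` data.frame ([read_expression_table()]);
#'   multiple samples may be row-bound first.
#' @param annotation_counts Gene-to-`M` mapping ([as_isoform_counts()]).
#' @param min_gene_expr Gene expression filter (default 1): genes with
#'   `E <= min_gene_expr` are excluded.
#' @return An object of class `gene_profiles`: a list of profiles, each a
#'   list with `gene_id`, `sample_id`, `condition`, `M`, `E`,
#'   `ranked_transcripts` and `frequencies` (both length `M`, descending).
#'   Attribute `dropped` counts transcripts with unknown genes.
#' @examples
#' tab <- data.frame(transcript_id = c("t1", "t2", "t3"),
#'                   gene_id = "g1", expression = c(6, 3, 1),
#'                   sample_id = "s1", condition = "none")
#' p <- build_gene_profiles(tab, c(g1 = 3))
#' p[[1]]$frequencies  # 0.6 0.3 0.1
#' @export
build_gene_profiles <- function(table, annotation_counts, min_gene_expr = 1) {
  annotation_counts <- as_isoform_counts(annotation_counts)
  needed <- c("transcript_id", "gene_id", "expression", "sample_id", "condition")
  if (!all(needed %in% names(table)))
    stopf("`table` must have columns: %s", paste(needed, collapse = ", "))

  known <- table$gene_id %in% names(annotation_counts) & !is.na(table$gene_id)
  n_dropped <- sum(!known)
  if (n_dropped > 0)
    message(sprintf("%d transcript row(s) with unknown gene dropped", n_dropped))
  table <- table[known, , drop = FALSE]

  keys <- interaction(table$gene_id, table$sample_id, table$condition,
                      drop = TRUE, sep = "\r")
  profiles <- lapply(split(seq_len(nrow(table)), keys), function(ix) {
    rows <- table[ix, , drop = FALSE]
    gene <- rows$gene_id[1]
    M <- unname(annotation_counts[[gene]])
    expr <- rows$expression
    tx <- rows$transcript_id
    if (length(tx) < M) {
      pad <- M - length(tx)
      tx <- c(tx, sprintf("%s.unobserved%d", gene, seq_len(pad)))
      expr <- c(expr, rep(0, pad))
    } else if (length(tx) > M) {
      warning(sprintf("gene %s: %d isoforms observed but %d annotated; using %d",
                      gene, length(tx), M, length(tx)), call. = FALSE)
      M <- length(tx)
    }
    E <- sum(expr)
    if (E <= min_gene_expr) return(NULL)
    ord <- order(-expr, tx)
    list(gene_id = gene, sample_id = rows$sample_id[1],
         condition = rows$condition[1], M = as.integer(M), E = E,
         ranked_transcripts = tx[ord], frequencies = expr[ord] / E)
  })
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]
  names(profiles) <- NULL
  structure(profiles, class = "gene_profiles", dropped = n_dropped)
}

#' @export
print.gene_profiles <- function(x, ...) {
  cat(sprintf("gene_profiles: %d profiles over %d gene(s), %d sample(s)\n",
              length(x), length(unique(vapply(x, `[[`, "", "gene_id"))),
              length(unique(vapply(x, `[[`, "", "sample_id")))))
  invisible(x)
}

#' Group profiles by annotated isoform count
#'
#' Pools the frequency vectors of all profiles (across samples and
#' conditions) into one matrix per isoform count `M`.
#'
#' @param profiles A `gene_profiles` object.
#' @return Named list: `M` (as character) to a matrix whose rows are
#'   descending frequency vectors.
#' @export
group_by_isoform_count <- function(profiles) {
  if (length(profiles) == 0L) return(list())
  Ms <- vapply(profiles, `[[`, 0L, "M")
  groups <- lapply(split(seq_along(profiles), Ms), function(ix) {
    do.call(rbind, lapply(profiles[ix], `[[`, "frequencies"))
  })
  groups
}

#' Write/read gene profiles as a long-format TSV
#'
#' One row per (gene, sample, rank): columns `gene_id`, `sample_id`,
#' `condition`, `M`, `E`, `k`, `transcript_id`, `frequency`. This is the
#' interchange format between pipeline stages.
#'
#' @param profiles A `gene_profiles` object.
#' @param path Output TSV path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()`
#'   reconstructs the `gene_profiles` object.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(gene_id = p$gene_id, sample_id = p$sample_id,
               condition = p$condition, M = p$M, E = p$E,
               k = seq_len(p$M), transcript_id = p$ranked_transcripts,
               frequency = p$frequencies, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- interaction(df$gene_id, df$sample_id, df$condition,
                      drop = TRUE, sep = "\r")
  profiles <- lapply(split(seq_len(nrow(df)), keys), function(ix) {
    rows <- df[ix, , drop = FALSE]
    rows <- rows[order(rows$k), , drop = FALSE]
    list(gene_id = as.character(rows$gene_id[1]),
         sample_id = as.character(rows$sample_id[1]),
         condition = as.character(rows$condition[1]),
         M = as.integer(rows$M[1]), E = rows$E[1],
         ranked_transcripts = as.character(rows$transcript_id),
         frequencies = rows$frequency)
  })
  names(profiles) <- NULL
  structure(profiles, class = "gene_profiles", dropped = 0L)
}
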