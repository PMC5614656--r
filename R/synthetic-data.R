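#' Read-simulator configuration
#'
#' Geometry and bookkeeping of the paired-end read simulator: each
#' fragment is `read_length + insert_length + read_length` bases (default
#' 100 + 100 + 100 = 300), with mate 1 the fragment's 5' end and mate 2
#' the reverse complement of its 3' end. Insert length is fixed (no
#' fragment-length variance), base qualities are a constant symbol, and
#' read names encode the source transcript and pair index so simulated
#' data can be re-quantified from truth.
#'
#' @param read_length Bases per mate (default 100).
#' @param insert_length Bases between mates (default 100).
#' @param replicates Number of replicate FASTQ datasets (default 10);
#'   replicate `r` uses a sub-seed derived from `(seed, r)`.
#' @param quality_char Single FASTQ quality symbol (default `"I"`,
#'   Phred 40).
#' @param seed Master seed.
#' @return An object of class `"read_sim_config"`.
#' @export
read_sim_config <- function(read_length = 100, insert_length = 100,
                            replicates = 10, quality_char = "I", seed = 1) {
  if (read_length <= 0) stopf("`read_length` must be > 0")
  if (insert_length < 0) stopf("`insert_length` must be >= 0")
  if (replicates < 1) stopf("`replicates` must be >= 1")
  if (nchar(quality_char) != 1L) stopf("`quality_char` must be one character")
  structure(list(read_length = as.integer(read_length),
                 insert_length = as.integer(insert_length),
                 replicates = as.integer(replicates),
                 quality_char = quality_char, seed = as.integer(seed)),
            class = "read_sim_config")
}

fragment_length <- function(config) 2L * config$read_length + config$insert_length

# Annotation skeleton shared by the transcriptome and expression-table
# generators: gene/transcript ids, per-gene isoform count M, lengths.
synthetic_annotation <- function(n_genes, M = 2, length_range = c(500, 2000),
                                 seed = NULL) {
  if (n_genes < 1) stopf("`n_genes` must be >= 1")
  if (is.function(M)) M <- M(n_genes)
  M <- as.integer(rep_len(M, n_genes))
  if (any(M < 1)) stopf("isoform counts must be >= 1")
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    rows <- data.frame(
      gene_id = rep(gene_id, M),
      transcript_id = unlist(lapply(seq_len(n_genes), function(i) {
        sprintf("%s.t%02d", gene_id[i], seq_len(M[i]))
      })),
      M = rep(M, M),
      stringsAsFactors = FALSE
    )
    rows$length <- sample.int(length_range[2] - length_range[1] + 1L,
                              nrow(rows), replace = TRUE) +
      as.integer(length_range[1]) - 1L
    rows
  })
}

#' Generate a synthetic transcriptome
#'
#' Random transcript sequences (uniform A/C/G/T) with a gene/transcript
#' annotation, standing in for a reference transcriptome so every
#' downstream stage can be exercised without downloads. Deterministic
#' under `seed`.
#'
#' @param n_genes Number of genes, `>= 1`.
#' @param M Isoform count per gene: a scalar, a vector of length
#'   `n_genes`, or a function of `n` returning one.
#' @param length_range Transcript length range in bases (default
#'   `c(500, 2000)`); the lower bound must be at least `min_length`
#'   unless `allow_short`.
#' @param seed Integer seed.
#' @param min_length Read-geometry minimum (default 300, one fragment).
#' @param allow_short Permit transcripts below `min_length` (they will be
#'   skipped by the read simulator).
#' @return A list with `sequences` (a [Biostrings::DNAStringSet] named by
#'   transcript id) and `annotation` (data.frame: `gene_id`,
#'   `transcript_id`, `M`, `length`).
#' @export
synthetic_transcriptome <- function(n_genes, M = 2, length_range = c(500, 2000),
                                    seed = NULL, min_length = 300,
                                    allow_short = FALSE) {
  if (length_range[1] < min_length && !allow_short)
    stopf("minimum transcript length %d is below the read-geometry minimum %d",
          length_range[1], min_length)
  ann <- synthetic_annotation(n_genes, M, length_range, seed)
  seqs <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "seq"), {
    vapply(ann$length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
  })
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- ann$transcript_id
  list(sequences = sequences, annotation = ann)
}

#' Write a synthetic transcriptome to FASTA plus annotation TSV
#'
#' @param transcriptome Result of [synthetic_transcriptome()].
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcriptome <- function(transcriptome, fasta_path, annotation_path) {
  Biostrings::writeXStringSet(transcriptome$sequences, fasta_path)
  utils::write.table(transcriptome$annotation, annotation_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(fasta_path, annotation_path))
}

#' Extract spliced transcript sequences from a genome and annotation
#'
#' Concatenates each transcript's exon sequences in genomic order
#' (GTF coordinates, 1-based inclusive) and reverse-complements
#' minus-strand transcripts.
#'
#' @param genome A named [Biostrings::DNAStringSet] or FASTA path.
#' @param annotation A GTF path (imported via \pkg{rtracklayer}) or a
#'   data.frame with columns `seqnames`, `start`, `end`, `strand`,
#'   `type`, `transcript_id` (rows with `type == "exon"` are used).
#' @return A [Biostrings::DNAStringSet] named by transcript id.
#' @export
extract_transcript_sequences <- function(genome, annotation) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation)) {
    annotation <- as.data.frame(rtracklayer::import(annotation))
  }
  ex <- annotation[annotation$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stopf("annotation contains no exon records")
  out <- lapply(split(ex, ex$transcript_id), function(rows) {
    rows <- rows[order(rows$start), , drop = FALSE]
    chr <- as.character(rows$seqnames[1])
    if (!chr %in% names(genome))
      stopf("transcript %s: sequence %s absent from genome",
            rows$transcript_id[1], chr)
    L <- length(genome[[chr]])
    if (any(rows$start < 1) || any(rows$end > L))
      stopf("transcript %s: exon outside genome bounds", rows$transcript_id[1])
    s <- do.call(Biostrings::xscat, lapply(seq_len(nrow(rows)), function(i) {
      Biostrings::subseq(genome[[chr]], rows$start[i], rows$end[i])
    }))
    if (as.character(rows$strand[1]) == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  })
  Biostrings::DNAStringSet(unlist(out))
}

#' Draw per-transcript expression levels from a named law
#'
#' Assigns each annotated transcript an independent expression draw:
#' per gene, its `M` isoform levels. Supported laws are
#' `"normal(mu,sd)"` (truncated at 0 by redrawing; at the default 10
#' standard deviations from 0 the truncation is negligible) and
#' `"weibull(a,b)"`.
#'
#' @param annotation Data.frame with a `transcript_id` column (e.g. from
#'   [synthetic_transcriptome()]).
#' @param law Law string, e.g. `"weibull(0.39,10)"` or `"normal(20,2)"`.
#' @param seed Integer seed.
#' @return Named numeric vector: transcript id to expression `E`.
#' @export
assign_expression <- function(annotation, law = "weibull(0.39,10)", seed = NULL) {
  parsed <- parse_expression_law(law)
  n <- nrow(annotation)
  E <- with_seed(seed, {
    if (parsed$family == "normal") {
      x <- stats::rnorm(n, parsed$par[1], parsed$par[2])
      while (any(x < 0)) {
        i <- x < 0
        x[i] <- stats::rnorm(sum(i), parsed$par[1], parsed$par[2])
      }
      x
    } else {
      stats::qweibull(stats::runif(n), shape = parsed$par[1], scale = parsed$par[2])
    }
  })
  stats::setNames(E, annotation$transcript_id)
}

parse_expression_law <- function(law) {
  m <- regmatches(law, regexec("^\\s*(normal|weibull)\\s*\\(([^,]+),([^)]+)\\)\\s*$", law))[[1]]
  if (length(m) != 4L)
    stopf("unknown expression law: %s (expected normal(mu,sd) or weibull(a,b))", law)
  par <- as.numeric(c(m[3], m[4]))
  if (any(!is.finite(par)) || par[2] <= 0) stopf("invalid law parameters in %s", law)
  list(family = m[2], par = par)
}

#' Read-pair count for a transcript
#'
#' The number of simulated read pairs for a transcript of length `L` at
#' expression `E` is `R = int(E * L / 100 / 2 + 0.5)` — round-half-up of
#' `E * L / 200`, so that `R` pairs of 100-base mates reconstruct an
#' expression of about `E` per 100 bases of transcript.
#'
#' @param E Expression level(s), `>= 0`.
#' @param L Transcript length(s) in bases, `> 0`.
#' @return Integer pair count(s).
#' @examples
#' read_pair_count(20, 1000)  # 100
#' @export
read_pair_count <- function(E, L) {
  if (any(E < 0)) stopf("`E` must be >= 0")
  if (any(L <= 0)) stopf("`L` must be > 0")
  as.integer(E * L / 100 / 2 + 0.5)
}

#' Simulate paired-end reads from one transcript
#'
#' Draws `R` fragments with uniformly random start positions over the
#' valid range, giving flat expected coverage over the transcript
#' interior. Mate 1 is the fragment's leading `read_length` bases; mate 2
#' is the reverse complement of its trailing `read_length` bases.
#'
#' @param sequence Transcript sequence (character or
#'   [Biostrings::DNAString]), length at least one fragment
#'   (`2 * read_length + insert_length`).
#' @param R Number of read pairs.
#' @param config A [read_sim_config()].
#' @param transcript_id Name prefix for read names
#'   (`<transcript_id>_pair<i>`).
#' @return A list with character vectors `read1`, `read2` (named by read
#'   name) and integer `starts`; `NULL` (with a warning) when the
#'   transcript is shorter than one fragment.
#' @export
simulate_read_pairs <- function(sequence, R, config = read_sim_config(),
                                transcript_id = "tx") {
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  frag <- fragment_length(config)
  if (L < frag) {
    warning(sprintf("transcript %s (length %d) shorter than fragment %d: skipped",
                    transcript_id, L, frag), call. = FALSE)
    return(NULL)
  }
  if (R == 0L) {
    return(list(read1 = character(0), read2 = character(0), starts = integer(0)))
  }
  starts <- sample.int(L - frag + 1L, R, replace = TRUE)
  rl <- config$read_length
  read1 <- substring(sequence, starts, starts + rl - 1L)
  ends <- starts + frag - 1L
  read2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(sequence, ends - rl + 1L, ends))))
  nm <- sprintf("%s_pair%06d", transcript_id, seq_len(R))
  list(read1 = stats::setNames(read1, nm),
       read2 = stats::setNames(read2, nm), starts = starts)
}

write_fastq <- function(reads, path, quality_char, gzip = FALSE) {
  qual <- vapply(nchar(reads), function(n) strrep(quality_char, n), "")
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads), "+", qual))
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a replicated paired-end RNA-seq experiment
#'
#' For each replicate, draws fresh expression levels from `law`, computes
#' per-transcript pair counts with [read_pair_count()], simulates uniform
#' fragment positions and writes a pair of FASTQ files
#' (`<prefix>_rep<r>_1.fastq[.gz]`, `_2`). Transcripts shorter than one
#' fragment are skipped and counted. Replicate `r` uses a sub-seed
#' derived from `(seed, r)`.
#'
#' @param transcriptome Result of [synthetic_transcriptome()] (or a list
#'   with `sequences` and `annotation` in that shape).
#' @param law Expression law string (see [assign_expression()]).
#' @param config A [read_sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @param gzip Write gzip-compressed FASTQ (default `FALSE`).
#' @return A list with `files` (data.frame: replicate, mate1, mate2),
#'   `truth` (data.frame: replicate, transcript_id, length, E, pairs),
#'   and `skipped` (transcript ids below fragment length).
#' @export
simulate_rnaseq <- function(transcriptome, law = "weibull(0.39,10)",
                            config = read_sim_config(), out_dir = ".",
                            prefix = "sim", gzip = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- transcriptome$annotation
  seqs <- as.character(transcriptome$sequences)[ann$transcript_id]
  frag <- fragment_length(config)
  short <- ann$transcript_id[ann$length < frag]

  files <- NULL; truth <- NULL
  for (r in seq_len(config$replicates)) {
    rseed <- derive_seed(config$seed, r)
    E <- assign_expression(ann, law, seed = rseed)
    pairs <- read_pair_count(E, ann$length)
    rec1 <- vector("list", nrow(ann)); rec2 <- vector("list", nrow(ann))
    with_seed(derive_seed(rseed, "reads"), {
      for (i in seq_len(nrow(ann))) {
        if (ann$transcript_id[i] %in% short) next
        rp <- simulate_read_pairs(seqs[i], pairs[i], config,
                                  transcript_id = ann$transcript_id[i])
        rec1[[i]] <- rp$read1; rec2[[i]] <- rp$read2
      }
    })
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    f1 <- file.path(out_dir, sprintf("%s_rep%d_1%s", prefix, r, ext))
    f2 <- file.path(out_dir, sprintf("%s_rep%d_2%s", prefix, r, ext))
    write_fastq(unlist(rec1), f1, config$quality_char, gzip)
    write_fastq(unlist(rec2), f2, config$quality_char, gzip)
    files <- rbind(files, data.frame(replicate = r, mate1 = f1, mate2 = f2,
                                     stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      replicate = r, transcript_id = ann$transcript_id, length = ann$length,
      E = unname(E),
      pairs = ifelse(ann$transcript_id %in% short, 0L, pairs),
      stringsAsFactors = FALSE))
  }
  if (length(short))
    warning(sprintf("%d transcript(s) shorter than one fragment skipped",
                    length(short)), call. = FALSE)
  list(files = files, truth = truth, skipped = short)
}

#' Truth-based re-quantification of simulated reads
#'
#' Counts read pairs per source transcript from the read names of a
#' simulated mate-1 FASTQ and inverts [read_pair_count()]:
#' `E_hat = 200 * R / L`. Recovery is exact up to the rounding granularity
#' `200 / L` of the pair-count formula.
#'
#' @param fastq1 Path to the mate-1 FASTQ (plain or gzip).
#' @param lengths Named vector of transcript lengths.
#' @return Data.frame with `transcript_id`, `pairs`, `E_hat`.
#' @export
requantify_reads <- function(fastq1, lengths) {
  reads <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  tx <- sub("_pair[0-9]+$", "", names(reads))
  counts <- table(tx)
  ids <- names(counts)
  if (any(!ids %in% names(lengths)))
    stopf("read names reference transcripts absent from `lengths`")
  data.frame(transcript_id = ids, pairs = as.integer(counts),
             E_hat = 200 * as.integer(counts) / as.numeric(lengths[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a ready-to-parse Salmon-dialect expression table
#'
#' Builds a synthetic annotation, draws per-transcript expression from
#' `law`, and lays the result out as a `quant.sf`-style table whose TPM
#' column carries the assigned expression values. The returned truth
#' objects (transcript-to-gene map and per-gene isoform counts) let every
#' downstream module run without any external quantifier.
#'
#' @param n_genes Number of genes.
#' @param M Isoform count specification (see [synthetic_transcriptome()]).
#' @param law Expression law string (default `"weibull(0.39,10)"`).
#' @param seed Integer seed.
#' @param length_range Transcript length range (default `c(500, 2000)`).
#' @param path Optional TSV output path; when given, the table is written
#'   there (and `t2g` alongside as `<path>.t2g.tsv`).
#' @return A list with `table` (the Salmon-dialect data.frame), `t2g`
#'   (transcript-to-gene data.frame), `counts` (named gene-to-M vector)
#'   and `truth` (named expression vector).
#' @export
expression_table <- function(n_genes, M = 2, law = "weibull(0.39,10)",
                             seed = NULL, length_range = c(500, 2000),
                             path = NULL) {
  ann <- synthetic_annotation(n_genes, M, length_range, seed)
  E <- assign_expression(ann, law,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, "expr"))
  tab <- data.frame(
    Name = ann$transcript_id,
    Length = ann$length,
    EffectiveLength = pmax(ann$length - 200L, 1L),
    TPM = unname(E),
    NumReads = read_pair_count(E, ann$length),
    stringsAsFactors = FALSE
  )
  t2g <- data.frame(transcript_id = ann$transcript_id, gene_id = ann$gene_id,
                    stringsAsFactors = FALSE)
  counts <- as_isoform_counts(unique(ann[c("gene_id", "M")]))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(t2g, paste0(path, ".t2g.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE, col.names = FALSE)
  }
  list(table = tab, t2g = t2g, counts = counts, truth = E)
}
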