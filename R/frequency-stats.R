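#' @name frequency_matrix
#' @title The rank-by-isoform-count median-frequency matrix
#'
#' @description
#' A `frequency_matrix` is a plain numeric matrix with rows indexed by
#' isoform rank `k = 1..k_max` (default 9) and columns by annotated
#' isoform count `M = 1..M_max` (default 30). Cell `(k, M)` holds the
#' median frequency `mf(k, M)` of the `k`-th most dominant isoform over
#' all genes with `M` isoforms; cells with `k > M` (and columns with no
#' genes) are masked as `NA`. Matrices from empirical profiles, from
#' Monte-Carlo simulation and from the closed-form approximation share
#' this layout and are compared by [matrix_distance()].
NULL

empty_frequency_matrix <- function(k_max = 9, M_max = 30) {
  structure(
    matrix(NA_real_, nrow = k_max, ncol = M_max,
           dimnames = list(k = seq_len(k_max), M = seq_len(M_max))),
    class = c("frequency_matrix", "matrix")
  )
}

#' Median-frequency matrix from grouped frequency vectors
#'
#' @param groups A named list mapping isoform count `M` (as name) to a
#'   matrix of descending frequency vectors (rows = genes), as returned by
#'   [group_by_isoform_count()] or [simulate_frequency_groups()].
#' @param k_max,M_max Matrix extent; see [frequency_matrix].
#' @return A `frequency_matrix` of per-rank sample medians. Columns for
#'   `M` values with no genes remain `NA`.
#' @export
median_frequency_matrix <- function(groups, k_max = 9, M_max = 30) {
  if (length(groups) == 0L) stopf("`groups` must be nonempty")
  mat <- empty_frequency_matrix(k_max, M_max)
  for (nm in names(groups)) {
    M <- as.integer(nm)
    if (is.na(M) || M < 1 || M > M_max) next
    f <- groups[[nm]]
    if (is.null(f) || NROW(f) == 0L) next
    f <- if (is.matrix(f)) f else matrix(f, nrow = 1)
    for (k in seq_len(min(k_max, M))) {
      mat[k, M] <- stats::median(f[, k])
    }
  }
  mat
}

#' Euclidean distance between two frequency matrices
#'
#' The square root of the summed squared differences over unmasked cells
#' (`k = 1..k_max`, `M = k..M_max`); masked (`NA`) cells contribute zero.
#' Both matrices must have the same extent. If one matrix has additional
#' masked columns (for instance, empirical data with no genes at some
#' `M`), those cells are excluded from the sum.
#'
#' @param f1,f2 `frequency_matrix` objects of identical dimension.
#' @return Nonnegative distance.
#' @export
matrix_distance <- function(f1, f2) {
  if (!all(dim(f1) == dim(f2)))
    stopf("frequency matrices have different extents (%dx%d vs %dx%d)",
          nrow(f1), ncol(f1), nrow(f2), ncol(f2))
  d2 <- (f1 - f2)^2
  sqrt(sum(d2[!is.na(d2)]))
}

#' Write/read a frequency matrix as CSV
#'
#' The on-disk layout is `k_max` rows by `M_max` columns with a header of
#' `M` values and a leading `k` column; masked cells are empty.
#'
#' @param mat A `frequency_matrix`.
#' @param path Output CSV path.
#' @return `write_frequency_matrix()` returns `path` invisibly;
#'   `read_frequency_matrix()` returns the matrix.
#' @export
write_frequency_matrix <- function(mat, path) {
  df <- data.frame(k = seq_len(nrow(mat)), mat, check.names = FALSE)
  names(df) <- c("k", colnames(mat))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_frequency_matrix
#' @export
read_frequency_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  structure(mat, dimnames = list(k = df$k, M = colnames(mat)),
            class = c("frequency_matrix", "matrix"))
}

#' Binned frequency distribution
#'
#' Normalized histogram of isoform frequencies on equal-width bins, the
#' operand of [kl_divergence()] and [shannon_entropy()].
#'
#' @param x Values inside `range` (frequencies live on `[0, 1]`).
#' @param n_bins Number of equal-width bins (default 40).
#' @param range Support, default `c(0, 1)`.
#' @return An object of class `"binned_dist"`: list with `edges` (length
#'   `n_bins + 1`) and `p` (probabilities summing to 1).
#' @export
binned_distribution <- function(x, n_bins = 40, range = c(0, 1)) {
  if (length(x) == 0L) stopf("`x` must be nonempty")
  if (any(x < range[1] - 1e-12) || any(x > range[2] + 1e-12))
    stopf("values outside the binning range")
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE,
                           include.lowest = TRUE)$counts
  structure(list(edges = edges, p = counts / sum(counts)),
            class = "binned_dist")
}

check_binned <- function(P) {
  if (!inherits(P, "binned_dist")) {
    if (is.numeric(P)) {
      if (any(P < 0) || abs(sum(P) - 1) > 1e-9)
        stopf("probabilities must be >= 0 and sum to 1")
      P <- structure(list(edges = seq(0, 1, length.out = length(P) + 1L),
                          p = P), class = "binned_dist")
    } else {
      stopf("expected a binned_dist or a probability vector")
    }
  }
  P
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `KLd(P || Q) = sum_i P(i) * log(P(i) / Q(i))` in nats over bins with
#' `P(i) > 0`: the information lost when `Q` (typically the Weibull-model
#' simulation) is used to approximate `P` (typically the empirical
#' frequency distribution). If `Q` has empty bins where `P` has mass, a
#' pseudo-mass of 1e-9 is added to every bin of `Q` and `Q` renormalized
#' before the sum, so the divergence stays finite; when `Q` covers `P`
#' no adjustment is made and `kl_divergence(P, P)` is exactly 0.
#'
#' @param P,Q `binned_dist` objects (or bare probability vectors) on
#'   identical bin edges.
#' @return Divergence in nats, `>= 0`.
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))  # 0.5*log(2) + 0.5*log(2/3)
#' @export
kl_divergence <- function(P, Q) {
  P <- check_binned(P); Q <- check_binned(Q)
  if (length(P$p) != length(Q$p) ||
      max(abs(P$edges - Q$edges)) > 1e-12)
    stopf("P and Q must share identical bin edges")
  q <- Q$p
  if (any(q == 0 & P$p > 0)) {
    q <- q + 1e-9
    q <- q / sum(q)
  }
  i <- P$p > 0
  sum(P$p[i] * log(P$p[i] / q[i]))
}

#' Shannon entropy of a binned distribution
#'
#' Reported in the conventional nonnegative form `-sum_i P(i) log P(i)`
#' in nats. (The information-content formula is sometimes displayed
#' without the leading minus; this function always returns the
#' nonnegative convention.)
#'
#' @param P A `binned_dist` or probability vector.
#' @return Entropy in nats, `>= 0`.
#' @export
shannon_entropy <- function(P) {
  P <- check_binned(P)
  i <- P$p > 0
  -sum(P$p[i] * log(P$p[i]))
}

#' Count expressed isoforms per gene at a frequency cutoff
#'
#' An isoform counts as expressed when its frequency is at least
#' `cutoff` (boundary inclusive). With the model's heavy-tailed expression
#' law most isoforms carry a small but nonzero share, so the expressed
#' count grows with the annotated count `M`; the default cutoff 0.001
#' defines "theoretically detectable".
#'
#' @param profiles A `gene_profiles` object (see [build_gene_profiles()]).
#' @param cutoff Frequency cutoff in (0, 1), default 0.001. A cutoff of 0
#'   counts all `M` isoforms of any expressed gene.
#' @return A list with `counts` (data.frame: `gene_id`, `sample_id`, `M`,
#'   `n_expressed`) and `summary` (data.frame per `M`: `n_genes`, `q1`,
#'   `median`, `q3` of the expressed count).
#' @export
expressed_isoform_counts <- function(profiles, cutoff = 0.001) {
  if (cutoff < 0 || cutoff >= 1) stopf("`cutoff` must be in [0, 1)")
  counts <- data.frame(
    gene_id   = vapply(profiles, `[[`, "", "gene_id"),
    sample_id = vapply(profiles, `[[`, "", "sample_id"),
    M         = vapply(profiles, `[[`, 0L, "M"),
    n_expressed = vapply(profiles, function(p) {
      if (cutoff == 0) p$M else sum(p$frequencies >= cutoff)
    }, 0L),
    stringsAsFactors = FALSE
  )
  summ <- do.call(rbind, lapply(split(counts$n_expressed, counts$M), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n_genes = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }))
  summ <- data.frame(M = as.integer(rownames(summ)), summ, row.names = NULL)
  list(counts = counts, summary = summ[order(summ$M), ])
}

#' Detect dominant-isoform switches between two conditions
#'
#' For each gene, compares the identity of the top-ranked (most dominant)
#' isoform between two conditions within each sample subset (for example,
#' sorted T-cell subsets). A subset votes only when the gene passes the
#' expression filter (i.e. has a profile) in both conditions of that
#' subset. Genes are reported with the number of subsets tested, the
#' number in which the dominant isoform switched, and a category:
#' `"all"` (switched in every tested subset), `"all_but_one"`, or
#' `"other"`. Genes absent from some subsets are flagged `partial`.
#'
#' @param profiles A `gene_profiles` object whose elements carry
#'   `sample_id` (the subset label) and `condition`.
#' @param condition_pair Character vector of the two condition labels,
#'   e.g. `c("resting", "activated")`.
#' @return A data.frame with one row per gene tested in at least one
#'   subset: `gene_id`, `n_subsets`, `n_tested`, `n_switched`,
#'   `category`, `partial`.
#' @export
detect_dominance_switches <- function(profiles, condition_pair) {
  if (length(condition_pair) != 2L)
    stopf("`condition_pair` must name exactly two conditions")
  conds <- vapply(profiles, `[[`, "", "condition")
  if (!all(condition_pair %in% conds))
    stopf("condition label(s) not present in profiles: %s",
          paste(setdiff(condition_pair, conds), collapse = ", "))
  keep <- conds %in% condition_pair
  profiles <- profiles[keep]
  conds <- conds[keep]
  genes <- vapply(profiles, `[[`, "", "gene_id")
  subsets <- vapply(profiles, `[[`, "", "sample_id")
  tops <- vapply(profiles, function(p) p$ranked_transcripts[1], "")
  all_subsets <- unique(subsets)
  key <- paste(genes, subsets, conds, sep = "\r")
  top_by_key <- tops[!duplicated(key)]
  names(top_by_key) <- key[!duplicated(key)]

  out <- lapply(unique(genes), function(g) {
    tested <- 0L; switched <- 0L
    for (s in all_subsets) {
      t1 <- top_by_key[paste(g, s, condition_pair[1], sep = "\r")]
      t2 <- top_by_key[paste(g, s, condition_pair[2], sep = "\r")]
      if (is.na(t1) || is.na(t2)) next
      tested <- tested + 1L
      if (t1 != t2) switched <- switched + 1L
    }
    if (tested == 0L) return(NULL)
    data.frame(gene_id = g, n_subsets = length(all_subsets),
               n_tested = tested, n_switched = switched,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, out)
  rep_df$category <- ifelse(
    rep_df$n_switched == rep_df$n_tested & rep_df$n_switched > 0, "all",
    ifelse(rep_df$n_switched == rep_df$n_tested - 1L & rep_df$n_switched > 0,
           "all_but_one", "other"))
  rep_df$partial <- rep_df$n_tested < rep_df$n_subsets
  rep_df
}
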