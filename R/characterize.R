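#' Convert a count matrix to TPM
#'
#' Per column: `rate_i = count_i / length_i`, `TPM_i = rate_i / sum(rate) *
#' 1e6`. Every non-degenerate column of the result sums to one million.
#' All-zero columns stay all-zero (with a warning).
#'
#' @param counts count matrix (features x samples) or `ExpressionMatrix`
#'   with unit `"counts"`.
#' @param lengths named numeric vector of feature lengths in nt (> 0),
#'   covering every row.
#' @return same shape as the input; an `ExpressionMatrix` in, an
#'   `ExpressionMatrix` with unit `"TPM"` out.
#' @export
compute_tpm <- function(counts, lengths) {
  is_em <- inherits(counts, "ExpressionMatrix")
  v <- em_values(counts)
  m <- match(rownames(v), names(lengths))
  if (anyNA(m)) lnc_stop("lengths missing for some features")
  len <- as.numeric(lengths[m])
  if (any(len <= 0)) lnc_stop("feature lengths must be positive")
  rate <- v / len
  cs <- colSums(rate)
  dead <- cs == 0
  if (any(dead)) {
    lnc_warn(sum(dead), " all-zero columns left at zero in TPM output")
    cs[dead] <- 1
  }
  tpm <- sweep(rate, 2, cs, "/") * 1e6
  if (is_em) expression_matrix(tpm, counts$samples, unit = "TPM") else tpm
}

#' A/U content of a nucleotide sequence
#'
#' `(#A + #T) / (#A + #C + #G + #T)`; `N` bases are excluded from the
#' denominator. All-N sequences return `NA`.
#'
#' @param sequence character vector of DNA sequences (U already mapped to T).
#' @return numeric vector of A/U fractions in `[0, 1]`.
#' @export
au_content <- function(sequence) {
  if (any(!nzchar(sequence))) lnc_stop("empty sequence")
  s <- toupper(sequence)
  check_dna(s)
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(s))
  au <- counts[, "A"] + counts[, "T"]
  acgt <- au + counts[, "C"] + counts[, "G"]
  out <- unname(ifelse(acgt == 0, NA_real_, au / acgt))
  names(out) <- names(sequence)
  out
}

#' Exon statistics and a between-group comparison of mean exon length
#'
#' @param transcripts `GenomeAnnotation`.
#' @param groups optional named character vector mapping transcript_id to a
#'   group label (e.g. mRNA / lincRNA / NAT). When given, a Welch two-sample
#'   t-test on per-transcript mean exon length is run for each pair of
#'   groups, and per-group tables report the fraction of transcripts with
#'   fewer than 3 exons.
#' @return list with `per_transcript` (transcript_id, n_exons,
#'   mean_exon_length), and when `groups` is supplied `group_table`
#'   (group, n, mean_exon_length, frac_lt3_exons) and `tests` (group1,
#'   group2, t, df, p). Pairs with fewer than 2 transcripts in a group are
#'   skipped with a warning.
#' @export
exon_stats <- function(transcripts, groups = NULL) {
  tx <- transcripts$transcripts
  per <- data.frame(
    transcript_id = tx$transcript_id,
    n_exons = tx$n_exons,
    mean_exon_length = tx$length / tx$n_exons,
    row.names = NULL
  )
  out <- list(per_transcript = per)
  if (!is.null(groups)) {
    per$group <- groups[per$transcript_id]
    per <- per[!is.na(per$group), ]
    gt <- do.call(rbind, lapply(split(per, per$group), function(d) {
      data.frame(group = d$group[1], n = nrow(d),
                 mean_exon_length = mean(d$mean_exon_length),
                 frac_lt3_exons = mean(d$n_exons < 3))
    }))
    rownames(gt) <- NULL
    out$group_table <- gt
    labs <- sort(unique(per$group))
    tests <- list()
    for (i in seq_along(labs)) {
      for (j in seq_along(labs)) {
        if (j <= i) next
        a <- per$mean_exon_length[per$group == labs[i]]
        b <- per$mean_exon_length[per$group == labs[j]]
        if (length(a) < 2 || length(b) < 2) {
          lnc_warn("group with < 2 transcripts; t-test skipped for ",
                   labs[i], " vs ", labs[j])
          next
        }
        tt <- welch_t(a, b)
        tests[[length(tests) + 1L]] <- data.frame(
          group1 = labs[i], group2 = labs[j],
          t = tt$t, df = tt$df, p = tt$p
        )
      }
    }
    out$tests <- if (length(tests)) do.call(rbind, tests) else NULL
  }
  out
}

# internal: Welch two-sample t with the conventions the pipeline needs:
# zero pooled variance with equal means -> t = 0, p = 1; with unequal
# means -> p = 0 (flagged by the caller where relevant).
welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    if (d == 0) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(d) * Inf, df = na + nb - 2, p = 0))
  }
  t <- d / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# internal: per-tissue mean matrix (features x tissues)
tissue_means <- function(v, tissues) {
  labs <- unique(tissues)
  out <- vapply(labs, function(tl) {
    rowMeans(v[, tissues == tl, drop = FALSE])
  }, numeric(nrow(v)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(v),
                                       dimnames = list(rownames(v), labs))
  out
}

#' Tissue-specific expression calls
#'
#' A feature is called tissue-specific when its largest per-tissue mean TPM
#' strictly exceeds twice the second-largest mean (the "expressed more than
#' twice as much in one tissue as all the others" rule) and the largest
#' mean exceeds the expression floor of 1 TPM.
#'
#' @param tpm TPM matrix or `ExpressionMatrix`.
#' @param sample_tissues tissue label per column (taken from the
#'   `ExpressionMatrix` sample sheet when omitted).
#' @param ratio fold requirement over the second-largest tissue mean
#'   (default 2, strict).
#' @param floor expression floor on the top tissue mean (default 1, strict).
#' @return data.frame (`feature_id`, `specific`, `tissue`, plus one
#'   `mean_<tissue>` column per tissue); `tissue` is `NA` for
#'   non-specific features.
#' @export
tissue_specificity <- function(tpm, sample_tissues = NULL, ratio = 2, floor = 1) {
  v <- em_values(tpm)
  tissues <- em_tissues(tpm, sample_tissues)
  if (length(unique(tissues)) < 2) lnc_stop("need at least 2 tissues")
  tm <- tissue_means(v, tissues)
  top_i <- max.col(tm, ties.method = "first")
  top <- tm[cbind(seq_len(nrow(tm)), top_i)]
  second <- vapply(seq_len(nrow(tm)), function(i) {
    max(tm[i, -top_i[i]])
  }, 0)
  specific <- (top > ratio * second) & (top > floor)
  out <- data.frame(
    feature_id = rownames(v),
    specific = specific,
    tissue = ifelse(specific, colnames(tm)[top_i], NA_character_),
    row.names = NULL
  )
  colnames(tm) <- paste0("mean_", colnames(tm))
  cbind(out, as.data.frame(tm, row.names = NULL))
}

#' Number of tissues in which each feature is expressed
#'
#' @inheritParams tissue_specificity
#' @param threshold mean-TPM threshold (default 1, strict).
#' @return list with `counts` (named integer vector per feature) and
#'   `summary` (fraction of features expressed in exactly one tissue and in
#'   five or more tissues).
#' @export
expressed_tissue_count <- function(tpm, sample_tissues = NULL, threshold = 1) {
  v <- em_values(tpm)
  tissues <- em_tissues(tpm, sample_tissues)
  tm <- tissue_means(v, tissues)
  counts <- rowSums(tm > threshold)
  names(counts) <- rownames(v)
  list(
    counts = counts,
    summary = c(frac_one_tissue = mean(counts == 1),
                frac_five_plus = mean(counts >= 5))
  )
}

#' Fold-change-to-second-largest heatmap matrix
#'
#' Divides each row of a per-tissue expression matrix by its second-largest
#' value, the transformation behind the tissue-specificity heatmap: exactly
#' one entry per row exceeds 1 iff the row maximum is unique.
#'
#' @param m numeric matrix (features x tissues), typically per-tissue mean
#'   TPM.
#' @param eps divisor substitute when the second-largest value is 0
#'   (default 1e-6); affected rows are flagged.
#' @return list with `fold` (the transformed matrix) and `flagged_rows`
#'   (rownames where the second-largest value was 0).
#' @export
foldchange_heatmap_matrix <- function(m, eps = 1e-6) {
  if (ncol(m) < 2) lnc_stop("need at least 2 columns")
  second <- apply(m, 1, function(r) sort(r, decreasing = TRUE)[2])
  flagged <- second == 0
  denom <- ifelse(flagged, eps, second)
  list(fold = m / denom,
       flagged_rows = rownames(m)[flagged])
}

# internal: canonical k-mer set of one or more reference sequences
canonical_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1), k:n)
    km <- km[!grepl("N", km, fixed = TRUE)]
    rc <- revcomp(km)
    out <- c(out, pmin(km, rc))
  }
  unique(out)
}

#' Assign a feature sequence to a parental subgenome by k-mer containment
#'
#' Each reference (the two parental genomes of the allopolyploid) is indexed
#' as a canonical k-mer set over both strands. The score against a
#' reference is the fraction of the query's k-mers present in that set; the
#' call goes to the higher score and ties (including queries shorter than
#' `k`) are `unassigned`. This is a deterministic, database-free surrogate
#' for a blastn best-hit assignment; precomputed best-hit tables can be used
#' instead wherever a `SubgenomeCall`-shaped data.frame is accepted.
#'
#' @param sequences named character vector of query sequences.
#' @param s_reference,t_reference character vectors of reference chromosome
#'   sequences for the S and T subgenomes.
#' @param k k-mer size (default 31).
#' @return data.frame (`feature_id`, `call` in `{S, T, unassigned}`,
#'   `score_S`, `score_T`).
#' @export
assign_subgenome <- function(sequences, s_reference, t_reference, k = 31) {
  if (length(s_reference) == 0 || all(!nzchar(s_reference)) ||
      length(t_reference) == 0 || all(!nzchar(t_reference))) {
    lnc_stop("empty subgenome reference")
  }
  set_s <- canonical_kmers(s_reference, k)
  set_t <- canonical_kmers(t_reference, k)
  score <- function(q) {
    n <- nchar(q)
    if (n < k) return(c(NA_real_, NA_real_))
    km <- substring(toupper(q), 1:(n - k + 1), k:n)
    km <- pmin(km, revcomp(km))
    c(mean(km %in% set_s), mean(km %in% set_t))
  }
  sc <- t(vapply(sequences, score, numeric(2)))
  call <- ifelse(is.na(sc[, 1]) | sc[, 1] == sc[, 2], "unassigned",
                 ifelse(sc[, 1] > sc[, 2], "S", "T"))
  data.frame(feature_id = names(sequences), call = call,
             score_S = sc[, 1], score_T = sc[, 2], row.names = NULL)
}

#' Pearson chi-square test of subgenome asymmetry
#'
#' Tests whether subgenome-of-origin proportions differ between two feature
#' classes (e.g. lincRNA vs protein-coding) with Pearson's chi-square test
#' without continuity correction (df = 1 for a 2x2 table).
#'
#' @param class_counts 2x2 numeric matrix, rows = classes, columns = S/T.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
subgenome_asymmetry_test <- function(class_counts) {
  m <- as.matrix(class_counts)
  if (any(dim(m) < 2)) lnc_stop("need a table with at least 2 rows and 2 columns")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0)) lnc_stop("zero expected cell; test undefined")
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Per-class subgenome counts and percentages
#'
#' @param calls data.frame as returned by [assign_subgenome()] (or any
#'   data.frame with `feature_id` and `call`).
#' @param classes named character vector mapping feature_id to class.
#' @return data.frame (`class`, `n_S`, `n_T`, `n_unassigned`, `percent_S`,
#'   `percent_T`); percentages use S+T as the denominator (unassigned
#'   excluded), half-up rounded to 2 decimals, `NA` when S+T = 0.
#' @export
subgenome_summary <- function(calls, classes) {
  cls <- classes[calls$feature_id]
  keep <- !is.na(cls)
  cls <- cls[keep]
  call <- calls$call[keep]
  labs <- sort(unique(cls))
  out <- do.call(rbind, lapply(labs, function(lb) {
    s <- sum(call == "S" & cls == lb)
    t <- sum(call == "T" & cls == lb)
    u <- sum(call == "unassigned" & cls == lb)
    data.frame(
      class = lb, n_S = s, n_T = t, n_unassigned = u,
      percent_S = if (s + t == 0) NA_real_ else round_half_up(s / (s + t) * 100, 2),
      percent_T = if (s + t == 0) NA_real_ else round_half_up(t / (s + t) * 100, 2)
    )
  }))
  rownames(out) <- NULL
  out
}
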