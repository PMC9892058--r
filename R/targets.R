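#' Pearson correlation coefficient
#'
#' Product-moment correlation with the argument checks the target-pair
#' logic relies on (equal length, n >= 3, non-constant vectors).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) lnc_stop("x and y must have equal length")
  if (length(x) < 3) lnc_stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    lnc_stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}

#' Positional (cis) target assignment for lincRNAs
#'
#' A lincRNA and a gene on the same chromosome form a cis pair when the
#' distance between the midpoints of their genomic spans is strictly below
#' `window`. The relation is oriented by the gene's strand: a lincRNA
#' centred before the gene's transcription start is `cis_upstream`, after
#' its end `cis_downstream`, and within the gene span
#' `cis_overlapping_window`. A bin summary counts non-overlapping pairs
#' whose edge-to-edge gap is at most `near_bin` on each side.
#'
#' @param lincrnas data.frame with `transcript_id`, `chrom`, `start`, `end`
#'   (e.g. the transcripts table of a `GenomeAnnotation` subset to
#'   lincRNAs).
#' @param annotation reference `GenomeAnnotation`.
#' @param window centre-distance cut in bp (default 100000, strict).
#' @param near_bin edge-distance bin in bp (default 5000).
#' @return list with `pairs` (data.frame `lncRNA_id`, `gene_id`,
#'   `relation`, `center_distance`) and `near_summary` (counts of pairs
#'   within `near_bin` upstream / downstream).
#' @export
cis_targets <- function(lincrnas, annotation, window = 100000, near_bin = 5000) {
  g <- annotation$genes
  rows <- list()
  for (chrom in unique(lincrnas$chrom)) {
    lc <- lincrnas[lincrnas$chrom == chrom, , drop = FALSE]
    gc <- g[g$chrom == chrom, , drop = FALSE]
    if (nrow(gc) == 0) next
    gcent <- (gc$start + gc$end) / 2
    ord <- order(gcent)
    gc <- gc[ord, , drop = FALSE]
    gcent <- gcent[ord]
    for (i in seq_len(nrow(lc))) {
      lcent <- (lc$start[i] + lc$end[i]) / 2
      # genes with |centre - lcent| < window, via the sorted centre vector
      lo <- findInterval(lcent - window, gcent) + 1L
      hi <- findInterval(lcent + window, gcent)
      if (lo > hi) next
      for (j in lo:hi) {
        d <- abs(gcent[j] - lcent)
        if (d >= window) next
        if (lcent >= gc$start[j] && lcent <= gc$end[j]) {
          rel <- "cis_overlapping_window"
        } else {
          before <- lcent < gc$start[j]
          plus <- gc$strand[j] == "+"
          rel <- if (before == plus) "cis_upstream" else "cis_downstream"
        }
        gap <- max(0, max(lc$start[i], gc$start[j]) -
                        min(lc$end[i], gc$end[j]))
        rows[[length(rows) + 1L]] <- data.frame(
          lncRNA_id = lc$transcript_id[i], gene_id = gc$gene_id[j],
          relation = rel, center_distance = d, edge_gap = gap
        )
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    lncRNA_id = character(0), gene_id = character(0),
    relation = character(0), center_distance = numeric(0),
    edge_gap = numeric(0)
  )
  rownames(pairs) <- NULL
  near <- pairs[pairs$relation != "cis_overlapping_window" &
                  pairs$edge_gap > 0 & pairs$edge_gap <= near_bin, ]
  list(
    pairs = pairs,
    near_summary = c(
      near_upstream = sum(near$relation == "cis_upstream"),
      near_downstream = sum(near$relation == "cis_downstream")
    )
  )
}

#' Host-gene targets of NATs and incRNAs
#'
#' Each NAT targets the protein-coding gene on its opposite strand; each
#' incRNA targets its host gene. lincRNAs contribute nothing here.
#'
#' @param classified data.frame from [classify_by_location()]
#'   (`transcript_id`, `class`, `linked_gene`).
#' @return data.frame (`lncRNA_id`, `gene_id`, `relation` in
#'   `{NAT_host, incRNA_host}`).
#' @export
host_targets <- function(classified) {
  d <- classified[classified$class %in% c("NAT", "incRNA"), , drop = FALSE]
  if (any(is.na(d$linked_gene))) {
    lnc_stop("NAT/incRNA without a linked gene violates the classification",
             " invariant: ",
             paste(d$transcript_id[is.na(d$linked_gene)], collapse = ", "))
  }
  data.frame(
    lncRNA_id = d$transcript_id,
    gene_id = d$linked_gene,
    relation = ifelse(d$class == "NAT", "NAT_host", "incRNA_host"),
    row.names = NULL
  )
}

#' Correlation-based (trans) target assignment
#'
#' Pairs every lincRNA with every gene whose expression correlation
#' satisfies `|r| > cutoff` (strict), excluding pairs already explained in
#' cis. The signed correlation is retained so positively and negatively
#' correlated pairs can be counted separately.
#'
#' @param lnc_ids,gene_ids feature ids present in `tpm`.
#' @param tpm TPM matrix or `ExpressionMatrix` covering both id sets with
#'   at least 3 samples.
#' @param cutoff absolute-correlation cut (default 0.9, strict).
#' @param exclude optional data.frame of cis pairs (`lncRNA_id`,
#'   `gene_id`) to drop.
#' @return data.frame (`lncRNA_id`, `gene_id`, `relation = "trans"`,
#'   `pcc`). Features with zero variance are skipped with a warning.
#' @export
trans_targets <- function(lnc_ids, gene_ids, tpm, cutoff = 0.9, exclude = NULL) {
  v <- em_values(tpm)
  if (ncol(v) < 3) lnc_stop("need at least 3 samples")
  miss <- setdiff(c(lnc_ids, gene_ids), rownames(v))
  if (length(miss)) lnc_stop("features absent from the matrix: ",
                             paste(utils::head(miss, 5), collapse = ", "))
  lv <- v[lnc_ids, , drop = FALSE]
  gv <- v[gene_ids, , drop = FALSE]
  const_l <- apply(lv, 1, stats::sd) == 0
  const_g <- apply(gv, 1, stats::sd) == 0
  if (any(const_l) || any(const_g)) {
    lnc_warn(sum(const_l) + sum(const_g),
             " constant features skipped (undefined correlation)")
    lv <- lv[!const_l, , drop = FALSE]
    gv <- gv[!const_g, , drop = FALSE]
  }
  if (nrow(lv) == 0 || nrow(gv) == 0) {
    return(data.frame(lncRNA_id = character(0), gene_id = character(0),
                      relation = character(0), pcc = numeric(0)))
  }
  r <- stats::cor(t(lv), t(gv))
  hit <- which(abs(r) > cutoff, arr.ind = TRUE)
  out <- data.frame(
    lncRNA_id = rownames(lv)[hit[, 1]],
    gene_id = rownames(gv)[hit[, 2]],
    relation = rep("trans", nrow(hit)),
    pcc = r[hit]
  )
  out <- out[out$lncRNA_id != out$gene_id, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(out) > 0) {
    key <- paste(out$lncRNA_id, out$gene_id)
    xkey <- paste(exclude$lncRNA_id, exclude$gene_id)
    out <- out[!key %in% xkey, , drop = FALSE]
  }
  out <- out[order(out$lncRNA_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
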