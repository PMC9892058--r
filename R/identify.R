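#' Find the longest open reading frame on the given strand
#'
#' Scans all three frames of the supplied (already oriented) spliced
#' sequence for ATG..in-frame-stop ORFs. The stop codon is required and is
#' counted in the ORF length. Codons containing `N` never match ATG or a
#' stop. The longest ORF wins; ties are broken by the smallest start.
#'
#' @param sequence a single DNA string over `{A,C,G,T,N}`.
#' @return `NULL` when no ORF exists, otherwise a list with `start` and
#'   `end` (1-based inclusive positions on the sequence), `frame`
#'   (0/1/2), `length_nt` (multiple of 3, includes the stop) and
#'   `length_aa` (`length_nt/3 - 1`).
#' @export
find_longest_orf <- function(sequence) {
  stopifnot(length(sequence) == 1)
  s <- toupper(sequence)
  check_dna(s)
  n <- nchar(s)
  if (n < 6) return(NULL)
  idx <- seq_len(n - 2L)
  cod <- substring(s, idx, idx + 2L)
  atg <- idx[cod == "ATG"]
  stp <- idx[cod %in% c("TAA", "TAG", "TGA")]
  if (length(atg) == 0 || length(stp) == 0) return(NULL)

  best <- NULL
  for (f in 0:2) {
    a <- atg[(atg - 1L) %% 3L == f]
    z <- stp[(stp - 1L) %% 3L == f]
    if (length(a) == 0 || length(z) == 0) next
    z <- sort(z)
    # first in-frame stop strictly downstream of each ATG
    pos <- findInterval(a + 2L, z) + 1L   # z[pos] >= a + 3
    ok <- pos <= length(z)
    if (!any(ok)) next
    a <- a[ok]
    j <- z[pos[ok]]
    len <- j - a + 3L
    k <- which(len == max(len))
    k <- k[which.min(a[k])]
    cand <- list(start = a[k], end = j[k] + 2L, frame = f,
                 length_nt = len[k], length_aa = len[k] / 3L - 1L)
    if (is.null(best) || cand$length_nt > best$length_nt ||
        (cand$length_nt == best$length_nt && cand$start < best$start)) {
      best <- cand
    }
  }
  best
}

# internal: exon GRanges of coding genes in an annotation
coding_exons <- function(annotation) {
  coding <- annotation$genes$gene_id[annotation$genes$biotype == "protein_coding"]
  annotation$exons[annotation$exons$gene_id %in% coding]
}

#' Filter assembled transcripts down to lncRNA candidates
#'
#' Applies the identification cascade, recording for each transcript the
#' first failed filter: (1) sense-strand exonic overlap with an annotated
#' protein-coding gene; (2) spliced length < `min_len`; (3) longest ORF >
#' `max_orf_aa` amino acids; (4) significant protein similarity (supplied as
#' a precomputed table); (5) coding potential — a transcript is kept only if
#' both scores are strictly negative (a score of exactly zero rejects).
#' Boundary transcripts at exactly `min_len` nt or exactly `max_orf_aa` aa
#' are kept.
#'
#' @param transcripts `GenomeAnnotation` of the assembled transcript models.
#' @param sequences named character vector of spliced sequences (see
#'   [extract_all_sequences()]).
#' @param annotation `GenomeAnnotation` of the reference gene models.
#' @param protein_hits character vector of transcript ids with a significant
#'   protein hit, or a data.frame with a `transcript_id` column.
#' @param coding_scores data.frame with columns `transcript_id`, `score1`,
#'   `score2` (two coding-potential scores per transcript).
#' @param min_len minimum spliced length in nt (default 200).
#' @param max_orf_aa maximum ORF length in amino acids (default 120).
#' @param missing_score_policy `"strict"` (error when a surviving transcript
#'   has no coding scores) or `"lenient"` (treat both scores as -1, with a
#'   warning).
#' @return data.frame (`transcript_id`, `kept`, `rejection_reason`) in the
#'   input transcript order; `rejection_reason` is `NA` for kept rows.
#' @export
filter_candidates <- function(transcripts, sequences, annotation,
                              protein_hits, coding_scores,
                              min_len = 200, max_orf_aa = 120,
                              missing_score_policy = c("strict", "lenient")) {
  missing_score_policy <- match.arg(missing_score_policy)
  ids <- transcripts$transcripts$transcript_id
  if (!all(ids %in% names(sequences))) {
    lnc_stop("sequences missing for some transcripts")
  }
  if (is.data.frame(protein_hits)) protein_hits <- protein_hits$transcript_id
  reason <- rep(NA_character_, length(ids))

  # 1. sense overlap with annotated coding exons
  cod_ex <- coding_exons(annotation)
  if (length(cod_ex) > 0) {
    hits <- GenomicRanges::findOverlaps(transcripts$exons, cod_ex,
                                        ignore.strand = FALSE)
    bad_tx <- unique(transcripts$exons$transcript_id[S4Vectors::queryHits(hits)])
    reason[ids %in% bad_tx] <- "overlaps_coding_sense"
  }

  # 2. length filter (strict <; exactly min_len is kept)
  len <- nchar(sequences[ids])
  sel <- is.na(reason) & len < min_len
  reason[sel] <- "too_short"

  # 3. ORF filter (strict >; exactly max_orf_aa is kept)
  todo <- which(is.na(reason))
  for (i in todo) {
    orf <- find_longest_orf(sequences[[ids[i]]])
    if (!is.null(orf) && orf$length_aa > max_orf_aa) reason[i] <- "orf_too_long"
  }

  # 4. protein similarity
  sel <- is.na(reason) & ids %in% protein_hits
  reason[sel] <- "protein_hit"

  # 5. coding potential: both scores must be < 0
  todo <- which(is.na(reason))
  if (length(todo) > 0) {
    m <- match(ids[todo], coding_scores$transcript_id)
    if (anyNA(m)) {
      missing <- ids[todo][is.na(m)]
      if (missing_score_policy == "strict") {
        lnc_stop("no coding scores for transcripts: ",
                 paste(utils::head(missing, 5), collapse = ", "))
      }
      lnc_warn(length(missing), " transcripts without coding scores treated",
               " as non-coding (scores -1)")
    }
    s1 <- ifelse(is.na(m), -1, coding_scores$score1[m])
    s2 <- ifelse(is.na(m), -1, coding_scores$score2[m])
    reason[todo[s1 >= 0 | s2 >= 0]] <- "coding_potential"
  }

  data.frame(transcript_id = ids, kept = is.na(reason),
             rejection_reason = reason, row.names = NULL)
}

# internal: intron GRanges per gene (union of exons removed from gene span)
gene_introns <- function(annotation) {
  ex <- annotation$exons
  g <- annotation$genes
  span <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    gene_id = g$gene_id
  )
  exu <- S4Vectors::split(ex, ex$gene_id)
  intr_list <- lapply(g$gene_id, function(gid) {
    gi <- span[span$gene_id == gid]
    if (!gid %in% names(exu)) return(GenomicRanges::GRanges())
    red <- GenomicRanges::reduce(exu[[gid]])
    out <- GenomicRanges::setdiff(gi, red, ignore.strand = FALSE)
    if (length(out) > 0) out$gene_id <- gid
    out
  })
  do.call(c, intr_list)
}

#' Classify lncRNA candidates by genomic position
#'
#' Position-based class assignment for transcripts that already survived
#' [filter_candidates()] (no sense-strand overlap with coding exons):
#' * NAT — at least `min_nat_overlap` bp of exonic overlap with a gene on
#'   the opposite strand (linked gene = largest overlap);
#' * incRNA — entirely contained in a single intron of a same-strand gene
#'   (linked gene = host);
#' * lincRNA — everything else (intergenic).
#' Precedence is NAT > incRNA > lincRNA.
#'
#' @param transcripts `GenomeAnnotation` of candidate transcripts.
#' @param annotation reference `GenomeAnnotation`.
#' @param min_nat_overlap minimum antisense exonic overlap in bp (default 1).
#' @return data.frame (`transcript_id`, `class`, `linked_gene`); lincRNAs
#'   have `NA` linked gene.
#' @export
classify_by_location <- function(transcripts, annotation, min_nat_overlap = 1) {
  ids <- transcripts$transcripts$transcript_id
  cls <- rep("lincRNA", length(ids))
  linked <- rep(NA_character_, length(ids))
  g <- annotation$genes
  gspan <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    gene_id = g$gene_id
  )

  # NAT: transcript exons vs opposite-strand gene span
  flip <- gspan
  GenomicRanges::strand(flip) <- ifelse(as.character(GenomicRanges::strand(gspan)) == "+", "-", "+")
  hits <- GenomicRanges::findOverlaps(transcripts$exons, flip,
                                      minoverlap = min_nat_overlap,
                                      ignore.strand = FALSE)
  if (length(hits) > 0) {
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(transcripts$exons)[S4Vectors::queryHits(hits)],
      GenomicRanges::ranges(flip)[S4Vectors::subjectHits(hits)]
    ))
    df <- data.frame(
      tx = transcripts$exons$transcript_id[S4Vectors::queryHits(hits)],
      gene = flip$gene_id[S4Vectors::subjectHits(hits)],
      ov = ov
    )
    agg <- stats::aggregate(ov ~ tx + gene, df, sum)
    # pick the opposite-strand gene with the largest total exonic overlap
    agg <- agg[order(agg$tx, -agg$ov, agg$gene), ]
    best <- agg[!duplicated(agg$tx), ]
    m <- match(best$tx, ids)
    cls[m] <- "NAT"
    linked[m] <- best$gene
  }

  # incRNA: whole transcript span within one intron of a same-strand gene
  introns <- gene_introns(annotation)
  if (length(introns) > 0) {
    tx <- transcripts$transcripts
    tspan <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand
    )
    wit <- GenomicRanges::findOverlaps(tspan, introns, type = "within",
                                       ignore.strand = FALSE)
    for (k in seq_along(wit)) {
      i <- S4Vectors::queryHits(wit)[k]
      if (cls[i] == "lincRNA") {
        cls[i] <- "incRNA"
        linked[i] <- introns$gene_id[S4Vectors::subjectHits(wit)[k]]
      }
    }
  }

  data.frame(transcript_id = ids, class = cls, linked_gene = linked,
             row.names = NULL)
}

#' Group transcripts into loci by strand and exonic overlap
#'
#' Transcripts sharing the strand and at least 1 bp of exonic overlap are
#' placed in the same locus (transitively).
#'
#' @param transcripts `GenomeAnnotation`.
#' @return named character vector mapping transcript_id to locus id
#'   (`LOC00001`, ...; numbering follows transcript order of first member).
#' @export
group_loci <- function(transcripts) {
  ids <- transcripts$transcripts$transcript_id
  hits <- GenomicRanges::findOverlaps(transcripts$exons, transcripts$exons,
                                      ignore.strand = FALSE)
  e1 <- transcripts$exons$transcript_id[S4Vectors::queryHits(hits)]
  e2 <- transcripts$exons$transcript_id[S4Vectors::subjectHits(hits)]
  gr <- igraph::graph_from_data_frame(
    unique(data.frame(e1, e2)), directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(gr)$membership
  comp <- comp[ids]
  # renumber components by first appearance
  first <- !duplicated(comp)
  relabel <- stats::setNames(seq_len(sum(first)), comp[first])
  out <- sprintf("LOC%05d", relabel[as.character(comp)])
  names(out) <- ids
  out
}

#' Flag high-confidence lncRNA loci by expression support
#'
#' A locus is high-confidence when its TPM — the maximum over its member
#' transcripts — exceeds 1 (strictly) in at least one sample.
#'
#' @param locus_members named list mapping locus id to member transcript ids.
#' @param tpm TPM matrix (features x samples) or `ExpressionMatrix`.
#' @param floor expression floor (default 1, strict).
#' @return named logical vector per locus. Loci with no member present in
#'   the matrix are flagged `FALSE` with a warning.
#' @export
flag_high_confidence <- function(locus_members, tpm, floor = 1) {
  v <- em_values(tpm)
  out <- vapply(locus_members, function(members) {
    present <- intersect(members, rownames(v))
    if (length(present) == 0) return(NA)
    max(v[present, , drop = FALSE]) > floor
  }, NA)
  if (anyNA(out)) {
    lnc_warn(sum(is.na(out)), " loci absent from the expression matrix; ",
             "flagged not high-confidence")
    out[is.na(out)] <- FALSE
  }
  out
}

#' Per-class counts and percentages
#'
#' @param classes character vector of class labels (one per transcript or
#'   locus), or a named count vector/table.
#' @return data.frame (`class`, `count`, `percent`); percentages are
#'   half-up rounded to 2 decimals and counts sum to the total.
#' @export
summarize_classes <- function(classes) {
  if (is.table(classes) || (!is.null(names(classes)) && is.numeric(classes))) {
    counts <- as.numeric(classes)
    labs <- names(classes)
  } else {
    tab <- table(classes)
    counts <- as.numeric(tab)
    labs <- names(tab)
  }
  if (length(counts) == 0 || sum(counts) == 0) {
    lnc_stop("cannot summarize an empty class set")
  }
  data.frame(
    class = labs,
    count = counts,
    percent = round_half_up(counts / sum(counts) * 100, 2),
    row.names = NULL
  )
}
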