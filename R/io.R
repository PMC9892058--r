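#' @title Annotation and transcript-model input/output
#'
#' @description
#' The package's coordinate backbone is [GenomicRanges::GRanges] (1-based,
#' closed intervals, the Bioconductor convention); GTF input is validated and
#' imported via \pkg{rtracklayer} and all interval arithmetic downstream uses
#' \pkg{IRanges}/\pkg{GenomicRanges} operations. FASTA input/output goes
#' through \pkg{Biostrings}.
#'
#' @name lncpath-io
NULL

#' Read a GTF file into a GenomeAnnotation object
#'
#' Parses a GTF (1-based inclusive coordinates, Ensembl-style attributes)
#' and groups exon features by transcript and gene. Exons are returned
#' sorted by coordinate within each transcript regardless of file order.
#'
#' @param path path to a GTF file.
#' @return an object of class `GenomeAnnotation`: a list with
#'   * `exons`: `GRanges` of exons with `transcript_id`, `gene_id` metadata;
#'   * `transcripts`: data.frame (`transcript_id`, `gene_id`, `chrom`,
#'     `strand`, `start`, `end`, `n_exons`, `length`);
#'   * `genes`: data.frame (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'     `biotype`).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) lnc_stop("GTF not found: ", path)
  # pre-scan for the error contracts rtracklayer cannot report by line
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) lnc_stop("GTF parse error at line ", i, ": fewer than 9 fields")
    st <- suppressWarnings(as.integer(f[4])); en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en)) lnc_stop("GTF parse error at line ", i, ": non-numeric coordinates")
    if (en < st) lnc_stop("GTF coordinate error at line ", i, ": end < start")
    if (f[3] == "exon") {
      if (!grepl("gene_id", f[9], fixed = TRUE)) {
        lnc_stop("GTF parse error at line ", i, ": missing gene_id attribute")
      }
      if (!grepl("transcript_id", f[9], fixed = TRUE)) {
        lnc_stop("GTF parse error at line ", i, ": missing transcript_id attribute")
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) lnc_stop("GTF contains no exon features: ", path)
  if (!all(as.character(GenomicRanges::strand(ex)) %in% c("+", "-"))) {
    lnc_stop("exon strand must be + or -")
  }
  ord <- order(ex$transcript_id, GenomicRanges::start(ex))
  ex <- ex[ord]
  S4Vectors::mcols(ex) <- S4Vectors::mcols(ex)[, c("transcript_id", "gene_id"),
                                               drop = FALSE]

  spl <- split(seq_along(ex), ex$transcript_id)
  tx <- data.frame(
    transcript_id = names(spl),
    gene_id = vapply(spl, function(i) ex$gene_id[i[1]], ""),
    chrom = vapply(spl, function(i) as.character(GenomicRanges::seqnames(ex)[i[1]]), ""),
    strand = vapply(spl, function(i) as.character(GenomicRanges::strand(ex)[i[1]]), ""),
    start = vapply(spl, function(i) min(GenomicRanges::start(ex)[i]), 0L),
    end = vapply(spl, function(i) max(GenomicRanges::end(ex)[i]), 0L),
    n_exons = lengths(spl),
    length = vapply(spl, function(i) sum(GenomicRanges::width(ex)[i]), 0L),
    row.names = NULL
  )

  gfeat <- gr[gr$type == "gene"]
  if (length(gfeat) > 0) {
    biot <- if ("gene_biotype" %in% names(S4Vectors::mcols(gfeat))) {
      ifelse(is.na(gfeat$gene_biotype), "protein_coding", gfeat$gene_biotype)
    } else rep("protein_coding", length(gfeat))
    genes <- data.frame(
      gene_id = gfeat$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gfeat)),
      strand = as.character(GenomicRanges::strand(gfeat)),
      start = GenomicRanges::start(gfeat),
      end = GenomicRanges::end(gfeat),
      biotype = biot,
      row.names = NULL
    )
  } else {
    # derive gene spans from transcripts sharing a gene_id
    gs <- split(seq_len(nrow(tx)), tx$gene_id)
    genes <- data.frame(
      gene_id = names(gs),
      chrom = vapply(gs, function(i) tx$chrom[i[1]], ""),
      strand = vapply(gs, function(i) tx$strand[i[1]], ""),
      start = vapply(gs, function(i) min(tx$start[i]), 0L),
      end = vapply(gs, function(i) max(tx$end[i]), 0L),
      biotype = "protein_coding",
      row.names = NULL
    )
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(exons = ex, transcripts = tx, genes = genes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), length(x$exons)))
  invisible(x)
}

#' Write a GenomeAnnotation (or transcript set) to GTF
#'
#' Emits one gene/transcript/exon hierarchy per locus with Ensembl-style
#' `gene_id "x"; transcript_id "y";` attributes. Round-trips losslessly
#' through [read_gtf()] for the fields the package uses.
#'
#' @param annotation a `GenomeAnnotation` object.
#' @param path output path.
#' @param extra_tx_attrs optional named list mapping transcript_id to a named
#'   character vector of additional attributes (e.g. class labels).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path, extra_tx_attrs = NULL) {
  ex <- annotation$exons
  tx <- annotation$transcripts
  genes <- annotation$genes
  con <- file(path, "w")
  on.exit(close(con))
  lines <- character(0)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    ga <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    lines <- c(lines, paste(g$chrom, "lncpath", "gene", g$start, g$end, ".",
                            g$strand, ".", ga, sep = "\t"))
    gtx <- tx[tx$gene_id == g$gene_id, , drop = FALSE]
    for (ti in seq_len(nrow(gtx))) {
      t1 <- gtx[ti, ]
      extra <- ""
      if (!is.null(extra_tx_attrs) && !is.null(extra_tx_attrs[[t1$transcript_id]])) {
        kv <- extra_tx_attrs[[t1$transcript_id]]
        extra <- paste0(" ", paste(sprintf('%s "%s";', names(kv), kv), collapse = " "))
      }
      ta <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                    g$gene_id, t1$transcript_id, extra)
      lines <- c(lines, paste(t1$chrom, "lncpath", "transcript", t1$start, t1$end,
                              ".", t1$strand, ".", ta, sep = "\t"))
      tex <- ex[ex$transcript_id == t1$transcript_id]
      for (ei in seq_along(tex)) {
        lines <- c(lines, paste(
          as.character(GenomicRanges::seqnames(tex)[ei]), "lncpath", "exon",
          GenomicRanges::start(tex)[ei], GenomicRanges::end(tex)[ei], ".",
          as.character(GenomicRanges::strand(tex)[ei]), ".", ta, sep = "\t"))
      }
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Extract the spliced (mature) sequence of a transcript
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for minus-strand transcripts, yielding the 5'-to-3' spliced sequence.
#'
#' @param transcript_id id of the transcript in `annotation`.
#' @param annotation a `GenomeAnnotation`.
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @return spliced sequence, a single character string.
#' @export
extract_spliced_sequence <- function(transcript_id, annotation, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- toupper(as.character(genome))
  ex <- annotation$exons[annotation$exons$transcript_id == transcript_id]
  if (length(ex) == 0) lnc_stop("unknown transcript: ", transcript_id)
  chrom <- as.character(GenomicRanges::seqnames(ex)[1])
  if (!chrom %in% names(genome)) lnc_stop("chromosome absent from genome: ", chrom)
  chrlen <- nchar(genome[[chrom]])
  st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
  if (any(st < 1) || any(en > chrlen)) {
    lnc_stop("exon out of chromosome bounds for transcript ", transcript_id)
  }
  pieces <- substring(genome[[chrom]], st, en)
  s <- paste(pieces, collapse = "")
  if (as.character(GenomicRanges::strand(ex)[1]) == "-") s <- revcomp(s)
  s
}

#' Extract spliced sequences for all transcripts in an annotation
#'
#' @inheritParams extract_spliced_sequence
#' @return named character vector, one spliced sequence per transcript.
#' @export
extract_all_sequences <- function(annotation, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- toupper(as.character(genome))
  ids <- annotation$transcripts$transcript_id
  out <- vapply(ids, extract_spliced_sequence, "",
                annotation = annotation, genome = genome)
  names(out) <- ids
  out
}

#' Write a numeric matrix as TSV (feature ids in the first column)
#'
#' Values are formatted with 17 significant digits so doubles round-trip
#' bit-exactly through [read_matrix_tsv()].
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read the sample sheet (sample, tissue, condition)
#'
#' @param samples data.frame with `sample`, `tissue`, `condition` columns.
#' @param path TSV path.
#' @return `path` (write) or the sample sheet data.frame (read).
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples[, c("sample", "tissue", "condition")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
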