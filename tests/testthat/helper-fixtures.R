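# Shared fixtures. Simulations are cached per configuration so multiple
# test files can reuse them without regenerating the genome.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed = 1, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.sim_cache[[key]])) {
    cfg <- simulation_config(seed = seed, ...)
    sim <- simulate_genome(cfg)
    expr <- simulate_expression(cfg, sim$truth)
    .sim_cache[[key]] <- list(cfg = cfg, sim = sim, expr = expr)
  }
  .sim_cache[[key]]
}

# a small hand-built annotation: two genes on chr1 (one plus-strand with
# two exons and a 200 bp intron, one minus-strand single-exon), used by
# the classification and cis-target unit tests
toy_annotation <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  gtf <- file.path(dir, "toy.gtf")
  lines <- c(
    'chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tgene_id "gA"; gene_biotype "protein_coding";',
    'chr1\ttoy\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\ttoy\texon\t1001\t1300\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\ttoy\texon\t1501\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\ttoy\tgene\t5001\t5400\t.\t-\t.\tgene_id "gB"; gene_biotype "protein_coding";',
    'chr1\ttoy\ttranscript\t5001\t5400\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";',
    'chr1\ttoy\texon\t5001\t5400\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";'
  )
  writeLines(lines, gtf)
  read_gtf(gtf)
}

# wrap transcript definitions (chrom, strand, exon intervals) into a
# GenomeAnnotation via a temporary GTF
toy_transcripts <- function(defs) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  gtf <- file.path(dir, "tx.gtf")
  lines <- character(0)
  for (d in defs) {
    for (iv in d$exons) {
      lines <- c(lines, sprintf(
        '%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        d$chrom, iv[1], iv[2], d$strand, paste0(d$id, "_g"), d$id
      ))
    }
  }
  writeLines(lines, gtf)
  read_gtf(gtf)
}
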