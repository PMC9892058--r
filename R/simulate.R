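#' Configuration of the synthetic two-subgenome dataset
#'
#' Defines the study conditions for the fully ground-truthed toy dataset:
#' a small allotetraploid-style genome (each S chromosome a mutated copy of
#' its T counterpart), coding genes with real ORFs, planted lincRNA / NAT /
#' incRNA loci, planted miRNA precursor hairpins and eTM sites, and an
#' expression design with tissue-specific genes, co-expression modules
#' (module `M1` active only in root samples) and a before/after topping
#' contrast.
#'
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @param n_chromosomes_per_subgenome chromosomes per parental subgenome.
#' @param chromosome_length template chromosome length in bp.
#' @param n_coding_genes number of protein-coding genes (>=
#'   `n_nat + n_incrna`, which are hosted on coding genes).
#' @param n_lincrna,n_nat,n_incrna planted lncRNA counts per class.
#' @param subgenome_divergence per-base substitution rate between the S and
#'   T copies of each chromosome.
#' @param n_tissues number of tissues; tissue 1 is always root.
#' @param n_samples_per_tissue replicates per tissue (condition "none").
#' @param n_topping_replicates root replicates per topping condition
#'   (before / after).
#' @param n_modules planted co-expression modules; module `M1` is the
#'   root-specific one.
#' @param module_size_range integer pair of allowed module sizes.
#' @param tissue_specific_fraction fraction of features planted as
#'   tissue-specific.
#' @param specificity_factor fold by which a tissue-specific gene is raised
#'   in its tissue (must exceed 2, the calling rule's threshold).
#' @param topping_effect_log2 true log2 fold change of topping-induced
#'   features.
#' @param noise_sd per-cell log2-scale noise standard deviation.
#' @param n_mirnas number of mature miRNAs (each gets one planted
#'   precursor lincRNA and one planted eTM lincRNA, capped by
#'   `n_lincrna`).
#' @param n_pathway_genes coding genes in the synthetic pathway list.
#' @return a validated `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes_per_subgenome = 2,
                              chromosome_length = 150000,
                              n_coding_genes = 200,
                              n_lincrna = 16,
                              n_nat = 8,
                              n_incrna = 6,
                              subgenome_divergence = 0.03,
                              n_tissues = 5,
                              n_samples_per_tissue = 4,
                              n_topping_replicates = 3,
                              n_modules = 3,
                              module_size_range = c(30, 40),
                              tissue_specific_fraction = 0.15,
                              specificity_factor = 4,
                              topping_effect_log2 = 2,
                              noise_sd = 0.2,
                              n_mirnas = 4,
                              n_pathway_genes = 5) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes_per_subgenome = n_chromosomes_per_subgenome,
    chromosome_length = chromosome_length,
    n_coding_genes = n_coding_genes,
    n_lincrna = n_lincrna, n_nat = n_nat, n_incrna = n_incrna,
    subgenome_divergence = subgenome_divergence,
    n_tissues = n_tissues,
    n_samples_per_tissue = n_samples_per_tissue,
    n_topping_replicates = n_topping_replicates,
    n_modules = n_modules,
    module_size_range = as.integer(module_size_range),
    tissue_specific_fraction = tissue_specific_fraction,
    specificity_factor = specificity_factor,
    topping_effect_log2 = topping_effect_log2,
    noise_sd = noise_sd,
    n_mirnas = n_mirnas,
    n_pathway_genes = n_pathway_genes
  )
  if (cfg$specificity_factor <= 2) {
    lnc_stop("specificity_factor must exceed 2 (the tissue-specificity rule)")
  }
  if (cfg$subgenome_divergence < 0 || cfg$subgenome_divergence > 0.2) {
    lnc_stop("subgenome_divergence must lie in [0, 0.2]")
  }
  if (cfg$n_coding_genes < cfg$n_nat + cfg$n_incrna) {
    lnc_stop("need n_coding_genes >= n_nat + n_incrna (NATs and incRNAs ",
             "are hosted on coding genes)")
  }
  if (cfg$n_tissues < 2 || cfg$n_samples_per_tissue < 2) {
    lnc_stop("need >= 2 tissues and >= 2 samples per tissue")
  }
  if (cfg$n_modules < 1 || cfg$module_size_range[1] < 2 ||
      cfg$module_size_range[1] > cfg$module_size_range[2]) {
    lnc_stop("invalid module configuration")
  }
  if (cfg$n_modules > cfg$n_tissues) {
    lnc_stop("need n_modules <= n_tissues (each module anchors to a ",
             "distinct tissue)")
  }
  if (cfg$noise_sd < 0) lnc_stop("noise_sd must be non-negative")
  structure(cfg, class = "SimulationConfig")
}

# stop codons in all three frames: TAA at offsets 2, 6, 10 (1-based), i.e.
# one stop per frame; an ORF cannot read through an intact cassette
STOP_CASSETTE <- "ATAAATAAATAA"

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# noncoding scaffold: random 60-mers interleaved with stop cassettes so the
# longest possible ORF stays far below the 360 nt coding filter
noncoding_dna <- function(n) {
  reps <- ceiling(n / 72)
  s <- paste(vapply(seq_len(reps), function(i) {
    paste0(rand_dna(60), STOP_CASSETTE)
  }, ""), collapse = "")
  substr(s, 1, n)
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

make_cds <- function(n_codons = 135) {
  paste0("ATG", paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}

mirror_iv <- function(iv, len) c(len - iv[2] + 1L, len - iv[1] + 1L)

# build one coding-gene block (plus NAT/incRNA capacity); intervals are
# 1-based relative to the block
build_coding_block <- function(kind = "plain", inc_len = 250) {
  k <- if (kind == "plain") sample(1:4, 1) else sample(2:4, 1)
  big_gap <- switch(kind, plain = 0L, nat_host = 300L,
                    inc_host = inc_len + 60L)
  pieces <- list()
  exon_iv <- list()
  pos <- 0L
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      el <- sample(40:60, 1)
      pieces[[length(pieces) + 1L]] <- noncoding_dna(el)
      exon_iv[[i]] <- c(pos + 1L, pos + el)
      pos <- pos + el
      il <- if (i == 1 && big_gap > 0) big_gap else sample(120:200, 1)
      pieces[[length(pieces) + 1L]] <- noncoding_dna(il)
      pos <- pos + il
    }
  }
  cds <- make_cds()
  last_exon <- paste0(noncoding_dna(10), cds, noncoding_dna(45))
  pieces[[length(pieces) + 1L]] <- last_exon
  exon_iv[[k]] <- c(pos + 1L, pos + nchar(last_exon))
  cds_iv <- c(pos + 10L + 1L, pos + 10L + nchar(cds))
  seq <- paste(unlist(pieces), collapse = "")
  len <- nchar(seq)
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") {
    seq <- revcomp(seq)
    exon_iv <- lapply(exon_iv, mirror_iv, len = len)
    cds_iv <- mirror_iv(cds_iv, len)
  }
  exon_iv <- exon_iv[order(vapply(exon_iv, function(iv) iv[1], 0))]
  list(seq = seq, len = len, strand = strand, exons = exon_iv,
       cds = cds_iv)
}

# widest exon-exon gap of a block, in block coordinates
widest_gap <- function(exons) {
  if (length(exons) < 2) lnc_stop("block has no intron")
  gaps <- t(vapply(seq_len(length(exons) - 1), function(i) {
    c(exons[[i]][2] + 1, exons[[i + 1]][1] - 1)
  }, numeric(2)))
  gaps[which.max(gaps[, 2] - gaps[, 1]), ]
}

# build one lincRNA block; role is "plain", "precursor" or "etm"
build_linc_block <- function(role, mirna = NULL) {
  if (role == "precursor") {
    stem <- paste0(rand_dna(30), mirna)
    designed <- paste0(noncoding_dna(72), stem, "CAACAA", revcomp(stem),
                       noncoding_dna(72))
    element <- c(72L + 30L + 1L, 72L + 30L + nchar(mirna))
    protect <- c(73L, 72L + 2L * nchar(stem) + 6L)
  } else if (role == "etm") {
    rc <- revcomp(mirna)
    m <- nchar(mirna)
    p <- 10L; B <- 3L
    site <- paste0(substr(rc, 1, m - p), "CCC", substr(rc, m - p + 1, m))
    designed <- paste0(noncoding_dna(100), site, noncoding_dna(100))
    element <- c(101L, 100L + nchar(site))
    protect <- element
  } else {
    designed <- noncoding_dna(sample(260:420, 1))
    element <- NULL
    protect <- NULL
  }
  len <- nchar(designed)
  strand <- sample(c("+", "-"), 1)
  seq <- designed
  protect_block <- protect
  if (strand == "-") {
    seq <- revcomp(designed)
    if (!is.null(protect)) protect_block <- mirror_iv(protect, len)
  }
  list(seq = seq, len = len, strand = strand, designed = designed,
       element = element, protect = protect_block, role = role,
       etm_bulge = if (role == "etm") c(position = 10L, length = 3L) else NULL)
}

#' Simulate the toy two-subgenome genome, annotation and transcript set
#'
#' Builds template chromosomes carrying coding genes (1-4 exons, ATG-led
#' ORFs > 360 nt), intergenic lincRNAs (some with an embedded miRNA
#' precursor hairpin or eTM site), antisense NATs over coding genes and
#' intron-contained incRNAs, then derives the T chromosomes (template as
#' is) and the S chromosomes (template mutated at
#' `subgenome_divergence` outside functional elements). Every planted
#' fact is recorded in the returned ground truth.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named sequences, `chrS_*` / `chrT_*`),
#'   `annotation` (reference coding genes, `GenomeAnnotation`),
#'   `transcripts` (assembled set: coding + lncRNA models),
#'   `sequences` (spliced transcript sequences), `mirnas` (mature
#'   sequences) and `truth` (per-feature classes, subgenomes, planted
#'   sites, module / tissue / topping assignments, score and pathway
#'   tables).
#' @export
simulate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes_per_subgenome

  mirnas <- stats::setNames(
    vapply(seq_len(config$n_mirnas), function(i) rand_dna(21), ""),
    sprintf("miR%02d", seq_len(config$n_mirnas))
  )

  # ---- block construction ------------------------------------------------
  blocks <- list()
  host_kind <- c(rep("nat_host", config$n_nat),
                 rep("inc_host", config$n_incrna),
                 rep("plain", config$n_coding_genes - config$n_nat -
                       config$n_incrna))
  for (i in seq_len(config$n_coding_genes)) {
    b <- build_coding_block(host_kind[i])
    b$id <- sprintf("G%03d", i)
    b$type <- "coding"
    b$host_kind <- host_kind[i]
    blocks[[length(blocks) + 1L]] <- b
  }
  n_prec <- min(config$n_mirnas, config$n_lincrna)
  n_etm <- min(config$n_mirnas, max(0L, config$n_lincrna - n_prec))
  linc_roles <- c(rep("precursor", n_prec), rep("etm", n_etm),
                  rep("plain", config$n_lincrna - n_prec - n_etm))
  for (j in seq_len(config$n_lincrna)) {
    role <- linc_roles[j]
    mi <- if (role == "precursor") mirnas[[j]] else if (role == "etm")
      mirnas[[j - n_prec]] else NULL
    b <- build_linc_block(role, mi)
    b$id <- sprintf("LINC%03d", j)
    b$type <- "lincRNA"
    b$mirna_id <- if (role == "precursor") names(mirnas)[j] else if
      (role == "etm") names(mirnas)[j - n_prec] else NA_character_
    blocks[[length(blocks) + 1L]] <- b
  }

  # ---- placement on template chromosomes --------------------------------
  cursor <- rep(0L, n_chrom)
  order_idx <- sample(seq_along(blocks))
  placements <- vector("list", length(blocks))
  for (step in seq_along(order_idx)) {
    bi <- order_idx[step]
    cc <- ((step - 1L) %% n_chrom) + 1L
    gap <- sample(250:450, 1)
    start <- cursor[cc] + gap + 1L
    end <- start + blocks[[bi]]$len - 1L
    if (end > config$chromosome_length) {
      lnc_stop("chromosome_length budget exceeded: chromosome ", cc,
               " needs ", end, " bp but has ", config$chromosome_length)
    }
    cursor[cc] <- end
    placements[[bi]] <- list(chrom_idx = cc, start = start, end = end)
  }

  # ---- template chromosome sequences ------------------------------------
  tmpl <- vector("list", n_chrom)
  for (cc in seq_len(n_chrom)) {
    parts <- character(0)
    pos <- 0L
    on_cc <- which(vapply(placements, function(p) p$chrom_idx, 0) == cc)
    on_cc <- on_cc[order(vapply(placements[on_cc], function(p) p$start, 0))]
    for (bi in on_cc) {
      p <- placements[[bi]]
      parts <- c(parts, noncoding_dna(p$start - pos - 1L), blocks[[bi]]$seq)
      pos <- p$end
    }
    parts <- c(parts, noncoding_dna(config$chromosome_length - pos))
    tmpl[[cc]] <- seq_chars(paste(parts, collapse = ""))
  }

  # ---- feature tables in absolute template coordinates -------------------
  gene_rows <- list(); tx_rows <- list(); exon_rows <- list()
  mask <- lapply(seq_len(n_chrom), function(cc) logical(config$chromosome_length))
  prec_rows <- list(); etm_rows <- list()
  nat_i <- 0L; inc_i <- 0L

  add_tx <- function(txid, gid, cc, strand, exon_abs, class) {
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      transcript_id = txid, gene_id = gid, chrom_idx = cc, strand = strand,
      class = class
    )
    for (iv in exon_abs) {
      exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
        transcript_id = txid, gene_id = gid, chrom_idx = cc,
        strand = strand, start = iv[1], end = iv[2]
      )
    }
  }

  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    p <- placements[[bi]]
    cc <- p$chrom_idx
    off <- p$start - 1L
    if (b$type == "coding") {
      gid <- b$id
      exon_abs <- lapply(b$exons, function(iv) iv + off)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, chrom_idx = cc, strand = b$strand,
        start = p$start, end = p$end, biotype = "protein_coding"
      )
      add_tx(paste0(gid, ".1"), gid, cc, b$strand, exon_abs, "coding")
      cds_abs <- b$cds + off
      mask[[cc]][cds_abs[1]:cds_abs[2]] <- TRUE
      if (b$host_kind == "nat_host") {
        nat_i <- nat_i + 1L
        gap <- widest_gap(b$exons) + off
        iv <- c(max(p$start, gap[1] - 25L), min(p$end, gap[2] + 25L))
        nat_strand <- if (b$strand == "+") "-" else "+"
        nid <- sprintf("NAT%03d", nat_i)
        add_tx(paste0(nid, ".1"), nid, cc, nat_strand, list(iv), "NAT")
        attr(tx_rows[[length(tx_rows)]], "linked_gene") <- gid
      }
      if (b$host_kind == "inc_host") {
        inc_i <- inc_i + 1L
        gap <- widest_gap(b$exons) + off
        iv <- c(gap[1] + 30L, gap[1] + 30L + 249L)
        iid <- sprintf("INC%03d", inc_i)
        add_tx(paste0(iid, ".1"), iid, cc, b$strand, list(iv), "incRNA")
        attr(tx_rows[[length(tx_rows)]], "linked_gene") <- gid
      }
    } else {
      gid <- b$id
      iv <- c(p$start, p$end)
      add_tx(paste0(gid, ".1"), gid, cc, b$strand, list(iv), "lincRNA")
      if (!is.null(b$protect)) {
        pr <- b$protect + off
        mask[[cc]][pr[1]:pr[2]] <- TRUE
      }
      if (b$role == "precursor") {
        prec_rows[[length(prec_rows) + 1L]] <- data.frame(
          lncRNA_id = paste0(gid, ".1"), miRNA_id = b$mirna_id,
          start = b$element[1], end = b$element[2]
        )
      }
      if (b$role == "etm") {
        etm_rows[[length(etm_rows) + 1L]] <- data.frame(
          lncRNA_id = paste0(gid, ".1"), miRNA_id = b$mirna_id,
          start = b$element[1], end = b$element[2],
          bulge_position = b$etm_bulge["position"],
          bulge_length = b$etm_bulge["length"]
        )
      }
    }
  }
  linked <- vapply(tx_rows, function(r) {
    lg <- attr(r, "linked_gene"); if (is.null(lg)) NA_character_ else lg
  }, "")
  tx <- do.call(rbind, tx_rows)
  tx$linked_gene <- linked
  exons <- do.call(rbind, exon_rows)
  genes <- do.call(rbind, gene_rows)

  # ---- subgenome assignment and mutated S chromosomes --------------------
  block_sub <- sample(c("S", "T"), length(blocks), replace = TRUE)
  names(block_sub) <- vapply(blocks, function(b) b$id, "")
  gene2block <- stats::setNames(
    rep(names(block_sub), 1L), names(block_sub)
  )
  # NAT/incRNA inherit the subgenome of their host block via the chromosome
  tx$subgenome <- NA_character_
  for (i in seq_len(nrow(tx))) {
    root_gene <- if (tx$class[i] %in% c("NAT", "incRNA")) tx$linked_gene[i]
      else tx$gene_id[i]
    tx$subgenome[i] <- block_sub[[root_gene]]
  }

  s_chrom <- lapply(tmpl, identity)
  mut_pos <- vector("list", n_chrom)
  if (config$subgenome_divergence > 0) {
    for (cc in seq_len(n_chrom)) {
      hit <- which(stats::runif(config$chromosome_length) <
                     config$subgenome_divergence & !mask[[cc]])
      for (q in hit) {
        s_chrom[[cc]][q] <- sample(
          setdiff(c("A", "C", "G", "T"), tmpl[[cc]][q]), 1)
      }
      mut_pos[[cc]] <- hit
    }
  }

  chrom_name <- function(sub, idx) sprintf("chr%s_%d", sub, idx)
  tx$chrom <- chrom_name(tx$subgenome, tx$chrom_idx)
  exons$chrom <- tx$chrom[match(exons$transcript_id, tx$transcript_id)]
  genes$subgenome <- block_sub[genes$gene_id]
  genes$chrom <- chrom_name(genes$subgenome, genes$chrom_idx)

  genome <- c(
    stats::setNames(lapply(seq_len(n_chrom), function(cc)
      paste(s_chrom[[cc]], collapse = "")), chrom_name("S", seq_len(n_chrom))),
    stats::setNames(lapply(seq_len(n_chrom), function(cc)
      paste(tmpl[[cc]], collapse = "")), chrom_name("T", seq_len(n_chrom)))
  )
  genome <- unlist(genome)

  build_ga <- function(tx_df, exon_df, genes_df) {
    gr <- GenomicRanges::GRanges(
      exon_df$chrom, IRanges::IRanges(exon_df$start, exon_df$end),
      strand = exon_df$strand, transcript_id = exon_df$transcript_id,
      gene_id = exon_df$gene_id
    )
    gr <- gr[order(gr$transcript_id, GenomicRanges::start(gr))]
    spl <- split(seq_along(gr), gr$transcript_id)
    txo <- data.frame(
      transcript_id = names(spl),
      gene_id = vapply(spl, function(i) gr$gene_id[i[1]], ""),
      chrom = vapply(spl, function(i)
        as.character(GenomicRanges::seqnames(gr)[i[1]]), ""),
      strand = vapply(spl, function(i)
        as.character(GenomicRanges::strand(gr)[i[1]]), ""),
      start = vapply(spl, function(i) min(GenomicRanges::start(gr)[i]), 0L),
      end = vapply(spl, function(i) max(GenomicRanges::end(gr)[i]), 0L),
      n_exons = lengths(spl),
      length = vapply(spl, function(i) sum(GenomicRanges::width(gr)[i]), 0L),
      row.names = NULL
    )
    structure(list(exons = gr, transcripts = txo, genes = genes_df),
              class = "GenomeAnnotation")
  }

  ref_genes <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    start = genes$start, end = genes$end, biotype = genes$biotype,
    row.names = NULL
  )
  ref_genes <- ref_genes[order(ref_genes$gene_id), ]
  rownames(ref_genes) <- NULL
  coding_tx <- tx$transcript_id[tx$class == "coding"]
  annotation <- build_ga(tx[tx$class == "coding", ],
                         exons[exons$transcript_id %in% coding_tx, ],
                         ref_genes)

  asm_genes <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d) {
    e <- exons[exons$gene_id == d$gene_id[1], ]
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               strand = d$strand[1], start = min(e$start), end = max(e$end),
               biotype = ifelse(d$class[1] == "coding", "protein_coding",
                                "lncRNA"))
  }))
  asm_genes <- asm_genes[order(asm_genes$gene_id), ]
  rownames(asm_genes) <- NULL
  transcripts <- build_ga(tx, exons, asm_genes)

  # ---- repair: planted lncRNAs must keep their ORFs <= 360 nt ------------
  lnc_ids <- tx$transcript_id[tx$class != "coding"]
  repair_needed <- TRUE
  guard <- 0L
  while (repair_needed && guard < 12L) {
    guard <- guard + 1L
    repair_needed <- FALSE
    genome_now <- genome
    for (id in lnc_ids) {
      s <- extract_spliced_sequence(id, transcripts, genome_now)
      orf <- find_longest_orf(s)
      if (!is.null(orf) && orf$length_nt > 360) {
        repair_needed <- TRUE
        row <- tx[tx$transcript_id == id, ]
        if (row$subgenome != "S") {
          lnc_stop("internal: template lncRNA ", id, " carries a long ORF")
        }
        cc <- row$chrom_idx
        e <- exons[exons$transcript_id == id, ][1, ]
        span <- e$start:e$end
        revert <- intersect(mut_pos[[cc]], span)
        if (length(revert) == 0) {
          lnc_stop("internal: cannot repair ORF of ", id)
        }
        for (q in revert) s_chrom[[cc]][q] <- tmpl[[cc]][q]
        mut_pos[[cc]] <- setdiff(mut_pos[[cc]], revert)
        genome[chrom_name("S", cc)] <- paste(s_chrom[[cc]], collapse = "")
      }
    }
  }

  # ---- force assignability: the S copy of every transcript's exonic
  # footprint differs from the T copy in >= 1 position -------------------
  if (config$subgenome_divergence > 0) {
    for (i in seq_len(nrow(tx))) {
      cc <- tx$chrom_idx[i]
      e <- exons[exons$transcript_id == tx$transcript_id[i], ]
      epos <- unlist(lapply(seq_len(nrow(e)), function(j) e$start[j]:e$end[j]))
      if (any(epos %in% mut_pos[[cc]])) next
      cand <- epos[!mask[[cc]][epos]]
      if (length(cand) == 0) next
      q <- cand[1]
      s_chrom[[cc]][q] <- setdiff(c("A", "C", "G", "T"), tmpl[[cc]][q])[1]
      mut_pos[[cc]] <- sort(c(mut_pos[[cc]], q))
      genome[chrom_name("S", cc)] <- paste(s_chrom[[cc]], collapse = "")
    }
  }

  sequences <- extract_all_sequences(transcripts, genome)

  # sanity: planted elements must be present verbatim in the spliced seqs
  for (r in prec_rows) {
    stopifnot(substr(sequences[[r$lncRNA_id]], r$start, r$end) ==
                mirnas[[r$miRNA_id]])
  }

  # ---- design assignments: modules, tissue specificity, topping ----------
  feats <- data.frame(
    feature_id = tx$transcript_id,
    type = ifelse(tx$class == "coding", "coding", "lncRNA"),
    class = tx$class,
    subgenome = tx$subgenome,
    linked_gene = tx$linked_gene,
    row.names = NULL
  )
  n_feat <- nrow(feats)

  linc_tx <- feats$feature_id[feats$class == "lincRNA"]
  plain_linc <- tx$transcript_id[tx$class == "lincRNA"]
  plain_linc <- plain_linc[grepl("LINC", plain_linc)]
  subnet_linc <- utils::tail(linc_tx, min(3L, length(linc_tx)))
  nat1 <- utils::head(feats$feature_id[feats$class == "NAT"], 1L)
  nat1_host <- if (length(nat1)) paste0(
    feats$linked_gene[feats$feature_id == nat1], ".1") else character(0)
  coding_ids <- feats$feature_id[feats$type == "coding"]
  pathway_pool <- setdiff(coding_ids, nat1_host)
  pathway_genes <- c(nat1_host,
                     sample(pathway_pool,
                            max(0L, config$n_pathway_genes - length(nat1_host))))

  module_sizes <- sample(config$module_size_range[1]:config$module_size_range[2],
                         config$n_modules, replace = TRUE)
  mandatory <- unique(c(pathway_genes, subnet_linc))
  if (module_sizes[1] < length(mandatory)) {
    module_sizes[1] <- length(mandatory)
  }
  if (sum(module_sizes) > n_feat) {
    lnc_stop("module budget exceeded: modules need ", sum(module_sizes),
             " features but only ", n_feat, " exist")
  }
  module <- rep(NA_character_, n_feat)
  names(module) <- feats$feature_id
  pool <- setdiff(feats$feature_id, mandatory)
  m1_extra <- sample(pool, module_sizes[1] - length(mandatory))
  module[c(mandatory, m1_extra)] <- "M1"
  pool <- setdiff(pool, m1_extra)
  if (config$n_modules > 1) {
    for (m in 2:config$n_modules) {
      mem <- sample(pool, module_sizes[m])
      module[mem] <- sprintf("M%d", m)
      pool <- setdiff(pool, mem)
    }
  }
  feats$module <- unname(module)

  background <- feats$feature_id[is.na(feats$module)]
  n_spec <- min(length(background),
                floor(config$tissue_specific_fraction * n_feat))
  tissues <- c("root", "leaf", "flower", "stem", "capsule",
               "anther", "petal", "seed")[seq_len(config$n_tissues)]
  spec_ids <- if (n_spec > 0) sample(background, n_spec) else character(0)
  feats$specific_tissue <- NA_character_
  feats$specific_tissue[match(spec_ids, feats$feature_id)] <-
    sample(tissues, n_spec, replace = TRUE)

  topping_ids <- unique(c(subnet_linc, pathway_genes, nat1,
                          utils::head(setdiff(background, spec_ids), 2L)))
  feats$topping_log2fc <- ifelse(feats$feature_id %in% topping_ids,
                                 config$topping_effect_log2, 0)

  coding_scores <- data.frame(
    transcript_id = feats$feature_id,
    score1 = ifelse(feats$type == "coding",
                    stats::runif(n_feat, 0.5, 2),
                    stats::runif(n_feat, -2, -0.5)),
    score2 = ifelse(feats$type == "coding",
                    stats::runif(n_feat, 0.5, 2),
                    stats::runif(n_feat, -2, -0.5)),
    row.names = NULL
  )
  protein_hits <- feats$feature_id[feats$type == "coding"]

  other_terms <- lapply(1:5, function(i) sample(feats$feature_id, 15))
  names(other_terms) <- sprintf("TERM%02d", 1:5)
  term_map_list <- c(list(PATHWAY_ALKALOID = c(pathway_genes, subnet_linc)),
                     other_terms)
  term_map <- do.call(rbind, lapply(names(term_map_list), function(tm) {
    data.frame(feature_id = term_map_list[[tm]], term_id = tm)
  }))

  truth <- list(
    features = feats,
    precursor_sites = if (length(prec_rows)) do.call(rbind, prec_rows) else
      data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                 start = integer(0), end = integer(0)),
    etm_sites = if (length(etm_rows)) do.call(rbind, etm_rows) else
      data.frame(lncRNA_id = character(0), miRNA_id = character(0),
                 start = integer(0), end = integer(0),
                 bulge_position = integer(0), bulge_length = integer(0)),
    root_module = "M1",
    tissues = tissues,
    pathway_genes = pathway_genes,
    subnet_lincrnas = subnet_linc,
    topping_ids = topping_ids,
    coding_scores = coding_scores,
    protein_hits = protein_hits,
    term_map = term_map
  )
  rownames(truth$precursor_sites) <- NULL
  rownames(truth$etm_sites) <- NULL

  list(genome = genome, annotation = annotation, transcripts = transcripts,
       sequences = sequences, mirnas = mirnas, truth = truth,
       config = config)
}

#' Simulate the expression matrix over the planted design
#'
#' Log-normal baselines (meanlog 3, sdlog 1 on the TPM scale) plus, on the
#' log2 scale: a shared per-sample module eigensignal (module `M1` active
#' only in root samples), a `log2(specificity_factor)` boost for
#' tissue-specific features in their tissue, the topping effect in
#' `after` samples, and iid Gaussian noise (`noise_sd`). Columns are then
#' normalised to TPM.
#'
#' @param config the [simulation_config()] used for the genome.
#' @param truth `truth` element of [simulate_genome()].
#' @return an `ExpressionMatrix` (unit TPM) whose sample sheet holds
#'   `n_tissues * n_samples_per_tissue` tissue samples (condition
#'   `"none"`) plus root topping samples (`"before"` / `"after"`).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1000003L)
  feats <- truth$features
  n <- nrow(feats)
  tissues <- truth$tissues

  samples <- rbind(
    do.call(rbind, lapply(tissues, function(tl) {
      data.frame(sample = sprintf("%s_%d", tl, seq_len(config$n_samples_per_tissue)),
                 tissue = tl, condition = "none")
    })),
    data.frame(sample = sprintf("topping_before_%d",
                                seq_len(config$n_topping_replicates)),
               tissue = "root", condition = "before"),
    data.frame(sample = sprintf("topping_after_%d",
                                seq_len(config$n_topping_replicates)),
               tissue = "root", condition = "after")
  )
  m <- nrow(samples)

  log2b <- log2(stats::rlnorm(n, meanlog = 3, sdlog = 1))
  e <- matrix(rep(log2b, m), nrow = n)
  rownames(e) <- feats$feature_id
  colnames(e) <- samples$sample

  # module m is anchored to tissue m (module M1 to root), mirroring the
  # tissue-specific module structure real co-expression networks show;
  # distinct anchor tissues keep planted eigengenes near-orthogonal
  mods <- sort(unique(stats::na.omit(feats$module)))
  for (md in mods) {
    mi <- as.integer(sub("^M", "", md))
    amp <- 2.2 * (tissues == tissues[mi])
    if (md != truth$root_module) {
      amp <- amp + stats::rnorm(length(tissues), 0, 0.25)
    }
    names(amp) <- tissues
    # per-sample eigensignal jitter models state variation across the
    # multi-tissue survey; the topping contrast is a controlled experiment
    # whose replicates differ only by measurement noise
    eig <- amp[samples$tissue] +
      stats::rnorm(m, 0, 0.35) * (samples$condition == "none")
    members <- feats$feature_id[!is.na(feats$module) & feats$module == md]
    e[members, ] <- sweep(e[members, , drop = FALSE], 2, eig, "+")
  }

  spec <- feats[!is.na(feats$specific_tissue), ]
  for (i in seq_len(nrow(spec))) {
    cols <- samples$tissue == spec$specific_tissue[i]
    e[spec$feature_id[i], cols] <- e[spec$feature_id[i], cols] +
      log2(config$specificity_factor)
  }

  topping <- feats$feature_id[feats$topping_log2fc != 0]
  after <- samples$condition == "after"
  e[topping, after] <- e[topping, after] + config$topping_effect_log2

  if (config$noise_sd > 0) {
    e <- e + matrix(stats::rnorm(n * m, 0, config$noise_sd), nrow = n)
  }

  x <- 2^e
  x <- sweep(x, 2, colSums(x), "/") * 1e6
  expression_matrix(x, samples, unit = "TPM")
}

#' Write a simulated dataset to disk
#'
#' Emits the genome and subgenome FASTAs, reference and transcript GTFs,
#' miRNA FASTA, expression and sample-sheet TSVs, coding-score /
#' protein-hit / pathway / term tables and the ground-truth tables.
#'
#' @param sim result of [simulate_genome()].
#' @param expr result of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return named list of written file paths, invisibly.
#' @export
write_simulation <- function(sim, expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  paths <- list(
    genome = pth("genome.fa"), genome_s = pth("genome_S.fa"),
    genome_t = pth("genome_T.fa"), annotation = pth("annotation.gtf"),
    transcripts = pth("transcripts.gtf"), mirnas = pth("mirnas.fa"),
    expression = pth("expression.tsv"), samples = pth("sample_sheet.tsv"),
    coding_scores = pth("coding_scores.tsv"),
    protein_hits = pth("protein_hits.tsv"),
    pathway_genes = pth("pathway_genes.tsv"),
    term_map = pth("term_map.tsv"),
    truth_features = pth("truth_features.tsv"),
    truth_precursors = pth("truth_precursor_sites.tsv"),
    truth_etms = pth("truth_etm_sites.tsv")
  )
  write_fasta(sim$genome, paths$genome)
  is_s <- startsWith(names(sim$genome), "chrS")
  write_fasta(sim$genome[is_s], paths$genome_s)
  write_fasta(sim$genome[!is_s], paths$genome_t)
  write_gtf(sim$annotation, paths$annotation)
  write_gtf(sim$transcripts, paths$transcripts)
  write_fasta(sim$mirnas, paths$mirnas)
  write_matrix_tsv(expr$values, paths$expression)
  write_sample_sheet(expr$samples, paths$samples)
  wt <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(sim$truth$coding_scores, paths$coding_scores)
  wt(data.frame(transcript_id = sim$truth$protein_hits), paths$protein_hits)
  wt(data.frame(gene_id = sim$truth$pathway_genes), paths$pathway_genes)
  wt(sim$truth$term_map, paths$term_map)
  wt(sim$truth$features, paths$truth_features)
  wt(sim$truth$precursor_sites, paths$truth_precursors)
  wt(sim$truth$etm_sites, paths$truth_etms)
  invisible(paths)
}
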