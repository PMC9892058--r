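#' Pipeline configuration
#'
#' Every tunable threshold of the pipeline in one flat list. The defaults
#' are the study's canonical parameters: 200 nt minimum length, 120 aa ORF
#' cap, TPM floor 1, 100 kb cis window with 5 kb near bins, trans PCC 0.9,
#' sub-network PCC 0.85, ANOVA screen alpha 0.001, DE alpha 0.05 with
#' induction log2FC > 1, unsigned network power 9 / minimum module size 30 /
#' merge height 0.25, k-mer size 31 for subgenome calls, and the eTM /
#' precursor matching rules.
#'
#' @param ... overrides of the defaults by name; unknown keys are an error.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_len = 200, max_orf_aa = 120, tpm_floor = 1,
    cis_window = 100000, near_bin = 5000,
    trans_pcc = 0.9, subnet_pcc = 0.85,
    anova_alpha = 0.001, de_alpha = 0.05, induced_log2fc = 1,
    pseudocount = 0.01,
    power = 9, min_module_size = 30, merge_cut_height = 0.25,
    cut_height = NULL, scalefree_r2_target = 0.8,
    kmer_k = 31,
    precursor_max_mismatch = 2, precursor_window = 80,
    precursor_min_pairs_fraction = 0.5, precursor_min_loop = 3,
    etm_bulge_min = 2, etm_bulge_max = 5, etm_bulge_positions = 9:11,
    etm_max_mismatch = 3,
    specificity_ratio = 2, trait = "root"
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad) > 0) {
    lnc_stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, ov, keep.null = TRUE)
  structure(cfg, class = "PipelineConfig")
}

# internal: run one stage, reporting the stage name on failure
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    lnc_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full lncRNA pipeline on a dataset directory
#'
#' Executes the stages in order — identify, characterize, mirna, targets,
#' network, de (+ enrichment), subnet — over the declared input files,
#' writing every stage output plus a machine-readable manifest
#' (`manifest.json` with the configuration, input checksums and per-stage
#' counts) to `out_dir`. With fixed inputs and configuration the run is
#' fully deterministic, so two runs produce byte-identical outputs.
#'
#' @param inputs named list of input paths: `genome`, `annotation`,
#'   `transcripts`, `mirnas`, `expression`, `samples`, `coding_scores`,
#'   `protein_hits`, and optionally `genome_s`, `genome_t` (subgenome
#'   references), `pathway_genes`, `term_map` (as written by
#'   [write_simulation()]).
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(inputs, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- c("genome", "annotation", "transcripts", "mirnas", "expression",
            "samples", "coding_scores", "protein_hits")
  miss <- setdiff(need, names(inputs))
  if (length(miss) > 0) lnc_stop("missing inputs: ", paste(miss, collapse = ", "))
  for (f in inputs[!vapply(inputs, is.null, TRUE)]) {
    if (!file.exists(f)) lnc_stop("input file not found: ", f)
  }
  out <- function(f) file.path(out_dir, f)
  wt <- function(d, f) utils::write.table(d, out(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  counts <- list()

  # ---- load --------------------------------------------------------------
  genome <- run_stage("load", read_fasta(inputs$genome))
  annotation <- run_stage("identify", read_gtf(inputs$annotation))
  transcripts <- run_stage("identify", read_gtf(inputs$transcripts))
  mirnas <- run_stage("load", read_fasta(inputs$mirnas))
  expr_v <- run_stage("load", read_matrix_tsv(inputs$expression))
  samples <- run_stage("load", read_sample_sheet(inputs$samples))
  tpm <- expression_matrix(expr_v[, samples$sample, drop = FALSE], samples,
                           unit = "TPM")
  coding_scores <- utils::read.table(inputs$coding_scores, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
  protein_hits <- utils::read.table(inputs$protein_hits, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)[[1]]

  tissue_cols <- samples$condition == "none"
  tissue_tpm <- expr_v[, samples$sample[tissue_cols], drop = FALSE]
  tissue_lab <- samples$tissue[tissue_cols]

  # ---- identify ----------------------------------------------------------
  res <- run_stage("identify", {
    seqs <- extract_all_sequences(transcripts, genome)
    decisions <- filter_candidates(transcripts, seqs, annotation,
                                   protein_hits, coding_scores,
                                   min_len = config$min_len,
                                   max_orf_aa = config$max_orf_aa)
    kept_ids <- decisions$transcript_id[decisions$kept]
    kept <- subset_annotation(transcripts, kept_ids)
    classified <- classify_by_location(kept, annotation)
    loci <- group_loci(kept)
    members <- split(names(loci), loci)
    hc <- flag_high_confidence(members, tissue_tpm, floor = config$tpm_floor)
    list(seqs = seqs, decisions = decisions, classified = classified,
         loci = loci, hc = hc, kept = kept)
  })
  wt(res$decisions, "filter_decisions.tsv")
  wt(res$classified, "classified.tsv")
  summ <- summarize_classes(res$classified$class)
  wt(summ, "class_summary.tsv")
  wt(data.frame(locus = names(res$hc), high_confidence = res$hc),
     "high_confidence_loci.tsv")
  counts$identify <- list(
    input_transcripts = nrow(transcripts$transcripts),
    kept = sum(res$decisions$kept),
    lincRNA = sum(res$classified$class == "lincRNA"),
    NAT = sum(res$classified$class == "NAT"),
    incRNA = sum(res$classified$class == "incRNA"),
    loci = length(unique(res$loci)),
    high_confidence_loci = sum(res$hc)
  )

  lnc_ids <- res$classified$transcript_id
  lnc_seqs <- res$seqs[lnc_ids]
  coding_ids <- intersect(annotation$transcripts$transcript_id,
                          rownames(expr_v))

  # ---- characterize ------------------------------------------------------
  char <- run_stage("characterize", {
    class_of <- stats::setNames(res$classified$class, lnc_ids)
    groups <- c(class_of,
                stats::setNames(rep("mRNA", length(coding_ids)), coding_ids))
    es <- exon_stats(transcripts, groups)
    au <- au_content(res$seqs[names(groups)[names(groups) %in%
                                              names(res$seqs)]])
    ts <- tissue_specificity(tissue_tpm, tissue_lab,
                             ratio = config$specificity_ratio,
                             floor = config$tpm_floor)
    etc <- expressed_tissue_count(tissue_tpm, tissue_lab,
                                  threshold = config$tpm_floor)
    tm <- tissue_means(tissue_tpm, tissue_lab)
    hm <- foldchange_heatmap_matrix(tm)
    sub <- NULL
    if (!is.null(inputs$genome_s) && !is.null(inputs$genome_t)) {
      sub <- assign_subgenome(res$seqs, read_fasta(inputs$genome_s),
                              read_fasta(inputs$genome_t), k = config$kmer_k)
    }
    list(es = es, au = au, ts = ts, etc = etc, hm = hm, sub = sub,
         class_of = class_of)
  })
  wt(char$es$per_transcript, "exon_stats.tsv")
  wt(char$ts, "tissue_specificity.tsv")
  write_matrix_tsv(char$hm$fold, out("heatmap_matrix.tsv"))
  counts$characterize <- list(
    tissue_specific = sum(char$ts$specific),
    frac_one_tissue = unname(char$etc$summary["frac_one_tissue"])
  )
  if (!is.null(char$sub)) {
    wt(char$sub, "subgenome_calls.tsv")
    subsum <- subgenome_summary(char$sub, char$class_of)
    wt(subsum, "subgenome_summary.tsv")
    counts$characterize$subgenome_S <- sum(char$sub$call == "S")
    counts$characterize$subgenome_T <- sum(char$sub$call == "T")
  }

  # ---- mirna -------------------------------------------------------------
  mir <- run_stage("mirna", {
    prec <- find_precursor_sites(
      mirnas, lnc_seqs,
      max_mismatch = config$precursor_max_mismatch,
      window = config$precursor_window,
      min_pairs_fraction = config$precursor_min_pairs_fraction,
      min_loop = config$precursor_min_loop
    )
    etm <- predict_etm(
      mirnas, lnc_seqs,
      bulge_min = config$etm_bulge_min, bulge_max = config$etm_bulge_max,
      bulge_positions = config$etm_bulge_positions,
      max_mismatch = config$etm_max_mismatch
    )
    list(prec = prec, etm = etm)
  })
  wt(mir$prec, "precursor_sites.tsv")
  wt(mir$etm, "etm_sites.tsv")
  counts$mirna <- list(precursor_sites = nrow(mir$prec),
                       etm_sites = nrow(mir$etm))

  # ---- targets -----------------------------------------------------------
  g2t <- stats::setNames(annotation$transcripts$transcript_id,
                         annotation$transcripts$gene_id)
  tgt <- run_stage("targets", {
    linc_df <- transcripts$transcripts[
      transcripts$transcripts$transcript_id %in%
        res$classified$transcript_id[res$classified$class == "lincRNA"], ]
    cis <- cis_targets(linc_df, annotation, window = config$cis_window,
                       near_bin = config$near_bin)
    hosts <- host_targets(res$classified)
    cis_tx <- data.frame(
      lncRNA_id = cis$pairs$lncRNA_id,
      gene_id = unname(g2t[cis$pairs$gene_id])
    )
    linc_expr <- intersect(linc_df$transcript_id, rownames(expr_v))
    trans <- trans_targets(linc_expr, coding_ids, tissue_tpm,
                           cutoff = config$trans_pcc, exclude = cis_tx)
    list(cis = cis, hosts = hosts, trans = trans)
  })
  wt(tgt$cis$pairs, "cis_pairs.tsv")
  wt(tgt$hosts, "host_pairs.tsv")
  wt(tgt$trans, "trans_pairs.tsv")
  counts$targets <- list(cis_pairs = nrow(tgt$cis$pairs),
                         host_pairs = nrow(tgt$hosts),
                         trans_pairs = nrow(tgt$trans),
                         near_upstream = unname(tgt$cis$near_summary["near_upstream"]),
                         near_downstream = unname(tgt$cis$near_summary["near_downstream"]))

  # ---- network -----------------------------------------------------------
  net <- run_stage("network", {
    screen <- anova_screen(tissue_tpm, tissue_lab, alpha = config$anova_alpha)
    sel <- screen$feature_id[screen$selected]
    sel <- intersect(sel, c(lnc_ids, coding_ids))
    if (length(sel) < config$min_module_size) {
      lnc_stop("fewer screened features (", length(sel),
               ") than min_module_size")
    }
    sel_tpm <- tissue_tpm[sel, , drop = FALSE]
    fit <- pick_soft_threshold(sel_tpm, target_r2 = config$scalefree_r2_target)
    adj <- adjacency_matrix(sel_tpm, power = config$power)
    tom <- tom_similarity(adj)
    det <- detect_modules(1 - tom, network_params(
      power = config$power, min_module_size = config$min_module_size,
      merge_cut_height = config$merge_cut_height,
      cut_height = config$cut_height
    ))
    labels <- merge_close_modules(det$labels, sel_tpm,
                                  merge_cut_height = config$merge_cut_height)
    em <- eigengene_matrix(labels, sel_tpm)
    traits <- stats::model.matrix(~ 0 + tissue_lab)
    colnames(traits) <- sub("^tissue_lab", "", colnames(traits))
    assoc <- module_trait_association(em, traits)
    list(screen = screen, fit = fit, labels = labels, em = em,
         assoc = assoc)
  })
  wt(net$screen, "anova_screen.tsv")
  wt(net$fit$fit_table, "soft_threshold_fit.tsv")
  wt(data.frame(feature_id = names(net$labels), module = net$labels),
     "module_membership.tsv")
  write_matrix_tsv(net$assoc$correlation, out("module_trait_correlation.tsv"))
  ftypes <- stats::setNames(
    ifelse(names(net$labels) %in% lnc_ids, "lncRNA", "coding"),
    names(net$labels)
  )
  msum <- module_summary(net$labels, ftypes)
  wt(msum, "module_summary.tsv")
  counts$network <- list(
    screened = sum(net$screen$selected),
    modules = length(setdiff(unique(net$labels), "grey")),
    grey = sum(net$labels == "grey"),
    soft_power_suggested = net$fit$power
  )

  # ---- de ----------------------------------------------------------------
  de <- run_stage("de", {
    top_cols <- samples$condition %in% c("before", "after")
    topping_de(expr_v[, samples$sample[top_cols], drop = FALSE],
               samples$condition[top_cols],
               pseudocount = config$pseudocount, floor = config$tpm_floor,
               p_cutoff = config$de_alpha, lfc_cutoff = config$induced_log2fc)
  })
  wt(de, "topping_de.tsv")
  counts$de <- list(deg = sum(de$deg), induced = sum(de$induced))

  if (!is.null(inputs$term_map)) {
    enr <- run_stage("de", {
      term_map <- utils::read.table(inputs$term_map, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE)
      universe <- rownames(expr_v)
      hypergeometric_enrichment(de$feature_id[de$induced], universe,
                                term_map, alpha = config$de_alpha)
    })
    wt(enr, "enrichment.tsv")
    counts$de$enriched_terms <- sum(enr$significant)
  }

  # ---- subnet ------------------------------------------------------------
  if (!is.null(inputs$pathway_genes)) {
    sn <- run_stage("subnet", {
      pathway <- utils::read.table(inputs$pathway_genes, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)[[1]]
      target <- select_target_module(net$assoc, trait = config$trait)
      nat_hosts <- tgt$hosts[tgt$hosts$relation == "NAT_host", , drop = FALSE]
      if (nrow(nat_hosts) > 0) {
        nat_hosts$gene_id <- unname(g2t[nat_hosts$gene_id])
      }
      subnet <- build_subnetwork(
        net$labels, target, pathway, ftypes, tissue_tpm, de = de,
        nat_hosts = nat_hosts, pcc_cutoff = config$subnet_pcc
      )
      list(target = target, subnet = subnet)
    })
    wt(sn$subnet$edges, "subnetwork_edges.tsv")
    wt(sn$subnet$nodes, "subnetwork_nodes.tsv")
    if (nrow(sn$subnet$edges) > 0) {
      wt(degree_ranking(sn$subnet$edges), "subnetwork_degree.tsv")
    }
    write_subnetwork_graphml(sn$subnet, out("subnetwork.graphml"))
    counts$subnet <- list(
      target_module = sn$target,
      edges = nrow(sn$subnet$edges),
      induced_edges = sum(sn$subnet$edges$lnc_induced),
      lncRNAs = length(unique(sn$subnet$edges$lncRNA_id))
    )
  }

  # ---- manifest ----------------------------------------------------------
  manifest <- list(
    package = "lncpath",
    config = unclass(config),
    inputs = lapply(inputs[!vapply(inputs, is.null, TRUE)], function(f)
      unname(tools::md5sum(f))),
    counts = counts
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Restrict a GenomeAnnotation to a transcript subset
#'
#' @param annotation `GenomeAnnotation`.
#' @param transcript_ids ids to keep.
#' @return a `GenomeAnnotation` with only the requested transcripts (gene
#'   table restricted to genes that still own a transcript).
#' @export
subset_annotation <- function(annotation, transcript_ids) {
  ex <- annotation$exons[annotation$exons$transcript_id %in% transcript_ids]
  tx <- annotation$transcripts[
    annotation$transcripts$transcript_id %in% transcript_ids, , drop = FALSE]
  genes <- annotation$genes[annotation$genes$gene_id %in% tx$gene_id, ,
                            drop = FALSE]
  rownames(tx) <- NULL
  rownames(genes) <- NULL
  structure(list(exons = ex, transcripts = tx, genes = genes),
            class = "GenomeAnnotation")
}
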