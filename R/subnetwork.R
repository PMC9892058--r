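#' Select the trait-specific module
#'
#' Picks the module whose eigengene has the largest positive correlation
#' with the trait indicator (e.g. the root-specific module that houses the
#' alkaloid biosynthesis programme). Ties go to the first label in
#' alphabetical order (logged); no positive correlation is an error.
#'
#' @param trait_assoc result of [module_trait_association()].
#' @param trait trait column name (default `"root"`).
#' @return the selected module label.
#' @export
select_target_module <- function(trait_assoc, trait = "root") {
  cm <- trait_assoc$correlation
  if (!trait %in% colnames(cm)) lnc_stop("trait column not found: ", trait)
  r <- cm[, trait]
  r <- r[!is.na(r)]
  if (length(r) == 0 || max(r) <= 0) {
    lnc_stop("no module correlates positively with trait '", trait, "'")
  }
  winners <- sort(names(r)[r == max(r)])
  if (length(winners) > 1) {
    message("tie between modules ", paste(winners, collapse = ", "),
            "; keeping ", winners[1])
  }
  winners[1]
}

#' Build the pathway-focused lncRNA-gene sub-network
#'
#' Candidate lncRNAs are module members of lncRNA type whose expression
#' correlates with at least one pathway gene in the module above
#' `pcc_cutoff` (strict); every such passing (lncRNA, pathway gene) pair
#' becomes an edge. NATs whose host gene is a pathway gene are included
#' regardless of module membership (flagged `NAT_host`). Each edge
#' carries an `lnc_induced` flag taken from the induction contrast
#' (`log2FC > 1` and adjusted `p < 0.05`).
#'
#' @param labels named module label vector.
#' @param target_module label of the module to mine (see
#'   [select_target_module()]).
#' @param pathway_genes character vector of pathway gene ids (non-empty).
#' @param feature_types named vector mapping ids to `"lncRNA"` /
#'   `"coding"`.
#' @param tpm expression matrix or `ExpressionMatrix` (PCC is computed
#'   across all of its samples).
#' @param de data.frame from [topping_de()], used for the `lnc_induced`
#'   flag (`NULL` leaves the flag `FALSE`).
#' @param nat_hosts optional data.frame from [host_targets()] restricted
#'   to NATs; rows whose `gene_id` is a pathway gene enter the network.
#' @param pcc_cutoff correlation threshold (default 0.85, strict).
#' @return list with `edges` (data.frame `lncRNA_id`, `gene_id`, `pcc`,
#'   `in_target_module`, `pcc_pass`, `nat_host`, `lnc_induced`) and
#'   `nodes` (id, type, degree). Pathway genes absent from the expression
#'   matrix are skipped with a warning.
#' @export
build_subnetwork <- function(labels, target_module, pathway_genes,
                             feature_types, tpm, de = NULL, nat_hosts = NULL,
                             pcc_cutoff = 0.85) {
  if (length(pathway_genes) == 0) lnc_stop("pathway gene list is empty")
  v <- em_values(tpm)
  missing <- setdiff(pathway_genes, rownames(v))
  if (length(missing) > 0) {
    lnc_warn(length(missing), " pathway genes absent from expression; skipped")
    pathway_genes <- setdiff(pathway_genes, missing)
  }
  members <- names(labels)[labels == target_module]
  mod_lnc <- members[feature_types[members] == "lncRNA"]
  mod_path <- intersect(members, pathway_genes)
  induced_ids <- character(0)
  if (!is.null(de)) induced_ids <- de$feature_id[de$induced]

  edges <- list()
  if (length(mod_lnc) > 0 && length(mod_path) > 0) {
    r <- stats::cor(t(v[mod_lnc, , drop = FALSE]),
                    t(v[mod_path, , drop = FALSE]))
    hit <- which(r > pcc_cutoff, arr.ind = TRUE)
    if (length(hit) > 0) {
      edges[[1]] <- data.frame(
        lncRNA_id = mod_lnc[hit[, 1]], gene_id = mod_path[hit[, 2]],
        pcc = r[hit], in_target_module = TRUE, pcc_pass = TRUE,
        nat_host = FALSE
      )
    }
  }
  if (!is.null(nat_hosts) && nrow(nat_hosts) > 0) {
    nh <- nat_hosts[nat_hosts$gene_id %in% pathway_genes, , drop = FALSE]
    if (nrow(nh) > 0) {
      pcc <- vapply(seq_len(nrow(nh)), function(i) {
        a <- nh$lncRNA_id[i]; b <- nh$gene_id[i]
        if (!a %in% rownames(v) || !b %in% rownames(v)) return(NA_real_)
        if (stats::sd(v[a, ]) == 0 || stats::sd(v[b, ]) == 0) return(NA_real_)
        stats::cor(v[a, ], v[b, ])
      }, 0)
      edges[[length(edges) + 1L]] <- data.frame(
        lncRNA_id = nh$lncRNA_id, gene_id = nh$gene_id, pcc = pcc,
        in_target_module = labels[nh$lncRNA_id] == target_module &
          !is.na(labels[nh$lncRNA_id]),
        pcc_pass = !is.na(pcc) & pcc > pcc_cutoff,
        nat_host = TRUE
      )
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else data.frame(
    lncRNA_id = character(0), gene_id = character(0), pcc = numeric(0),
    in_target_module = logical(0), pcc_pass = logical(0),
    nat_host = logical(0)
  )
  edges <- edges[!duplicated(paste(edges$lncRNA_id, edges$gene_id)), ,
                 drop = FALSE]
  edges$lnc_induced <- edges$lncRNA_id %in% induced_ids
  edges <- edges[order(edges$lncRNA_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL

  ids <- unique(c(edges$lncRNA_id, edges$gene_id))
  deg <- vapply(ids, function(x) {
    sum(edges$lncRNA_id == x) + sum(edges$gene_id == x)
  }, 0L)
  nodes <- data.frame(
    id = ids,
    type = ifelse(ids %in% edges$lncRNA_id, "lncRNA", "coding"),
    degree = deg, row.names = NULL
  )
  list(edges = edges, nodes = nodes)
}

#' Rank sub-network nodes by degree
#'
#' @param edges edge data.frame with `lncRNA_id` and `gene_id` columns.
#' @return data.frame (`id`, `degree`) in decreasing degree, ties broken
#'   by id.
#' @export
degree_ranking <- function(edges) {
  if (nrow(edges) == 0) lnc_stop("no edges to rank")
  ids <- c(edges$lncRNA_id, edges$gene_id)
  tab <- table(ids)
  out <- data.frame(id = names(tab), degree = as.integer(tab),
                    row.names = NULL)
  out <- out[order(-out$degree, out$id), ]
  rownames(out) <- NULL
  out
}

#' Export a sub-network to GraphML
#'
#' @param subnet list from [build_subnetwork()].
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_subnetwork_graphml <- function(subnet, path) {
  g <- igraph::graph_from_data_frame(
    subnet$edges[, c("lncRNA_id", "gene_id", "pcc", "lnc_induced")],
    directed = FALSE, vertices = subnet$nodes
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
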