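#' Parameters of the weighted co-expression network
#'
#' Defaults follow the standard unsigned WGCNA-style call used for the
#' tobacco network: soft power 9, minimum module size 30, module
#' eigengene merge height 0.25.
#'
#' @param power soft-threshold exponent (positive integer, default 9).
#' @param min_module_size smallest allowed module (default 30).
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @param cut_height static tree-cut height; `NULL` (default) means 0.995
#'   of the maximum merge height of the dendrogram.
#' @param scalefree_r2_target signed scale-free fit target for
#'   [pick_soft_threshold()] (default 0.8).
#' @return a `NetworkParams` list.
#' @export
network_params <- function(power = 9, min_module_size = 30,
                           merge_cut_height = 0.25, cut_height = NULL,
                           scalefree_r2_target = 0.8) {
  stopifnot(power >= 1, min_module_size >= 1,
            merge_cut_height > 0, merge_cut_height < 1)
  structure(list(power = power, min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 cut_height = cut_height,
                 scalefree_r2_target = scalefree_r2_target),
            class = "NetworkParams")
}

# WGCNA-style module colour order; overflow modules get numbered labels
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "grey60",
  "lightcyan", "midnightblue", "lightgreen", "lightyellow", "royalblue"
)

#' Unsigned adjacency matrix
#'
#' `a_ij = |cor(x_i, x_j)|^power` with a zero diagonal (self-connections
#' are excluded from connectivity).
#'
#' @param tpm expression matrix (features x samples) or `ExpressionMatrix`.
#' @param power soft-threshold exponent.
#' @return symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @export
adjacency_matrix <- function(tpm, power = 9) {
  v <- em_values(tpm)
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    lnc_stop("constant feature rows have no defined correlation: ",
             paste(utils::head(rownames(v)[sds == 0], 5), collapse = ", "))
  }
  a <- abs(stats::cor(t(v)))^power
  diag(a) <- 0
  a
}

#' Scale-free soft-threshold selection
#'
#' For each candidate power, computes the adjacency, the connectivity
#' `k_i = sum_j a_ij`, and the scale-free fit: `log10 p(k)` against
#' `log10 k` over `n_bins` equal-width connectivity bins, with
#' `R^2` signed negative when the slope is positive. The chosen power is
#' the smallest whose signed `R^2` reaches `target_r2`, falling back to
#' the argmax when none does.
#'
#' @inheritParams adjacency_matrix
#' @param candidate_powers integer vector of powers to scan (default 1:20).
#' @param target_r2 signed fit target (default 0.8).
#' @param n_bins connectivity bins for the fit (default 10).
#' @return list with `power` (chosen), `fit_table` (power, signed R^2,
#'   slope, mean/max connectivity; `NA` fit when fewer than 2 non-empty
#'   bins, e.g. for degenerate all-equal correlations).
#' @export
pick_soft_threshold <- function(tpm, candidate_powers = 1:20, target_r2 = 0.8,
                                n_bins = 10) {
  v <- em_values(tpm)
  if (ncol(v) < 8) lnc_stop("need at least 8 samples for a meaningful fit")
  cr <- abs(stats::cor(t(v)))
  diag(cr) <- 0
  rows <- lapply(candidate_powers, function(b) {
    k <- rowSums(cr^b)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = b, r2 = fit$r2, slope = fit$slope,
               mean_k = mean(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r2) & tab$r2 >= target_r2)
  power <- if (length(ok) > 0) {
    tab$power[ok[1]]
  } else if (all(is.na(tab$r2))) {
    lnc_warn("degenerate network: scale-free fit undefined for every power")
    candidate_powers[1]
  } else {
    tab$power[which.max(tab$r2)]
  }
  list(power = power, fit_table = tab)
}

# internal: signed scale-free topology fit R^2. Connectivities are
# discretised into n_bins equal-width bins (equal-count bins would make
# p(k) constant by construction and the fit vacuous); p(k) is the fraction
# of nodes per bin and dk the bin's mean connectivity.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2 || max(k) - min(k) < 1e-12) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  br <- unique(seq(min(k), max(k), length.out = n_bins + 1))
  if (length(br) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & !is.na(pk) & dk > 0 & pk > 0
  if (sum(keep) < 2) return(list(r2 = NA_real_, slope = NA_real_))
  x <- log10(dk[keep]); y <- log10(pk[keep])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (!is.finite(slope) || !is.finite(r2)) {
    return(list(r2 = NA_real_, slope = NA_real_))
  }
  list(r2 = if (slope > 0) -r2 else r2, slope = slope)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; `TOM_ii = 1`. The
#' clustering input is the dissimilarity `1 - TOM`.
#'
#' @param adjacency symmetric zero-diagonal matrix in `[0, 1]`.
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(abs(a - t(a)) > 1e-12) || any(diag(a) != 0)) {
    lnc_stop("adjacency must be symmetric with a zero diagonal")
  }
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cut_height` (default 0.995 of the maximum merge height). Clusters
#' smaller than `min_module_size` fall into the reserved `"grey"`
#' unassigned bucket; surviving modules are labelled by decreasing size
#' from the conventional colour list (turquoise, blue, brown, ...).
#'
#' @param tom_dissim square dissimilarity matrix (`1 - TOM`).
#' @param params a [network_params()] list.
#' @return list with `labels` (named character vector per feature),
#'   `tree` (the `hclust` object) and `cut_height` (the absolute height
#'   used).
#' @export
detect_modules <- function(tom_dissim, params = network_params()) {
  d <- as.matrix(tom_dissim)
  stopifnot(nrow(d) == ncol(d))
  ids <- rownames(d)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  h <- params$cut_height
  if (is.null(h)) h <- 0.995 * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  good <- names(sizes)[sizes >= params$min_module_size]
  lab <- rep("grey", length(raw))
  if (length(good) > 0) {
    ord <- good[order(-sizes[good], as.integer(good))]
    colors <- c(MODULE_COLORS, sprintf("module%02d", seq_len(max(
      0, length(ord) - length(MODULE_COLORS)
    )) + length(MODULE_COLORS)))
    for (i in seq_along(ord)) lab[raw == as.integer(ord[i])] <- colors[i]
  } else {
    lnc_warn("no cluster reached min_module_size; all features are grey")
  }
  names(lab) <- ids
  list(labels = lab, tree = tree, cut_height = h)
}

#' Module eigengene (first principal component)
#'
#' Rows are standardised to mean 0 / sd 1; the eigengene is the first
#' right singular vector across samples, with its sign fixed so that it
#' correlates non-negatively with the mean standardised profile.
#' `variance_explained` is the fraction of variance carried by the first
#' singular value.
#'
#' @param tpm expression matrix restricted to one module's members
#'   (features x samples, >= 2 samples).
#' @return list with `eigengene` (unit-norm vector per sample),
#'   `variance_explained` and `excluded` (ids of zero-variance rows
#'   dropped with a warning).
#' @export
module_eigengene <- function(tpm) {
  v <- em_values(tpm)
  if (nrow(v) == 0) lnc_stop("empty module")
  if (ncol(v) < 2) lnc_stop("need at least 2 samples")
  sds <- apply(v, 1, stats::sd)
  excluded <- rownames(v)[sds == 0]
  if (length(excluded) > 0) {
    lnc_warn(length(excluded), " zero-variance rows excluded from eigengene")
    v <- v[sds > 0, , drop = FALSE]
    if (nrow(v) == 0) lnc_stop("no variable rows left in module")
  }
  x <- t(scale(t(v)))
  sv <- svd(x)
  e <- sv$v[, 1]
  mp <- colMeans(x)
  if (sum(e * mp) < 0) e <- -e
  list(eigengene = stats::setNames(e, colnames(v)),
       variance_explained = sv$d[1]^2 / sum(sv$d^2),
       excluded = excluded)
}

# internal: eigengene matrix (modules x samples) for non-grey labels
eigengene_matrix <- function(labels, v) {
  mods <- setdiff(sort(unique(labels)), "grey")
  out <- t(vapply(mods, function(m) {
    module_eigengene(v[names(labels)[labels == m], , drop = FALSE])$eigengene
  }, numeric(ncol(v))))
  rownames(out) <- mods
  out
}

#' Merge modules with close eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - cor(E_a, E_b)` is strictly below
#' `merge_cut_height`, recomputing eigengenes after every merge until a
#' fixpoint (ties broken by label order; the merged module keeps the
#' label of its larger member, ties again by label order). The grey
#' bucket never merges.
#'
#' @param labels named module label vector (from [detect_modules()]).
#' @param tpm expression matrix covering the labelled features.
#' @param merge_cut_height dissimilarity threshold (default 0.25).
#' @return updated label vector.
#' @export
merge_close_modules <- function(labels, tpm, merge_cut_height = 0.25) {
  v <- em_values(tpm)[names(labels), , drop = FALSE]
  repeat {
    mods <- setdiff(sort(unique(labels)), "grey")
    if (length(mods) < 2) break
    em <- eigengene_matrix(labels, v)
    dis <- 1 - stats::cor(t(em))
    diag(dis) <- Inf
    mi <- which(dis == min(dis), arr.ind = TRUE)
    # deterministic tie-break: first pair in label order
    mi <- mi[order(rownames(dis)[mi[, 1]], colnames(dis)[mi[, 2]]), ,
             drop = FALSE]
    if (dis[mi[1, 1], mi[1, 2]] >= merge_cut_height) break
    a <- rownames(dis)[mi[1, 1]]
    b <- colnames(dis)[mi[1, 2]]
    na <- sum(labels == a); nb <- sum(labels == b)
    keep <- if (na > nb) a else if (nb > na) b else min(a, b)
    drop <- setdiff(c(a, b), keep)
    labels[labels == drop] <- keep
  }
  labels
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with each trait indicator
#' (e.g. `root = 1` for root samples, else 0), with the two-sided p-value
#' from the t transform on `n - 2` degrees of freedom.
#'
#' @param eigengenes matrix (modules x samples) as from the internal
#'   eigengene computation, or a single eigengene vector.
#' @param traits data.frame / matrix of numeric indicator columns, one row
#'   per sample.
#' @return list of matrices `correlation` and `p_value`
#'   (modules x traits); constant indicators give `NA` cells.
#' @export
module_trait_association <- function(eigengenes, traits) {
  if (is.null(dim(eigengenes))) {
    eigengenes <- matrix(eigengenes, nrow = 1,
                         dimnames = list("module", names(eigengenes)))
  }
  traits <- as.matrix(traits)
  n <- ncol(eigengenes)
  stopifnot(nrow(traits) == n)
  cormat <- matrix(NA_real_, nrow(eigengenes), ncol(traits),
                   dimnames = list(rownames(eigengenes), colnames(traits)))
  pmat <- cormat
  for (j in seq_len(ncol(traits))) {
    if (stats::sd(traits[, j]) == 0) next
    r <- as.vector(stats::cor(t(eigengenes), traits[, j]))
    r2 <- pmin(r^2, 1 - 1e-15)
    tval <- r * sqrt((n - 2) / (1 - r2))
    cormat[, j] <- r
    pmat[, j] <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(correlation = cormat, p_value = pmat)
}

#' Per-module composition summary
#'
#' Counts lncRNA and coding members per module with percentages of each
#' type's total across modules (grey excluded from the denominators),
#' half-up rounded to 2 decimals.
#'
#' @param labels named module label vector.
#' @param feature_types named character vector mapping feature id to
#'   `"lncRNA"` or `"coding"`.
#' @return data.frame (`module`, `n_lncRNA`, `percent_lncRNA`, `n_coding`,
#'   `percent_coding`) sorted by decreasing total size.
#' @export
module_summary <- function(labels, feature_types) {
  ft <- feature_types[names(labels)]
  mods <- setdiff(unique(labels), "grey")
  tot_l <- sum(labels != "grey" & ft == "lncRNA")
  tot_c <- sum(labels != "grey" & ft == "coding")
  out <- do.call(rbind, lapply(mods, function(m) {
    nl <- sum(labels == m & ft == "lncRNA")
    nc <- sum(labels == m & ft == "coding")
    data.frame(
      module = m, n_lncRNA = nl,
      percent_lncRNA = if (tot_l > 0) round_half_up(nl / tot_l * 100, 2) else NA_real_,
      n_coding = nc,
      percent_coding = if (tot_c > 0) round_half_up(nc / tot_c * 100, 2) else NA_real_
    )
  }))
  out <- out[order(-(out$n_lncRNA + out$n_coding), out$module), , drop = FALSE]
  rownames(out) <- NULL
  out
}
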