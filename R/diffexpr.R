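#' One-way ANOVA screen across tissues
#'
#' Classical one-way F test per feature (`MS_between / MS_within`, upper
#' tail of the F distribution on `g-1, n-g` df), vectorised across
#' features; the screen keeps features with `p < alpha` (strict). Features
#' with zero within-group variance but unequal group means get `p = 0`
#' by convention and are flagged.
#'
#' @param tpm TPM matrix or `ExpressionMatrix`.
#' @param sample_tissues tissue label per sample (from the sample sheet
#'   when an `ExpressionMatrix` is given).
#' @param alpha selection threshold (default 0.001, strict).
#' @return data.frame (`feature_id`, `f_statistic`, `p_value`, `selected`,
#'   `degenerate`).
#' @export
anova_screen <- function(tpm, sample_tissues = NULL, alpha = 0.001) {
  v <- em_values(tpm)
  tissues <- em_tissues(tpm, sample_tissues)
  labs <- unique(tissues)
  g <- length(labs)
  n <- ncol(v)
  if (g < 2) lnc_stop("need at least 2 tissues")
  if (n <= g) lnc_stop("need more samples than tissues")
  nt <- vapply(labs, function(tl) sum(tissues == tl), 0L)
  gm <- vapply(labs, function(tl) rowMeans(v[, tissues == tl, drop = FALSE]),
               numeric(nrow(v)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(v))
  grand <- rowSums(sweep(gm, 2, nt, "*")) / n
  ssb <- rowSums(sweep((gm - grand)^2, 2, nt, "*"))
  ssw <- rowSums(v^2) - rowSums(sweep(gm^2, 2, nt, "*"))
  ssw <- pmax(ssw, 0)  # guard tiny negative rounding
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  degenerate <- msw == 0 & msb > 0
  f <- ifelse(msw == 0, ifelse(msb > 0, Inf, 0), msb / msw)
  p <- ifelse(msw == 0, ifelse(msb > 0, 0, 1),
              stats::pf(f, g - 1, n - g, lower.tail = FALSE))
  if (any(degenerate)) {
    lnc_warn(sum(degenerate), " features with zero within-group variance ",
             "and unequal means (p set to 0)")
  }
  data.frame(feature_id = rownames(v), f_statistic = f, p_value = p,
             selected = p < alpha, degenerate = degenerate,
             row.names = NULL)
}

#' Pseudocount-stabilised log2 fold change
#'
#' @param mean_after,mean_before non-negative group means.
#' @param pseudocount added to both means (default 0.01) so the ratio is
#'   always finite.
#' @return `log2((mean_after + pseudocount) / (mean_before + pseudocount))`.
#' @export
log2_fold_change <- function(mean_after, mean_before, pseudocount = 0.01) {
  if (any(mean_after < 0) || any(mean_before < 0)) {
    lnc_stop("means must be non-negative")
  }
  log2((mean_after + pseudocount) / (mean_before + pseudocount))
}

#' Differential expression for the before/after induction contrast
#'
#' Per feature: Welch two-sample t-test on `log2(TPM + pseudocount)`
#' between the `before` and `after` condition samples; the fold change is
#' [log2_fold_change()] of the raw TPM means. A feature is a DEG when it
#' passes the expression floor (`max(mean_before, mean_after) > floor`)
#' and `p < p_cutoff`; it is *induced* when additionally
#' `log2FC > lfc_cutoff` and the Benjamini-Hochberg adjusted p is below
#' `p_cutoff`. All inequalities are strict.
#'
#' @param tpm TPM matrix or `ExpressionMatrix`.
#' @param conditions condition label per sample (`"before"` / `"after"`;
#'   other labels are ignored). Taken from the sample sheet when omitted.
#' @param pseudocount log-transform offset (default 0.01).
#' @param floor expression floor on the larger group mean (default 1).
#' @param p_cutoff significance level (default 0.05).
#' @param lfc_cutoff induction fold-change cut in log2 (default 1).
#' @return data.frame (`feature_id`, `mean_before`, `mean_after`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`,
#'   `passes_expression_floor`, `deg`, `induced`, `degenerate`).
#' @export
topping_de <- function(tpm, conditions = NULL, pseudocount = 0.01, floor = 1,
                       p_cutoff = 0.05, lfc_cutoff = 1) {
  v <- em_values(tpm)
  cond <- em_conditions(tpm, conditions)
  ib <- which(cond == "before")
  ia <- which(cond == "after")
  if (length(ib) < 2 || length(ia) < 2) {
    lnc_stop("need at least 2 replicates per condition")
  }
  lb <- log2(v[, ib, drop = FALSE] + pseudocount)
  la <- log2(v[, ia, drop = FALSE] + pseudocount)
  nb <- length(ib); na_ <- length(ia)
  mb <- rowMeans(lb); ma <- rowMeans(la)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  va <- rowSums((la - ma)^2) / (na_ - 1)
  se2 <- va / na_ + vb / nb
  d <- ma - mb
  tval <- ifelse(se2 == 0, ifelse(d == 0, 0, Inf * sign(d)), d / sqrt(se2))
  df <- ifelse(se2 == 0, na_ + nb - 2,
               se2^2 / ((va / na_)^2 / pmax(na_ - 1, 1) +
                        (vb / nb)^2 / pmax(nb - 1, 1)))
  p <- ifelse(se2 == 0, ifelse(d == 0, 1, 0),
              2 * stats::pt(-abs(tval), df))
  mean_b <- rowMeans(v[, ib, drop = FALSE])
  mean_a <- rowMeans(v[, ia, drop = FALSE])
  lfc <- log2_fold_change(mean_a, mean_b, pseudocount)
  adj <- bh_adjust(p)
  pass_floor <- pmax(mean_b, mean_a) > floor
  deg <- pass_floor & p < p_cutoff
  induced <- deg & lfc > lfc_cutoff & adj < p_cutoff
  data.frame(
    feature_id = rownames(v), mean_before = mean_b, mean_after = mean_a,
    log2_fold_change = lfc, p_value = p, adjusted_p = adj,
    passes_expression_floor = pass_floor, deg = deg, induced = induced,
    degenerate = se2 == 0 & d != 0, row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control; the output preserves the input
#' order and never drops below the raw p-value.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    lnc_stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' For each term, tests whether the selection contains more term members
#' than expected by chance: `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` with `N` the universe size, `K` the term
#' members in the universe, `n` the selection size and `k` the term
#' members selected. P-values are Benjamini-Hochberg corrected across the
#' tested terms; significance is `adjusted_p < alpha` (strict).
#'
#' @param selection character vector of selected feature ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all feature ids.
#' @param term_map data.frame (`feature_id`, `term_id`) or named list of
#'   feature-id vectors per term.
#' @param alpha significance level (default 0.05).
#' @return data.frame (`term_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `adjusted_p`, `significant`), sorted by p-value.
#' @export
hypergeometric_enrichment <- function(selection, universe, term_map,
                                      alpha = 0.05) {
  selection <- unique(selection)
  universe <- unique(universe)
  if (!all(selection %in% universe)) {
    lnc_stop("selection must be a subset of the universe")
  }
  if (is.data.frame(term_map)) {
    term_map <- split(term_map$feature_id, term_map$term_id)
  }
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(term_map), function(tm) {
    members <- intersect(unique(term_map[[tm]]), universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, selection))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, k = k, K = K, n = n, N = N, p_value = p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$adjusted_p < alpha
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct vectors are averaged first; then
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)` and the fold change is
#' `2^-ddCt`. Adding any constant to every Ct leaves the result
#' unchanged.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   numeric vectors of positive cycle-threshold values (replicates).
#' @return list with `ddct` and `fold_change`.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- list(ct_target_treated, ct_ref_treated,
              ct_target_control, ct_ref_control)
  if (any(vapply(cts, function(x) any(x <= 0), TRUE))) {
    lnc_stop("Ct values must be positive")
  }
  m <- vapply(cts, mean, 0)
  ddct <- (m[1] - m[2]) - (m[3] - m[4])
  list(ddct = ddct, fold_change = 2^-ddct)
}
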