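test_that("TPM conversion matches the closed form and normalises columns", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(counts, c(a = 1000, b = 2000))
  expect_equal(tpm[, 1], c(a = 666666.6667, b = 333333.3333), tolerance = 1e-8)
  # symmetry: equal counts and lengths give 1e6 / n each
  cc <- matrix(5, 4, 2, dimnames = list(letters[1:4], c("x", "y")))
  expect_true(all(abs(compute_tpm(cc, stats::setNames(rep(100, 4), letters[1:4])) -
                        2.5e5) < 1e-9))
  # random matrices: every column sums to 1e6
  set.seed(3)
  m <- matrix(stats::rpois(500, 40), 50, 10,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%02d", 1:10)))
  lens <- stats::setNames(sample(200:3000, 50), rownames(m))
  out <- compute_tpm(m, lens)
  expect_true(all(abs(colSums(out) - 1e6) < 1e6 * 1e-9))
  expect_warning(compute_tpm(cbind(m, z = 0), c(lens)), "all-zero")
  expect_error(compute_tpm(m, lens[-1]), "missing")
})

test_that("A/U content excludes N from the denominator", {
  expect_equal(au_content("ATAT"), 1)
  expect_equal(au_content("GCGC"), 0)
  expect_equal(au_content("ATGC"), 0.5)
  expect_equal(au_content("ATGCNN"), 0.5)
  expect_true(is.na(au_content("NNNN")))
  expect_error(au_content(""), "empty")
})

test_that("exon statistics and the Welch test match reference computations", {
  tx <- toy_transcripts(list(
    list(id = "single", chrom = "c", strand = "+", exons = list(c(1, 300))),
    list(id = "multi", chrom = "c", strand = "+",
         exons = list(c(1, 100), c(201, 260)))
  ))
  es <- exon_stats(tx)
  p <- es$per_transcript
  expect_equal(p$n_exons[p$transcript_id == "single"], 1L)
  expect_equal(p$mean_exon_length[p$transcript_id == "single"], 300)
  expect_equal(p$mean_exon_length[p$transcript_id == "multi"], 80)

  # grouped comparison against stats::t.test on random groups
  set.seed(21)
  defs <- lapply(1:60, function(i) {
    len <- sample(80:900, 1)
    list(id = sprintf("t%02d", i), chrom = "c", strand = "+",
         exons = list(c(1000 * i, 1000 * i + len)))
  })
  txs <- toy_transcripts(defs)
  groups <- stats::setNames(rep(c("g1", "g2"), each = 30),
                            sprintf("t%02d", 1:60))
  es2 <- exon_stats(txs, groups)
  a <- es2$per_transcript$mean_exon_length[
    groups[es2$per_transcript$transcript_id] == "g1"]
  b <- es2$per_transcript$mean_exon_length[
    groups[es2$per_transcript$transcript_id] == "g2"]
  ref <- stats::t.test(a, b)
  expect_equal(es2$tests$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(es2$tests$p, ref$p.value, tolerance = 1e-12)
  # identical groups degenerate to t = 0, p = 1
  w <- lncpath:::welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
})

test_that("tissue specificity uses a strict 2x rule over tissue means", {
  mk <- function(means) {
    # 2 samples per tissue, exact means, zero within-tissue variance
    v <- matrix(rep(means, each = 2), nrow = 1)
    rownames(v) <- "f"
    colnames(v) <- sprintf("s%d", seq_len(ncol(v)))
    tissue_specificity(v, rep(sprintf("t%d", seq_along(means)), each = 2))
  }
  expect_true(mk(c(10, 4, 1))$specific)
  expect_equal(mk(c(10, 4, 1))$tissue, "t1")
  expect_false(mk(c(10, 6, 1))$specific)   # 10 < 2*6
  expect_false(mk(c(10, 5))$specific)      # exactly 2x fails the strict rule
  expect_false(mk(c(0.9, 0.1))$specific)   # expression floor
  # scale invariance in the feature's own values
  v <- matrix(c(8, 8, 3, 3, 1, 1), 1,
              dimnames = list("f", sprintf("s%d", 1:6)))
  t1 <- tissue_specificity(v, rep(c("a", "b", "c"), each = 2))$specific
  t2 <- tissue_specificity(v * 17, rep(c("a", "b", "c"), each = 2))$specific
  expect_equal(t1, t2)
})

test_that("expressed-tissue counts use a strict threshold", {
  v <- rbind(
    one = c(1.5, 1.5, 0.2, 0.2, 0.0, 0.0),
    none = rep(0, 6),
    all3 = rep(2, 6)
  )
  colnames(v) <- sprintf("s%d", 1:6)
  out <- expressed_tissue_count(v, rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(out$counts), c(1, 0, 3))
  expect_equal(unname(out$summary["frac_one_tissue"]), 1 / 3)
  # boundary: mean exactly at the threshold does not count
  vb <- matrix(c(1, 1), 1, dimnames = list("f", c("s1", "s2")))
  expect_equal(unname(expressed_tissue_count(vb, c("a", "b"))$counts), 0)
})

test_that("fold-change heatmap rows divide by the second-largest value", {
  m <- rbind(a = c(8, 4, 2), b = c(5, 5, 1))
  colnames(m) <- c("t1", "t2", "t3")
  out <- foldchange_heatmap_matrix(m)
  expect_equal(unname(out$fold["a", ]), c(2, 1, 0.5))
  expect_equal(unname(out$fold["b", ]), c(1, 1, 0.2))
  expect_equal(out$flagged_rows, character(0))
  # zero second-largest is flagged and guarded by epsilon
  z <- rbind(z = c(3, 0, 0))
  colnames(z) <- c("t1", "t2", "t3")
  outz <- foldchange_heatmap_matrix(z)
  expect_equal(outz$flagged_rows, "z")
  expect_equal(unname(outz$fold["z", 1]), 3e6)
  # exactly one entry > 1 iff the row max is unique
  set.seed(9)
  r <- matrix(stats::runif(400), 80, 5)
  rownames(r) <- sprintf("f%02d", 1:80)
  fr <- foldchange_heatmap_matrix(r)$fold
  n_gt1 <- rowSums(fr > 1)
  unique_max <- apply(r, 1, function(x) sum(x == max(x)) == 1)
  expect_equal(n_gt1 == 1, unique_max)
})

test_that("subgenome calls follow k-mer containment with tie -> unassigned", {
  set.seed(5)
  s_ref <- random_dna_string(2000)
  # a sequence copied verbatim from the S reference is called S
  q <- substr(s_ref, 301, 800)
  t_ref <- random_dna_string(2000)
  out <- assign_subgenome(c(q = q), s_ref, t_ref, k = 31)
  expect_equal(out$call, "S")
  expect_equal(out$score_S, 1)
  # identical references: every query is a tie
  out2 <- assign_subgenome(c(q = q), s_ref, s_ref, k = 31)
  expect_equal(out2$call, "unassigned")
  # shorter than k: unassigned
  out3 <- assign_subgenome(c(q = "ACGT"), s_ref, t_ref, k = 31)
  expect_equal(out3$call, "unassigned")
  expect_error(assign_subgenome(c(q = q), "", t_ref), "empty")
})

test_that("k-mer subgenome calls agree with a local-alignment best-hit oracle", {
  set.seed(17)
  base <- random_dna_string(1500)
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (q in hit) ch[q] <- sample(setdiff(c("A", "C", "G", "T"), ch[q]), 1)
    paste(ch, collapse = "")
  }
  s_ref <- base
  t_ref <- mutate(base, 0.05)  # 5% divergence between the references
  n <- 200
  queries <- vapply(seq_len(n), function(i) {
    a <- sample(1:1200, 1)
    q <- substr(s_ref, a, a + 260)
    mutate(q, stats::runif(1, 0.01, 0.10))
  }, "")
  names(queries) <- sprintf("q%03d", seq_len(n))
  # k = 21 keeps the containment score informative across the whole 1-10%
  # mutation range (at k = 31 no intact k-mer survives the top of the
  # range, which correctly yields unassigned ties rather than wrong calls)
  got <- assign_subgenome(queries, s_ref, t_ref, k = 21)$call
  want <- vapply(queries, oracle_best_hit, "", s_ref = s_ref, t_ref = t_ref)
  expect_gte(mean(got == unname(want)), 0.95)
})

test_that("the asymmetry chi-square matches the Pearson formula and conventions", {
  even <- subgenome_asymmetry_test(matrix(50, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_equal(even$df, 1)
  tab <- matrix(c(10548, 35758, 4803, 33742), 2, 2)
  out <- subgenome_asymmetry_test(tab)
  expect_lt(out$p_value, 1e-5)
  expect_error(subgenome_asymmetry_test(matrix(c(0, 0, 5, 5), 2, 2)),
               "expected")
})

test_that("small-table chi-square p is close to the permutation null", {
  # the label-permutation null with both margins fixed is the
  # hypergeometric distribution of cell (1,1); the Monte-Carlo tail uses
  # mid-p tie handling (half weight on the observed statistic), the
  # standard comparator for a discrete permutation distribution
  for (tabv in list(c(11, 9, 9, 11), c(12, 8, 9, 11))) {
    tab <- matrix(tabv, 2, 2)
    out <- subgenome_asymmetry_test(tab)
    set.seed(123)
    a11 <- stats::rhyper(1e6, m = sum(tab[1, ]), n = sum(tab[2, ]),
                         k = sum(tab[, 1]))
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ]); N <- n1 + n2
    c1 <- sum(tab[, 1])
    e11 <- n1 * c1 / N; e12 <- n1 * (N - c1) / N
    e21 <- n2 * c1 / N; e22 <- n2 * (N - c1) / N
    a21 <- c1 - a11
    stat <- (a11 - e11)^2 / e11 + ((n1 - a11) - e12)^2 / e12 +
      (a21 - e21)^2 / e21 + ((n2 - a21) - e22)^2 / e22
    p_mc <- mean(stat > out$statistic + 1e-9) +
      0.5 * mean(abs(stat - out$statistic) <= 1e-9)
    expect_lt(abs(p_mc - out$p_value) / out$p_value, 0.10)
  }
})

test_that("per-class subgenome percentages reproduce hand-computable shares", {
  calls <- data.frame(
    feature_id = c(sprintf("l%05d", 1:15351), sprintf("n%04d", 1:3273),
                   "u1", "z1", "z2"),
    call = c(rep("S", 10548), rep("T", 4803), rep("S", 1706), rep("T", 1567),
             "unassigned", "S", "T")
  )
  classes <- stats::setNames(
    c(rep("lincRNA", 15351), rep("NAT", 3273), "lincRNA", "tiny", "tiny"),
    calls$feature_id
  )
  out <- subgenome_summary(calls, classes)
  expect_equal(out$percent_S[out$class == "lincRNA"], 68.71)
  expect_equal(out$percent_S[out$class == "NAT"], 52.12)
  expect_equal(out$percent_S[out$class == "tiny"], 50.00)
  expect_equal(out$n_unassigned[out$class == "lincRNA"], 1)
  # percentages sum to 100 within rounding
  expect_true(all(abs(out$percent_S + out$percent_T - 100) <= 0.01))
})
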