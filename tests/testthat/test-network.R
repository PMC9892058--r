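test_that("unsigned adjacency follows |r|^power with a zero diagonal", {
  n <- 8
  set.seed(81)
  base <- stats::rnorm(n)
  v <- rbind(a = base, b = 2 * base + 3, c = stats::rnorm(n))
  colnames(v) <- sprintf("s%d", 1:n)
  a <- adjacency_matrix(v, power = 9)
  expect_equal(a["a", "b"], 1)       # r = 1 at any power
  expect_equal(diag(a), c(a = 0, b = 0, c = 0))
  expect_equal(a["a", "c"], abs(stats::cor(base, v["c", ]))^9)
  expect_true(isSymmetric(a))
  # closed form: r = 0.5 at power 9
  expect_equal(0.5^9, 0.001953125)
  vc <- rbind(a = base, k = rep(1, n))
  colnames(vc) <- sprintf("s%d", 1:n)
  expect_error(adjacency_matrix(vc, 9), "constant feature.*k")
})

test_that("TOM matches hand evaluation and the triple-loop oracle", {
  # 3-node clique: TOM = 1 off-diagonal
  a3 <- matrix(1, 3, 3) - diag(3)
  t3 <- tom_similarity(a3)
  expect_equal(t3, matrix(1, 3, 3))
  # single edge a_12 = 0.5: TOM_12 = (0 + 0.5)/(0.5 + 1 - 0.5) = 0.5
  a1 <- matrix(0, 3, 3)
  a1[1, 2] <- a1[2, 1] <- 0.5
  expect_equal(tom_similarity(a1)[1, 2], 0.5)
  # random matrices vs the naive O(n^3) evaluation
  set.seed(83)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    a <- matrix(stats::runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_similarity(a)
    expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
  expect_error(tom_similarity(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("soft-threshold fit table behaves and degenerates sanely", {
  set.seed(85)
  # block-structured data reaches a high signed fit at moderate power
  nfeat <- 90; nsamp <- 24
  labs <- rep(1:3, each = 30)
  sig <- matrix(stats::rnorm(3 * nsamp), 3)
  v <- sig[labs, ] + matrix(stats::rnorm(nfeat * nsamp, 0, 0.6), nfeat)
  rownames(v) <- sprintf("f%02d", 1:nfeat)
  colnames(v) <- sprintf("s%02d", 1:nsamp)
  out <- pick_soft_threshold(v, candidate_powers = 1:12)
  expect_true(out$power %in% 1:12)
  # mean connectivity is monotone non-increasing in the power
  expect_true(all(diff(out$fit_table$mean_k) <= 1e-9))
  # perfectly correlated features: adjacency all 1, degenerate fit flagged
  base <- stats::rnorm(10)
  vd <- outer(rep(1, 12), base) + outer(seq_len(12), rep(0, 10))
  vd <- vd + outer(seq_len(12), rep(1, 10))  # distinct means, identical shape
  rownames(vd) <- sprintf("g%02d", 1:12)
  colnames(vd) <- sprintf("s%02d", 1:10)
  expect_warning(outd <- pick_soft_threshold(vd), "degenerate")
  expect_true(all(is.na(outd$fit_table$r2)))
})

test_that("a planted heavy-tailed connectivity structure reaches the fit target", {
  set.seed(99)
  nsamp <- 30
  sizes <- c(60, 30, 15, 8, 4, 2)  # power-law-like hub hierarchy
  v <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    shared <- stats::rnorm(nsamp)
    t(vapply(seq_len(sizes[b]), function(i) {
      sqrt(0.85) * shared + sqrt(0.15) * stats::rnorm(nsamp)
    }, numeric(nsamp)))
  }))
  v <- rbind(v, matrix(stats::rnorm(30 * nsamp), 30))
  rownames(v) <- sprintf("f%03d", seq_len(nrow(v)))
  colnames(v) <- sprintf("s%02d", seq_len(nsamp))
  out <- pick_soft_threshold(v)
  chosen_r2 <- out$fit_table$r2[out$fit_table$power == out$power]
  expect_gte(chosen_r2, 0.8)
  # chosen power is the smallest reaching the target
  earlier <- out$fit_table$r2[out$fit_table$power < out$power]
  expect_true(all(is.na(earlier) | earlier < 0.8))
})

test_that("planted correlation blocks are detected as modules", {
  set.seed(87)
  nsamp <- 30
  mk_block <- function(n, rho = 0.9) {
    shared <- stats::rnorm(nsamp)
    t(vapply(seq_len(n), function(i) {
      sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(nsamp)
    }, numeric(nsamp)))
  }
  v <- rbind(mk_block(30), mk_block(30))
  rownames(v) <- sprintf("f%02d", 1:60)
  colnames(v) <- sprintf("s%02d", 1:nsamp)
  tom <- tom_similarity(adjacency_matrix(v, 9))
  det <- detect_modules(1 - tom, network_params(min_module_size = 30))
  mods <- setdiff(unique(det$labels), "grey")
  expect_equal(length(mods), 2L)
  expect_equal(length(unique(det$labels[1:30])), 1L)
  expect_equal(length(unique(det$labels[31:60])), 1L)
  expect_false(det$labels[1] == det$labels[31])
  # labels come from the colour list by decreasing size
  expect_true(all(mods %in% c("turquoise", "blue")))
})

test_that("identical profiles collapse into a single module", {
  nsamp <- 12
  base <- stats::rnorm(nsamp)
  v <- outer(1:40, rep(1, nsamp)) + outer(rep(1, 40), base)
  rownames(v) <- sprintf("f%02d", 1:40)
  colnames(v) <- sprintf("s%02d", 1:nsamp)
  tom <- tom_similarity(adjacency_matrix(v, 9))
  det <- detect_modules(1 - tom, network_params())
  expect_equal(length(setdiff(unique(det$labels), "grey")), 1L)
  expect_equal(sum(det$labels != "grey"), 40L)
})

test_that("eigengenes are first principal components with a fixed sign", {
  set.seed(89)
  nsamp <- 15
  prof <- stats::rnorm(nsamp)
  # identical profiles: variance explained 1, eigengene tracks the profile
  v <- outer(rep(1, 10), prof) + stats::rnorm(10)
  rownames(v) <- sprintf("f%02d", 1:10)
  colnames(v) <- sprintf("s%02d", 1:nsamp)
  eg <- module_eigengene(v)
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  expect_gt(stats::cor(eg$eigengene, prof), 0.999)
  # two anti-correlated halves: still variance 1; sign fixed by the rule
  v2 <- rbind(outer(rep(1, 6), prof), outer(rep(1, 4), -prof)) +
    stats::rnorm(10)
  rownames(v2) <- sprintf("g%02d", 1:10)
  colnames(v2) <- sprintf("s%02d", 1:nsamp)
  eg2 <- module_eigengene(v2)
  expect_equal(eg2$variance_explained, 1, tolerance = 1e-12)
  x2 <- t(scale(t(v2)))
  expect_gte(sum(eg2$eigengene * colMeans(x2)), 0)
  # sigma1^2 equals the leading eigenvalue of the standardized cross-product
  v3 <- matrix(stats::rnorm(8 * nsamp), 8,
               dimnames = list(sprintf("h%d", 1:8), sprintf("s%02d", 1:nsamp)))
  eg3 <- module_eigengene(v3)
  x3 <- t(scale(t(v3)))
  ev <- eigen(crossprod(x3), symmetric = TRUE)$values
  expect_equal(eg3$variance_explained, ev[1] / sum(ev), tolerance = 1e-10)
  expect_equal(sum(eg3$eigengene^2), 1, tolerance = 1e-12)
  # zero-variance rows are excluded with a warning
  v4 <- rbind(v3, flat = rep(2, nsamp))
  expect_warning(module_eigengene(v4), "zero-variance")
})

test_that("module merging is strict at the height cut and idempotent", {
  set.seed(91)
  nsamp <- 20
  prof <- stats::rnorm(nsamp)
  mk <- function(n, p) {
    out <- t(vapply(seq_len(n), function(i) p + stats::rnorm(nsamp, 0, 0.05),
                    numeric(nsamp)))
    out
  }
  # two modules with essentially identical eigengenes merge
  v <- rbind(mk(10, prof), mk(10, prof * 1.5 + 2))
  rownames(v) <- sprintf("f%02d", 1:20)
  colnames(v) <- sprintf("s%02d", 1:nsamp)
  labels <- stats::setNames(rep(c("blue", "turquoise"), each = 10),
                            rownames(v))
  merged <- merge_close_modules(labels, v)
  expect_equal(length(unique(merged)), 1L)
  # eigengene correlation exactly 0.7 (dissimilarity 0.3) does not merge
  # at 0.25: orthogonalise the noise so the sample correlation is exact
  a <- stats::rnorm(nsamp)
  z <- stats::resid(stats::lm(stats::rnorm(nsamp) ~ a))
  b <- 0.7 * scale(a)[, 1] + sqrt(1 - 0.49) * scale(z)[, 1]
  v2 <- rbind(mk(10, a), mk(10, b * stats::sd(a)))
  rownames(v2) <- sprintf("g%02d", 1:20)
  colnames(v2) <- sprintf("s%02d", 1:nsamp)
  labels2 <- stats::setNames(rep(c("blue", "turquoise"), each = 10),
                             rownames(v2))
  merged2 <- merge_close_modules(labels2, v2)
  expect_equal(length(unique(merged2)), 2L)
  # idempotence / fixpoint: a second pass changes nothing
  expect_equal(merge_close_modules(merged2, v2), merged2)
})

test_that("module-trait association returns exact correlations and null p-values", {
  nsamp <- 20
  root <- rep(c(1, 0), c(5, 15))
  eg <- rbind(m1 = scale(root)[, 1], m2 = scale(seq_len(nsamp))[, 1])
  colnames(eg) <- sprintf("s%02d", 1:nsamp)
  traits <- data.frame(root = root, constant = rep(1, nsamp))
  out <- module_trait_association(eg, traits)
  expect_equal(out$correlation["m1", "root"], 1)
  expect_true(is.na(out$correlation["m1", "constant"]))
  expect_lt(out$p_value["m1", "root"], 1e-12)
  # p-values match the t transform used by cor.test
  set.seed(93)
  for (i in 1:20) {
    e <- stats::rnorm(nsamp)
    tr <- stats::rnorm(nsamp)
    got <- module_trait_association(matrix(e, 1, dimnames = list("m", NULL)),
                                    data.frame(x = tr))
    ref <- stats::cor.test(e, tr)
    expect_equal(got$p_value[1, 1], ref$p.value, tolerance = 1e-10)
  }
  # null p-values are approximately uniform
  set.seed(95)
  ps <- replicate(1000, {
    e <- stats::rnorm(12)
    tr <- stats::rnorm(12)
    module_trait_association(matrix(e, 1), data.frame(x = tr))$p_value[1, 1]
  })
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.05)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.05)
})

test_that("module composition percentages reproduce the reference shares", {
  # lincRNA counts per module over a 2771 total; coding counts arbitrary
  lnc_counts <- c(MEturquoise = 522, MEpink = 46, MEblue = 785, MEgreen = 210,
                  MEyellow = 632, MEred = 208, MEsalmon = 5, MEblack = 56,
                  MEbrown = 217, MEpurple = 11, MEmagenta = 34, MEtan = 27,
                  MEgreenyellow = 17, MEcyan = 1)
  labels <- rep(names(lnc_counts), lnc_counts)
  ids <- sprintf("l%04d", seq_along(labels))
  labels <- stats::setNames(labels, ids)
  types <- stats::setNames(rep("lncRNA", length(ids)), ids)
  out <- module_summary(labels, types)
  expect_equal(sum(out$n_lncRNA), 2771)
  expect_equal(out$percent_lncRNA[out$module == "MEblue"], 28.33)
  expect_equal(out$percent_lncRNA[out$module == "MEyellow"], 22.81)
  expect_equal(out$percent_lncRNA[out$module == "MEturquoise"], 18.84)
  # a single module owns 100%
  single <- module_summary(stats::setNames(rep("m", 4), letters[1:4]),
                           stats::setNames(rep("lncRNA", 4), letters[1:4]))
  expect_equal(single$percent_lncRNA, 100)
})

test_that("planted modules are recovered at moderate noise (5-seed ARI)", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:5, function(s) {
    fx <- cached_sim(seed = s, noise_sd = 0.3)
    e <- fx$expr
    tis <- e$samples$condition == "none"
    v <- e$values[, tis]
    scr <- anova_screen(v, e$samples$tissue[tis])
    sel <- scr$feature_id[scr$selected]
    det <- detect_modules(1 - tom_similarity(adjacency_matrix(v[sel, ], 9)),
                          network_params())
    lab <- merge_close_modules(det$labels, v[sel, ])
    tr <- fx$sim$truth
    planted <- intersect(tr$features$feature_id[!is.na(tr$features$module)],
                         sel)
    mclust::adjustedRandIndex(
      lab[planted], tr$features$module[match(planted, tr$features$feature_id)]
    )
  }, 0)
  expect_gte(mean(aris), 0.9)
})
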