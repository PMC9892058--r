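test_that("ORF finder handles hand-readable cases", {
  orf <- find_longest_orf("ATGAAATAG")
  expect_equal(orf$length_nt, 9L)
  expect_equal(orf$length_aa, 2L)
  expect_equal(orf$start, 1L)
  expect_null(find_longest_orf("CCCCCCCCC"))
  # codons containing N never match ATG or a stop
  expect_null(find_longest_orf("ATNAAATAG"))
  expect_null(find_longest_orf("ATGAAATAN"))
  # stop required: an ATG running off the end is not an ORF
  expect_null(find_longest_orf("ATGAAAAAA"))
})

test_that("ORF finder matches exhaustive ATG-stop enumeration on random sequences", {
  set.seed(11)
  for (i in 1:150) {
    s <- random_dna_string(600)
    got <- find_longest_orf(s)
    want <- oracle_longest_orf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$length_nt, want$length_nt)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("filter cascade applies thresholds with the documented strictness", {
  ann <- toy_annotation()
  mk <- function(seq) {
    # an intergenic single-exon transcript far from the toy genes
    toy_transcripts(list(
      list(id = "q", chrom = "chr1", strand = "+",
           exons = list(c(20001, 20000 + nchar(seq))))
    ))
  }
  run1 <- function(seq, score1 = -1, score2 = -1, hits = character(0)) {
    filter_candidates(
      mk(seq), c(q = seq), ann, hits,
      data.frame(transcript_id = "q", score1 = score1, score2 = score2)
    )
  }
  # length < 200 rejected; exactly 200 kept
  short <- run1(strrep("C", 150))
  expect_false(short$kept)
  expect_equal(short$rejection_reason, "too_short")
  expect_true(run1(paste0(strrep("C", 100), "ATAAATAAATAA", strrep("C", 88)))$kept)
  # ORF of exactly 121 aa (366 nt) rejected, 120 aa (363 nt) kept
  orf121 <- paste0("ATG", strrep("AAA", 120), "TAA")
  r <- run1(paste0(strrep("C", 40), orf121, strrep("C", 40)))
  expect_equal(r$rejection_reason, "orf_too_long")
  orf120 <- paste0("ATG", strrep("AAA", 119), "TAA")
  expect_true(run1(paste0(strrep("C", 40), orf120, strrep("C", 40)))$kept)
  # protein hit
  ph <- run1(strrep("C", 300), hits = "q")
  expect_equal(ph$rejection_reason, "protein_hit")
  # coding potential: score exactly 0 rejects (strictly-negative rule)
  cp <- run1(strrep("C", 300), score1 = -0.5, score2 = 0)
  expect_equal(cp$rejection_reason, "coding_potential")
  expect_true(run1(strrep("C", 300), score1 = -0.001, score2 = -0.001)$kept)
})

test_that("missing coding scores follow the configured policy", {
  ann <- toy_annotation()
  tx <- toy_transcripts(list(
    list(id = "q", chrom = "chr1", strand = "+", exons = list(c(20001, 20300)))
  ))
  seqs <- c(q = strrep("C", 300))
  empty_scores <- data.frame(transcript_id = character(0),
                             score1 = numeric(0), score2 = numeric(0))
  expect_error(
    filter_candidates(tx, seqs, ann, character(0), empty_scores),
    "no coding scores"
  )
  expect_warning(
    out <- filter_candidates(tx, seqs, ann, character(0),
                             empty_scores, missing_score_policy = "lenient"),
    "without coding scores"
  )
  expect_true(out$kept)
})

test_that("cascade records the first failed filter and is order-deterministic", {
  fx <- cached_sim(seed = 1)
  sim <- fx$sim
  dec <- filter_candidates(sim$transcripts, sim$sequences, sim$annotation,
                           sim$truth$protein_hits, sim$truth$coding_scores)
  # coding transcripts fail at the sense-overlap step even though they
  # would also fail the ORF and score filters
  coding <- sim$truth$features$feature_id[sim$truth$features$type == "coding"]
  expect_true(all(dec$rejection_reason[dec$transcript_id %in% coding] ==
                    "overlaps_coding_sense"))
  expect_equal(dec$kept, is.na(dec$rejection_reason))
  # permuting input order never changes any decision
  perm <- sample(sim$transcripts$transcripts$transcript_id)
  shuffled <- subset_annotation(sim$transcripts, perm)
  shuffled$transcripts <- shuffled$transcripts[
    match(perm, shuffled$transcripts$transcript_id), ]
  dec2 <- filter_candidates(shuffled, sim$sequences, sim$annotation,
                            sim$truth$protein_hits, sim$truth$coding_scores)
  m <- match(dec$transcript_id, dec2$transcript_id)
  expect_equal(dec$kept, dec2$kept[m])
  expect_equal(dec$rejection_reason, dec2$rejection_reason[m])
  # post-hoc invariants over outputs
  kept <- dec$transcript_id[dec$kept]
  expect_true(all(nchar(sim$sequences[kept]) >= 200))
  for (id in kept) {
    orf <- find_longest_orf(sim$sequences[[id]])
    expect_true(is.null(orf) || orf$length_aa <= 120)
  }
})

test_that("location classes follow the NAT > incRNA > lincRNA precedence", {
  ann <- toy_annotation()
  # same-strand transcript inside gA's intron (1301..1500)
  inc <- toy_transcripts(list(
    list(id = "i1", chrom = "chr1", strand = "+", exons = list(c(1350, 1450)))
  ))
  ci <- classify_by_location(inc, ann)
  expect_equal(ci$class, "incRNA")
  expect_equal(ci$linked_gene, "gA")
  # opposite-strand transcript overlapping gA's exon by 50 bp
  nat <- toy_transcripts(list(
    list(id = "n1", chrom = "chr1", strand = "-", exons = list(c(1251, 1400)))
  ))
  cn <- classify_by_location(nat, ann)
  expect_equal(cn$class, "NAT")
  expect_equal(cn$linked_gene, "gA")
  # antisense inside the intron only: NAT precedence over intron containment
  nat2 <- toy_transcripts(list(
    list(id = "n2", chrom = "chr1", strand = "-", exons = list(c(1350, 1450)))
  ))
  expect_equal(classify_by_location(nat2, ann)$class, "NAT")
  # far from both genes: lincRNA with no link
  linc <- toy_transcripts(list(
    list(id = "l1", chrom = "chr1", strand = "+", exons = list(c(9000, 9400)))
  ))
  cl <- classify_by_location(linc, ann)
  expect_equal(cl$class, "lincRNA")
  expect_true(is.na(cl$linked_gene))
})

test_that("planted classes are recovered exactly from synthetic ground truth", {
  fx <- cached_sim(seed = 1)
  sim <- fx$sim
  dec <- filter_candidates(sim$transcripts, sim$sequences, sim$annotation,
                           sim$truth$protein_hits, sim$truth$coding_scores)
  kept <- subset_annotation(sim$transcripts, dec$transcript_id[dec$kept])
  cl <- classify_by_location(kept, sim$annotation)
  truth <- sim$truth$features
  m <- match(cl$transcript_id, truth$feature_id)
  expect_equal(cl$class, truth$class[m])
  has_link <- cl$class %in% c("NAT", "incRNA")
  expect_equal(cl$linked_gene[has_link], truth$linked_gene[m][has_link])
  expect_true(all(is.na(cl$linked_gene[!has_link])))
})

test_that("high-confidence flags use a strict TPM floor", {
  tpm <- matrix(c(1.0, 0.5,
                  1.01, 0.2,
                  0, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  flags <- flag_high_confidence(list(L1 = "a", L2 = "b", L3 = "c"), tpm)
  expect_equal(unname(flags), c(FALSE, TRUE, FALSE))
  # locus-level TPM is the max over member transcripts
  flags2 <- flag_high_confidence(list(L = c("a", "b")), tpm)
  expect_true(flags2[["L"]])
  expect_warning(
    miss <- flag_high_confidence(list(L = "absent"), tpm),
    "absent from the expression matrix"
  )
  expect_false(miss[["L"]])
})

test_that("class summaries report half-up percentages", {
  s <- summarize_classes(c(lincRNA = 24084, NAT = 5778, incRNA = 350))
  expect_equal(s$percent[s$class == "lincRNA"], 79.72)
  expect_equal(s$percent[s$class == "NAT"], 19.12)
  expect_equal(s$percent[s$class == "incRNA"], 1.16)
  expect_equal(sum(s$count), 30212)
  s2 <- summarize_classes(c(a = 1, b = 1, c = 0))
  expect_equal(s2$percent, c(50, 50, 0))
  expect_error(summarize_classes(character(0)), "empty")
})

test_that("locus grouping joins same-strand transcripts with exonic overlap", {
  tx <- toy_transcripts(list(
    list(id = "a", chrom = "c", strand = "+", exons = list(c(100, 200))),
    list(id = "b", chrom = "c", strand = "+", exons = list(c(150, 250))),
    list(id = "c", chrom = "c", strand = "-", exons = list(c(150, 250))),
    list(id = "d", chrom = "c", strand = "+", exons = list(c(500, 600)))
  ))
  loci <- group_loci(tx)
  expect_equal(loci[["a"]], loci[["b"]])   # overlap, same strand
  expect_false(loci[["a"]] == loci[["c"]]) # opposite strand
  expect_false(loci[["a"]] == loci[["d"]]) # no overlap
})
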