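# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms or different decompositions than
# the package code.

# exhaustive ORF scan: every ATG, first in-frame stop, no clever indexing
oracle_longest_orf <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (i in seq_len(max(0, n - 5))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      cod <- substr(s, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- j + 2 - i + 1
        if (is.null(best) || len > best$length_nt) {
          best <- list(start = i, end = j + 2, length_nt = len)
        }
        break
      }
      j <- j + 3
    }
  }
  best
}

# naive Hamming scan: compare every window character by character
oracle_hamming <- function(text, pattern, max_mismatch) {
  m <- nchar(pattern)
  out <- integer(0)
  mm <- integer(0)
  for (s in seq_len(nchar(text) - m + 1)) {
    d <- sum(strsplit(substr(text, s, s + m - 1), "")[[1]] !=
               strsplit(pattern, "")[[1]])
    if (d <= max_mismatch) {
      out <- c(out, s)
      mm <- c(mm, d)
    }
  }
  data.frame(start = out, mismatches = mm)
}

# exhaustive nested-structure enumeration (no memoisation, different
# decomposition from the package DP); only usable for very short sequences
oracle_max_pairs <- function(s, min_loop = 3) {
  ch <- strsplit(toupper(s), "")[[1]]
  ok <- function(a, b) paste0(ch[a], ch[b]) %in%
    c("AT", "TA", "CG", "GC", "GT", "TG")
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)              # i unpaired
    for (k in (i + min_loop + 1L):j) {  # i paired with k
      if (ok(i, k)) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  rec(1L, length(ch))
}

# direct triple-loop evaluation of the topological overlap formula
oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, ]); kj <- sum(a[j, ])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  tom
}

# all-pairs centre-distance filter
oracle_cis_pairs <- function(lnc, genes, window) {
  out <- character(0)
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(genes))) {
      if (lnc$chrom[i] != genes$chrom[j]) next
      d <- abs((lnc$start[i] + lnc$end[i]) / 2 -
                 (genes$start[j] + genes$end[j]) / 2)
      if (d < window) {
        out <- c(out, paste(lnc$transcript_id[i], genes$gene_id[j]))
      }
    }
  }
  sort(out)
}

# all-pairs correlation filter
oracle_trans_pairs <- function(lnc_ids, gene_ids, v, cutoff) {
  out <- character(0)
  for (a in lnc_ids) {
    for (b in gene_ids) {
      if (a == b) next
      r <- stats::cor(v[a, ], v[b, ])
      if (abs(r) > cutoff) out <- c(out, paste(a, b))
    }
  }
  sort(out)
}

# hand-written Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by direct log-space summation of
# binomial-coefficient ratios
oracle_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K]
  if (length(xs) == 0) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# local-alignment best-hit subgenome oracle (query + its reverse
# complement against each reference, best local score wins)
oracle_best_hit <- function(query, s_ref, t_ref) {
  score <- function(ref) {
    max(vapply(c(query, as.character(revcomp(query))), function(q) {
      Biostrings::pairwiseAlignment(q, ref, type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1),
        gapOpening = 2, gapExtension = 1, scoreOnly = TRUE)
    }, 0))
  }
  ss <- max(vapply(s_ref, score, 0))
  st <- max(vapply(t_ref, score, 0))
  if (ss > st) "S" else if (st > ss) "T" else "unassigned"
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
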