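#' Maximum base-pairing score of an RNA/DNA sequence (Nussinov)
#'
#' Dynamic program maximising the number of nested base pairs
#' (Watson-Crick plus the G:U wobble, written G:T in DNA space) with a
#' minimum hairpin loop length. Used as a fast structural plausibility
#' check on putative miRNA precursor windows; it is a maximum-pairing
#' surrogate, not a thermodynamic folding energy.
#'
#' @param sequence a single DNA string.
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @return integer, the maximum number of base pairs.
#' @export
nussinov_max_pairs <- function(sequence, min_loop = 3) {
  s <- seq_chars(toupper(normalize_u_to_t(sequence)))
  n <- length(s)
  if (n < min_loop + 2) return(0L)
  ok_pair <- matrix(FALSE, 5, 5,
                    dimnames = list(c("A", "C", "G", "T", "N"),
                                    c("A", "C", "G", "T", "N")))
  ok_pair["A", "T"] <- ok_pair["T", "A"] <- TRUE
  ok_pair["C", "G"] <- ok_pair["G", "C"] <- TRUE
  ok_pair["G", "T"] <- ok_pair["T", "G"] <- TRUE
  dp <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1L:(n - span)) {
      j <- i + span
      best <- max(dp[i + 1L, j], dp[i, j - 1L])
      if (ok_pair[s[i], s[j]]) best <- max(best, dp[i + 1L, j - 1L] + 1L)
      # bifurcation, vectorised over the split point
      k <- i:(j - 1L)
      best <- max(best, max(dp[i, k] + dp[cbind(k + 1L, j)]))
      dp[i, j] <- best
    }
  }
  dp[1L, n]
}

# internal: Hamming distance scan of a pattern over a text, all offsets
hamming_scan <- function(text, pattern, max_mismatch) {
  x <- utf8ToInt(text)
  p <- utf8ToInt(pattern)
  m <- length(p)
  n <- length(x)
  if (n < m) return(data.frame(start = integer(0), mismatches = integer(0)))
  mism <- integer(n - m + 1L)
  idx <- 0:(m - 1L)
  for (s in seq_len(n - m + 1L)) {
    mism[s] <- sum(x[s + idx] != p)
  }
  keep <- mism <= max_mismatch
  data.frame(start = which(keep), mismatches = mism[keep])
}

#' Detect lncRNAs that can act as miRNA precursors
#'
#' Two-stage rule: (1) an ungapped scan of each lncRNA (given strand) for
#' windows within Hamming distance `max_mismatch` of the mature miRNA;
#' (2) a hairpin plausibility check — the maximum base-pairing score
#' ([nussinov_max_pairs()]) of the site plus `window` nt of flank on each
#' side must reach `min_pairs_fraction * window`.
#'
#' @param mature_mirnas named character vector of mature miRNA sequences
#'   (18-26 nt; U is normalised to T; other letters are an error).
#' @param lncrnas named character vector of lncRNA spliced sequences.
#' @param max_mismatch maximum mismatches in the mature-match stage
#'   (default 2).
#' @param window flank length in nt on each side of the match (default 80).
#' @param min_pairs_fraction hairpin pass threshold as a fraction of
#'   `window` (default 0.5).
#' @param min_loop minimum hairpin loop for the pairing DP (default 3).
#' @param only_passing drop sites failing the hairpin check (default TRUE).
#' @return data.frame (`lncRNA_id`, `miRNA_id`, `start`, `end`,
#'   `mismatches`, `hairpin_score`, `passes_hairpin`); coordinates are
#'   1-based inclusive on the lncRNA and the interval length equals the
#'   miRNA length.
#' @export
find_precursor_sites <- function(mature_mirnas, lncrnas, max_mismatch = 2,
                                 window = 80, min_pairs_fraction = 0.5,
                                 min_loop = 3, only_passing = TRUE) {
  mirnas <- normalize_u_to_t(mature_mirnas)
  if (any(grepl("[^ACGT]", mirnas))) {
    lnc_stop("mature miRNAs must contain only A/C/G/T/U")
  }
  rows <- list()
  for (li in seq_along(lncrnas)) {
    lseq <- toupper(lncrnas[[li]])
    for (mi in seq_along(mirnas)) {
      mseq <- mirnas[[mi]]
      hits <- hamming_scan(lseq, mseq, max_mismatch)
      if (nrow(hits) == 0) next
      for (h in seq_len(nrow(hits))) {
        st <- hits$start[h]
        en <- st + nchar(mseq) - 1L
        flank <- substring(lseq, max(1L, st - window),
                           min(nchar(lseq), en + window))
        score <- nussinov_max_pairs(flank, min_loop = min_loop)
        rows[[length(rows) + 1L]] <- data.frame(
          lncRNA_id = names(lncrnas)[li], miRNA_id = names(mirnas)[mi],
          start = st, end = en, mismatches = hits$mismatches[h],
          hairpin_score = score,
          passes_hairpin = score >= min_pairs_fraction * window
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    lncRNA_id = character(0), miRNA_id = character(0), start = integer(0),
    end = integer(0), mismatches = integer(0), hairpin_score = integer(0),
    passes_hairpin = logical(0)
  )
  if (only_passing) out <- out[out$passes_hairpin, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: pair class between a miRNA base (5'->3') and the lncRNA base it
# faces when the site is read 3'->5': "wc", "gu" or "mm"
pair_class <- function(mi_base, site_base) {
  ifelse(COMPLEMENT[mi_base] == site_base, "wc",
         ifelse((mi_base == "G" & site_base == "T") |
                (mi_base == "T" & site_base == "G"), "gu", "mm"))
}

#' Predict endogenous target mimic (eTM) sites
#'
#' An eTM site pairs with the miRNA like a cleavage target except for a
#' short unpaired bulge on the lncRNA side opposite the cleavage-site
#' region, which blocks slicing. The rule set: perfect Watson-Crick
#' pairing at miRNA positions 2-8 (seed); a lncRNA bulge of
#' `bulge_min`-`bulge_max` nt inserted after a miRNA position in
#' `bulge_positions`; at most `max_mismatch` mismatches outside the seed,
#' with G:U wobbles allowed freely; a bulge-free perfect complement is a
#' cleavage target, not an eTM, and is never reported. Overlapping sites
#' for the same lncRNA-miRNA pair are deduplicated keeping the fewest
#' mismatches, then the leftmost site.
#'
#' @inheritParams find_precursor_sites
#' @param bulge_min,bulge_max allowed bulge lengths in nt (defaults 2 and 5).
#' @param bulge_positions miRNA positions (5'-anchored) after which the
#'   bulge may sit (default 9:11).
#' @param max_mismatch maximum non-seed mismatches (default 3).
#' @return data.frame (`lncRNA_id`, `miRNA_id`, `start`, `end`,
#'   `bulge_position`, `bulge_length`, `mismatch_count`, `gu_count`,
#'   `pairing`, `site_seq`); `pairing` uses `|` (Watson-Crick), `o`
#'   (G:U), `.` (mismatch) and `-` (bulge), written along the miRNA 5'->3'.
#' @export
predict_etm <- function(mature_mirnas, lncrnas, bulge_min = 2, bulge_max = 5,
                        bulge_positions = 9:11, max_mismatch = 3) {
  mirnas <- normalize_u_to_t(mature_mirnas)
  if (any(grepl("[^ACGT]", mirnas))) {
    lnc_stop("mature miRNAs must contain only A/C/G/T/U")
  }
  rows <- list()
  for (mi in seq_along(mirnas)) {
    mseq <- mirnas[[mi]]
    m <- nchar(mseq)
    mch <- seq_chars(mseq)
    # seed (miRNA 2-8) must be perfectly paired; on the site read 5'->3'
    # that is the reverse complement of the seed, ending 1 nt before the
    # site's 3' end (miRNA position 1 faces the site's last base)
    seed_rc <- revcomp(substr(mseq, 2, 8))
    for (li in seq_along(lncrnas)) {
      lseq <- toupper(lncrnas[[li]])
      n <- nchar(lseq)
      qpos <- gregexpr(seed_rc, lseq, fixed = TRUE)[[1]]
      if (qpos[1] == -1) next
      for (q in qpos) {
        for (B in bulge_min:bulge_max) {
          L <- m + B
          for (p in bulge_positions) {
            if (p + 1L > m) next
            # site start s satisfies: seed occupies site positions
            # (L-7)..(L-1), i.e. s + L - 8 == q
            s <- q - L + 8L
            if (s < 1L || s + L - 1L > n) next
            site <- seq_chars(substring(lseq, s, s + L - 1L))
            t3 <- rev(site)  # site read 3'->5', aligned to miRNA 5'->3'
            # miRNA position i faces t3[i] (i <= p) or t3[i + B] (i > p)
            face <- c(t3[seq_len(p)], t3[(p + B + 1L):L])
            cls <- pair_class(mch, face)
            if (any(cls[2:8] != "wc")) next   # seed must be perfect WC
            nonseed <- setdiff(seq_len(m), 2:8)
            mm <- sum(cls[nonseed] == "mm")
            if (mm > max_mismatch) next
            gu <- sum(cls[nonseed] == "gu")
            glyph <- c(wc = "|", gu = "o", mm = ".")[cls]
            pairing <- paste(c(glyph[seq_len(p)], rep("-", B),
                               glyph[(p + 1L):m]), collapse = "")
            rows[[length(rows) + 1L]] <- data.frame(
              lncRNA_id = names(lncrnas)[li], miRNA_id = names(mirnas)[mi],
              start = s, end = s + L - 1L, bulge_position = p,
              bulge_length = B, mismatch_count = mm, gu_count = gu,
              pairing = pairing,
              site_seq = substring(lseq, s, s + L - 1L)
            )
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      lncRNA_id = character(0), miRNA_id = character(0), start = integer(0),
      end = integer(0), bulge_position = integer(0), bulge_length = integer(0),
      mismatch_count = integer(0), gu_count = integer(0),
      pairing = character(0), site_seq = character(0)
    ))
  }
  out <- do.call(rbind, rows)
  # dedupe overlapping sites per (lncRNA, miRNA): fewest mismatches, then
  # smallest bulge, then leftmost
  out <- out[order(out$lncRNA_id, out$miRNA_id, out$mismatch_count,
                   out$bulge_length, out$start), ]
  keep <- logical(nrow(out))
  for (grp in split(seq_len(nrow(out)),
                    paste(out$lncRNA_id, out$miRNA_id))) {
    kept_iv <- matrix(numeric(0), ncol = 2)
    for (i in grp) {
      overlaps <- nrow(kept_iv) > 0 &&
        any(out$start[i] <= kept_iv[, 2] & out$end[i] >= kept_iv[, 1])
      if (!overlaps) {
        keep[i] <- TRUE
        kept_iv <- rbind(kept_iv, c(out$start[i], out$end[i]))
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$lncRNA_id, out$miRNA_id, out$start), ]
  rownames(out) <- NULL
  out
}

#' Aligned eTM site table for sequence-logo construction
#'
#' Pads the bulge region of each site with `-` so all sites of one miRNA
#' reach a common width, keeping the pairing regions in register.
#'
#' @param sites data.frame from [predict_etm()].
#' @return named list, one character vector of equal-width aligned site
#'   sequences (5'->3') per miRNA.
#' @export
etm_site_table <- function(sites) {
  if (nrow(sites) == 0) lnc_stop("no eTM sites to align")
  out <- lapply(split(sites, sites$miRNA_id), function(d) {
    bmax <- max(d$bulge_length)
    vapply(seq_len(nrow(d)), function(i) {
      s <- d$site_seq[i]
      L <- nchar(s)
      B <- d$bulge_length[i]
      p <- d$bulge_position[i]
      # bulge occupies site positions (L - p - B + 1)..(L - p)
      left <- substring(s, 1, L - p)
      right <- substring(s, L - p + 1, L)
      paste0(substring(left, 1, nchar(left) - B),
             substring(left, nchar(left) - B + 1, nchar(left)),
             strrep("-", bmax - B), right)
    }, "")
  })
  out
}
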