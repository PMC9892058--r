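#' Round half away from zero to a fixed number of decimals
#'
#' Percentage tables in this package are reported with conventional
#' "half-up" rounding (0.005 -> 0.01), not the banker's rounding of
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: stop with a consistent prefix
lnc_stop <- function(...) stop(..., call. = FALSE)

lnc_warn <- function(...) warning(..., call. = FALSE)

# internal: check a sequence uses only the DNA alphabet (with N)
check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    lnc_stop(what, " contains characters outside the ",
             if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}", " alphabet")
  }
  invisible(x)
}

# internal: U -> T normalisation for RNA-space inputs (mature miRNAs)
normalize_u_to_t <- function(x) {
  chartr("uU", "tT", x) |> toupper()
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# internal: complement map for single bases stored as character vectors
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# internal: split a sequence into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
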