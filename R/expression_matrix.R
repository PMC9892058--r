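#' Expression matrix with sample metadata
#'
#' Lightweight container pairing a features-by-samples numeric matrix with a
#' sample sheet (tissue and condition per sample) and a unit flag. Most
#' statistical functions in the package accept either this container or a
#' plain matrix plus metadata vectors; the container is what the I/O layer
#' and the pipeline pass around.
#'
#' @param values numeric matrix, rows = features, columns = samples; no
#'   negative entries.
#' @param samples data.frame with columns `sample`, `tissue`, `condition`
#'   (condition one of `"before"`, `"after"`, `"none"`); one row per matrix
#'   column, in column order.
#' @param unit `"counts"` or `"TPM"`. TPM columns must each sum to 1e6
#'   (relative tolerance 1e-6); degenerate all-zero columns are permitted.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, samples, unit = c("counts", "TPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    lnc_stop("values must be a numeric matrix")
  }
  if (any(values < 0)) lnc_stop("expression values must be non-negative")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    lnc_stop("values must carry feature rownames and sample colnames")
  }
  samples <- as.data.frame(samples)
  need <- c("sample", "tissue", "condition")
  if (!all(need %in% names(samples))) {
    lnc_stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (!identical(as.character(samples$sample), colnames(values))) {
    lnc_stop("sample sheet rows must match matrix columns in order")
  }
  if (!all(samples$condition %in% c("before", "after", "none"))) {
    lnc_stop("condition must be one of before/after/none")
  }
  if (unit == "TPM") {
    cs <- colSums(values)
    live <- cs > 0
    if (any(abs(cs[live] - 1e6) > 1e-6 * 1e6)) {
      lnc_stop("TPM columns must sum to 1e6 (rel. tol 1e-6)")
    }
  }
  structure(
    list(values = values, samples = samples, unit = unit),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d features x %d samples [%s]\n",
    nrow(x$values), ncol(x$values), x$unit
  ))
  cat("tissues:", paste(unique(x$samples$tissue), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# internal: accept an ExpressionMatrix or a plain matrix
em_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else x
}

em_tissues <- function(x, sample_tissues = NULL) {
  if (!is.null(sample_tissues)) return(as.character(sample_tissues))
  if (inherits(x, "ExpressionMatrix")) return(as.character(x$samples$tissue))
  lnc_stop("sample_tissues must be supplied for a plain matrix")
}

em_conditions <- function(x, conditions = NULL) {
  if (!is.null(conditions)) return(as.character(conditions))
  if (inherits(x, "ExpressionMatrix")) return(as.character(x$samples$condition))
  lnc_stop("conditions must be supplied for a plain matrix")
}
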