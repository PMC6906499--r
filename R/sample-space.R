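#' Define the gene-by-disease sample space
#'
#' The sample space of drug development is modelled as the matrix of all
#' unique gene-disease pairings: every protein-coding gene crossed with every
#' common human disease. A subset of genes is causal for each disease and an
#' independent subset of genes encodes druggable proteins. The defaults are
#' the base-case parameterisation: 20,000 protein-coding genes, 10,000
#' complex diseases, 4,000 druggable genes and an average of 100 causal genes
#' per disease.
#'
#' @param n_genes Number of protein-coding genes (rows of the matrix).
#' @param n_diseases Number of common human diseases (columns).
#' @param n_druggable Number of genes encoding druggable proteins.
#' @param causal_per_disease Average number of causal genes per disease. May
#'   be non-integer when used as an average in the analytic formulas; the
#'   simulator requires an integer per-disease count.
#' @return An object of class `sample_space`.
#' @examples
#' space <- sample_space()
#' p_causal(space)
#' @export
sample_space <- function(n_genes = 20000, n_diseases = 10000,
                         n_druggable = 4000, causal_per_disease = 100) {
  n_genes <- check_count(n_genes, "n_genes")
  n_diseases <- check_count(n_diseases, "n_diseases")
  n_druggable <- check_count(n_druggable, "n_druggable")
  if (!is.numeric(causal_per_disease) || length(causal_per_disease) != 1L ||
      is.na(causal_per_disease) || causal_per_disease < 0) {
    abort_targetodds("`causal_per_disease` must be a single non-negative number.",
                     "targetodds_invalid_argument")
  }
  if (n_druggable > n_genes) {
    abort_targetodds("`n_druggable` cannot exceed `n_genes`.",
                     "targetodds_invalid_argument")
  }
  if (causal_per_disease > n_genes) {
    abort_targetodds("`causal_per_disease` cannot exceed `n_genes`.",
                     "targetodds_invalid_argument")
  }
  structure(
    list(
      n_genes = n_genes,
      n_diseases = n_diseases,
      n_druggable = n_druggable,
      causal_per_disease = as.double(causal_per_disease)
    ),
    class = "sample_space"
  )
}

#' @export
print.sample_space <- function(x, ...) {
  cat("Gene x disease sample space\n")
  cat(sprintf("  genes:               %s\n", format(x$n_genes, big.mark = ",")))
  cat(sprintf("  diseases:            %s\n", format(x$n_diseases, big.mark = ",")))
  cat(sprintf("  druggable genes:     %s\n", format(x$n_druggable, big.mark = ",")))
  cat(sprintf("  causal per disease:  %s\n", format(x$causal_per_disease, big.mark = ",")))
  cat(sprintf("  P(causal) = %.4g, P(druggable) = %.4g, P(causal & druggable) = %.4g\n",
              p_causal(x), p_druggable(x), p_causal_druggable(x)))
  invisible(x)
}

check_space <- function(space) {
  if (!inherits(space, "sample_space")) {
    abort_targetodds("`space` must be created with `sample_space()`.",
                     "targetodds_invalid_argument")
  }
  space
}

#' Probability that a random gene-disease pairing is causal
#'
#' The fraction of causal pairings in the sample space, equal to the average
#' number of causal genes per disease over the genome size. This is also the
#' prior truth fraction (gamma) for a discovery experiment whose hypotheses
#' are random picks from the space; it does not depend on the number of
#' diseases considered.
#'
#' @inheritParams therapeutic_partition
#' @return A probability.
#' @export
p_causal <- function(space) {
  check_space(space)
  space$causal_per_disease / space$n_genes
}

#' Probability that a random gene-disease pairing involves a druggable gene
#'
#' @inheritParams therapeutic_partition
#' @return A probability.
#' @export
p_druggable <- function(space) {
  check_space(space)
  space$n_druggable / space$n_genes
}

#' Probability that a random pairing is both causal and druggable
#'
#' Causality and druggability are modelled as independent gene labels, so the
#' unrestricted probability is the product of [p_causal()] and
#' [p_druggable()]. Restricting the sampling frame to the druggable genome
#' removes the druggability factor: among druggable genes, every causal gene
#' is automatically causal-and-druggable, raising the prior truth fraction by
#' the reciprocal of the druggable fraction (five-fold under the defaults).
#'
#' @inheritParams therapeutic_partition
#' @param restrict_to_druggable If `TRUE`, the sampling frame is the
#'   druggable genome rather than the whole genome.
#' @return A probability.
#' @export
p_causal_druggable <- function(space, restrict_to_druggable = FALSE) {
  check_space(space)
  if (isTRUE(restrict_to_druggable)) {
    p_causal(space)
  } else {
    p_causal(space) * p_druggable(space)
  }
}

#' Partition the genome of a single disease by causality and druggability
#'
#' For a disease with `causal_per_disease` causal genes, re-assorts the
#' genome into the four expected classes: causal and druggable, causal but
#' not druggable, druggable but not causal, and neither. Counts are
#' expectations under independent labels and sum exactly to `n_genes`.
#'
#' @param space A [sample_space()].
#' @return A tibble with columns `causal`, `druggable` and `genes`.
#' @examples
#' therapeutic_partition(sample_space())
#' @export
therapeutic_partition <- function(space) {
  check_space(space)
  c_genes <- space$causal_per_disease
  p_t <- p_druggable(space)
  causal_druggable <- c_genes * p_t
  tibble::tibble(
    causal = c(TRUE, TRUE, FALSE, FALSE),
    druggable = c(TRUE, FALSE, TRUE, FALSE),
    genes = c(
      causal_druggable,
      c_genes - causal_druggable,
      (space$n_genes - c_genes) * p_t,
      (space$n_genes - c_genes) * (1 - p_t)
    )
  )
}
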