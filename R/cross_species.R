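# Cross-species overlap of regulated gene sets over one-to-one ortholog
# pairs. The pair universe is the only comparable ground: genes without an
# ortholog in the other species are excluded from all overlap statistics.

#' Overlap of two species' regulated sets over ortholog pairs
#'
#' Counts, over the pair universe, pairs regulated in species A, in species
#' B, and in both, and tests association with a two-tailed Fisher exact test
#' on the 2x2 pair table. The hypergeometric upper tail (probability of an
#' overlap at least this large) is reported alongside.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (one-to-one).
#' @param set_a regulated gene ids in species A (A identifiers).
#' @param set_b regulated gene ids in species B (B identifiers).
#' @return object of class `overlap_result`: list with `n_pairs`,
#'   `a_regulated`, `b_regulated`, `both`, `enrichment`, `p_value`,
#'   `p_upper_tail`.
#' @export
ortholog_overlap <- function(pairs, set_a, set_b) {
  validate_ortholog_pairs(pairs)
  in_a <- pairs$gene_a %in% set_a
  in_b <- pairs$gene_b %in% set_b
  n_pairs <- nrow(pairs)
  a <- sum(in_a); b <- sum(in_b); both <- sum(in_a & in_b)
  enr <- if (a > 0 && b > 0) (both / n_pairs) / ((a / n_pairs) * (b / n_pairs))
         else NA_real_
  p <- if (a > 0 && b > 0 && n_pairs > 0) fisher_two_tailed(both, a, b, n_pairs)
       else 1
  p_upper <- if (n_pairs > 0 && a > 0 && b > 0)
    stats::phyper(both - 1, a, n_pairs - a, b, lower.tail = FALSE) else 1
  structure(list(n_pairs = n_pairs, a_regulated = a, b_regulated = b,
                 both = both, enrichment = enr, p_value = p,
                 p_upper_tail = p_upper),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap_result over", x$n_pairs, "ortholog pairs\n")
  cat("  regulated in A:", x$a_regulated, "| in B:", x$b_regulated,
      "| in both:", x$both, "\n")
  cat("  enrichment:", signif(x$enrichment, 4),
      "| two-tailed Fisher p:", format(x$p_value, digits = 3),
      "| upper-tail p:", format(x$p_upper_tail, digits = 3), "\n")
  invisible(x)
}

#' Concordance of the top-k genes of one species with the other's regulated set
#'
#' Restricts the ranked species-B list to genes with an ortholog pair, takes
#' the first k (ties in the caller's ranking broken by gene id), and returns
#' the fraction whose species-A ortholog is regulated.
#'
#' @param ranked_b species-B gene ids ordered by decreasing fold change.
#' @param set_a regulated gene ids in species A.
#' @param pairs ortholog pair data.frame.
#' @param k number of top genes to examine (>= 1).
#' @return fraction in \[0, 1\].
#' @export
top_k_concordance <- function(ranked_b, set_a, pairs, k) {
  if (k < 1) isc_stop("k must be >= 1", "isc_domain_error")
  validate_ortholog_pairs(pairs)
  keep <- ranked_b %in% pairs$gene_b
  eligible <- ranked_b[keep]
  if (k > length(eligible))
    isc_stop("k exceeds the number of ranked genes with an ortholog",
             "isc_domain_error")
  top <- eligible[seq_len(k)]
  partner <- pairs$gene_a[match(top, pairs$gene_b)]
  mean(partner %in% set_a)
}
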