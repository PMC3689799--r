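# Two-tailed Fisher exact enrichment of gene categories within regulated
# sets, and the secretome size/cysteine classifier.

#' Two-tailed Fisher exact test from enrichment counts
#'
#' Exact hypergeometric two-sided p-value for the 2x2 table
#' \[\[k, K-k\], \[n-k, G-K-n+k\]\]: the sum of the probabilities of all
#' tables (with the same margins) whose probability does not exceed that of
#' the observed table — the minimum-likelihood two-sided convention.
#'
#' @param k regulated genes in the category.
#' @param K category size in the universe.
#' @param n regulated-set size.
#' @param G universe size.
#' @return p-value in (0, 1\].
#' @export
fisher_two_tailed <- function(k, K, n, G) {
  if (k < 0 || K > G || n > G || k > K || k > n || k < n - (G - K))
    isc_stop("inconsistent counts: need 0 <= k <= min(K, n), K <= G, n <= G, k >= n-(G-K)",
             "isc_domain_error")
  support <- max(0, n - (G - K)):min(K, n)
  probs <- stats::dhyper(support, K, G - K, n)
  p_obs <- stats::dhyper(k, K, G - K, n)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Enrichment factor
#'
#' Ratio of the category's frequency in the regulated set to its frequency in
#' the universe: (k/K)/(n/G), equivalently (k/n)/(K/G). Symmetric in the
#' roles of category and regulated set.
#'
#' @inheritParams fisher_two_tailed
#' @return enrichment factor; 1 means no enrichment.
#' @export
enrichment_factor <- function(k, K, n, G) {
  if (K <= 0 || n <= 0)
    isc_stop("K and n must be positive", "isc_domain_error")
  (k / K) / (n / G)
}

#' Enrichment of annotation categories in a regulated gene set
#'
#' @param regulated character vector of regulated gene ids.
#' @param categories named list: category label -> character vector of member
#'   gene ids. Members must belong to the universe.
#' @param universe character vector of all gene ids considered.
#' @return data.frame sorted by p-value: `category, k, K, n, G, fraction_pct`
#'   (percentage of the category that is regulated), `enrichment, p_value`.
#'   With an empty regulated set, enrichment is 0 and p is 1.
#' @export
enrich_categories <- function(regulated, categories, universe) {
  regulated <- intersect(regulated, universe)
  n <- length(regulated)
  G <- length(universe)
  rows <- lapply(names(categories), function(lab) {
    members <- categories[[lab]]
    outside <- setdiff(members, universe)
    if (length(outside) > 0)
      isc_stop(paste0("category '", lab, "' has member(s) outside the universe: ",
                      paste(utils::head(outside, 3), collapse = ", ")),
               "isc_validation_error")
    K <- length(members)
    k <- length(intersect(members, regulated))
    enr <- if (n == 0 || K == 0) 0 else enrichment_factor(k, K, n, G)
    p <- if (n == 0 || K == 0) 1 else fisher_two_tailed(k, K, n, G)
    data.frame(category = lab, k = k, K = K, n = n, G = G,
               fraction_pct = if (K > 0) 100 * k / K else NA_real_,
               enrichment = enr, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}

#' Secretome size / cysteine-content labels for one protein
#'
#' Labels: EXTRACELLULAR for any secreted protein; SMALL_EXTRACELLULAR when
#' additionally shorter than 250 aa (strict); CYS_RICH_3_5 / CYS_RICH_6 when
#' a small extracellular protein's cysteine content exceeds 3.5% / 6% of its
#' length. Missing fields simply yield no corresponding label.
#'
#' @param is_secreted logical (may be NA).
#' @param length_aa protein length in amino acids (may be NA).
#' @param cys_count number of cysteines (may be NA).
#' @return character vector of labels (possibly empty).
#' @export
classify_secretome <- function(is_secreted, length_aa = NA, cys_count = NA) {
  labels <- character(0)
  if (isTRUE(is_secreted)) {
    labels <- "EXTRACELLULAR"
    if (!is.na(length_aa) && length_aa < 250) {
      labels <- c(labels, "SMALL_EXTRACELLULAR")
      if (!is.na(cys_count)) {
        pct <- 100 * cys_count / length_aa
        if (pct > 3.5) labels <- c(labels, "CYS_RICH_3_5")
        if (pct > 6) labels <- c(labels, "CYS_RICH_6")
      }
    }
  }
  labels
}

#' Secretome category sets from a gene map
#'
#' Applies [classify_secretome()] to every gene carrying the secreted /
#' length / cysteine annotations and returns the label -> gene-id sets, ready
#' for [enrich_categories()].
#'
#' @param gene_map gene map with columns `secreted`, `length_aa`, `cys_count`.
#' @return named list of character vectors.
#' @export
secretome_categories <- function(gene_map) {
  labs <- c("EXTRACELLULAR", "SMALL_EXTRACELLULAR", "CYS_RICH_3_5", "CYS_RICH_6")
  out <- stats::setNames(vector("list", length(labs)), labs)
  for (l in labs) out[[l]] <- character(0)
  for (i in seq_len(nrow(gene_map))) {
    got <- classify_secretome(gene_map$secreted[i], gene_map$length_aa[i],
                              gene_map$cys_count[i])
    for (l in got) out[[l]] <- c(out[[l]], gene_map$gene_id[i])
  }
  out
}
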