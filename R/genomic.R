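# Genomic-distribution statistics: maximal runs of adjacent coregulated
# genes, the analytic random-placement null with embedded-run corrections,
# Monte-Carlo and exact-enumeration validation, chromosome-level enrichment,
# and sliding-window density scans.
#
# The null model treats the genome as a single concatenated sequence of g
# genes of which a fraction f is regulated. The expected number of windows of
# n consecutive regulated genes is c_n = f^n * g; maximal-run expectations
# N_n follow by subtracting runs embedded in longer runs (a run of m contains
# m - n + 1 windows of size n), top-down from n = nmax:
#   N_nmax = c_nmax;  N_n = c_n - sum_{m > n} (m - n + 1) N_m.

#' Detect maximal runs of regulated genes along chromosomes
#'
#' A maximal run is a longest block of consecutive genes (in order_index
#' order, within one chromosome) that all belong to the regulated set. Runs
#' never span chromosome boundaries; UNPLACED genes are excluded.
#'
#' @param gene_map validated gene map.
#' @param regulated character vector of regulated gene ids; all must occur in
#'   the map.
#' @return object of class `run_set`: list with `runs` (data.frame
#'   chromosome, start_index, length), `counts_by_length` (named vector over
#'   run lengths >= 2), `singletons`, `n_regulated_placed`.
#' @export
detect_runs <- function(gene_map, regulated) {
  missing <- setdiff(regulated, gene_map$gene_id)
  if (length(missing) > 0)
    isc_stop(paste0("regulated gene(s) absent from gene map: ",
                    paste(utils::head(missing, 5), collapse = ", ")),
             "isc_validation_error")
  placed <- gene_map[gene_map$chromosome != "UNPLACED", , drop = FALSE]
  runs <- list()
  for (chr in unique(placed$chromosome)) {
    sub <- placed[placed$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$order_index), , drop = FALSE]
    flags <- sub$gene_id %in% regulated
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    if (length(hit) > 0)
      runs[[chr]] <- data.frame(chromosome = chr,
                                start_index = sub$order_index[starts[hit]],
                                length = r$lengths[hit],
                                stringsAsFactors = FALSE)
  }
  runs <- if (length(runs) > 0) do.call(rbind, runs)
          else data.frame(chromosome = character(0), start_index = integer(0),
                          length = integer(0))
  rownames(runs) <- NULL
  lens <- runs$length
  counts <- table(factor(lens[lens >= 2]))
  structure(list(
    runs = runs,
    counts_by_length = stats::setNames(as.numeric(counts), names(counts)),
    singletons = sum(lens == 1),
    n_regulated_placed = sum(placed$gene_id %in% regulated)
  ), class = "run_set")
}

#' @export
print.run_set <- function(x, ...) {
  cat("run_set:", nrow(x$runs), "maximal runs;", x$singletons, "singletons;",
      x$n_regulated_placed, "regulated placed genes\n")
  if (length(x$counts_by_length) > 0) {
    cat("  runs by length:\n")
    print(x$counts_by_length)
  }
  invisible(x)
}

#' Expected window counts under random placement
#'
#' c_n = f^n * g, the expected number of windows of n consecutive regulated
#' genes in a concatenated genome of g genes with regulated fraction f.
#'
#' @param f regulated fraction in \[0, 1\].
#' @param g total number of genes.
#' @param nmax largest window size. Default 10.
#' @return named numeric vector c_2..c_nmax.
#' @export
null_window_counts <- function(f, g, nmax = 10L) {
  if (f < 0 || f > 1) isc_stop("f must lie in [0, 1]", "isc_domain_error")
  n <- 2:nmax
  stats::setNames(f^n * g, n)
}

#' Correct window counts for runs embedded in longer runs
#'
#' Converts window counts c_n into expected counts N_n of maximal runs of
#' exactly n genes: N_nmax = c_nmax, then descending
#' N_n = c_n - sum_\{m > n\} (m - n + 1) N_m (a maximal run of m adjacent
#' regulated genes contains m - n + 1 windows of size n).
#'
#' @param c named numeric vector of window counts for n = 2..nmax (as from
#'   [null_window_counts()]).
#' @return named numeric vector N_2..N_nmax.
#' @export
corrected_run_counts <- function(c) {
  ns <- as.integer(names(c))
  if (length(ns) == 0 || any(is.na(ns)) || !identical(ns, min(ns):max(ns)))
    isc_stop("c must be named with a contiguous integer range of run sizes",
             "isc_domain_error")
  nmax <- max(ns)
  N <- stats::setNames(numeric(length(ns)), ns)
  N[as.character(nmax)] <- c[[as.character(nmax)]]
  if (nmax > min(ns)) {
    for (n in seq(nmax - 1L, min(ns))) {
      m <- (n + 1L):nmax
      N[as.character(n)] <- c[[as.character(n)]] -
        sum((m - n + 1) * N[as.character(m)])
    }
  }
  N
}

#' Expected fraction of regulated genes lying in runs of a minimum size
#'
#' sum_\{n >= min_size\} n * N_n / (f * g): of all regulated genes, the
#' expected proportion found inside maximal runs of `min_size` or more under
#' random placement.
#'
#' @inheritParams null_window_counts
#' @param min_size smallest run size counted (>= 2). Default 4.
#' @return fraction in \[0, 1\].
#' @export
expected_fraction_in_runs <- function(f, g, min_size = 4L, nmax = 10L) {
  if (f * g == 0) isc_stop("f * g must be positive", "isc_domain_error")
  if (min_size < 2) isc_stop("min_size must be >= 2", "isc_domain_error")
  N <- corrected_run_counts(null_window_counts(f, g, nmax))
  ns <- as.integer(names(N))
  keep <- ns >= min_size
  sum(ns[keep] * N[keep]) / (f * g)
}

# Count maximal runs of consecutive integers in a sorted vector of distinct
# positions; returns the run-length vector.
run_lengths_of_positions <- function(pos) {
  if (length(pos) == 0) return(integer(0))
  pos <- sort(pos)
  breaks <- c(TRUE, diff(pos) > 1L)
  as.integer(table(cumsum(breaks)))
}

#' Monte-Carlo expected maximal-run counts under random placement
#'
#' Draws `n_sets` sets of m distinct positions uniformly from 1..g (the
#' genome as one concatenated sequence), counts maximal runs of consecutive
#' positions of each size, and averages over sets.
#'
#' @param g total number of genes.
#' @param m number of regulated genes (m <= g).
#' @param n_sets number of random sets. Default 20.
#' @param seed RNG seed.
#' @param nmax largest run size tabulated. Default 10.
#' @return named numeric vector: mean count of maximal runs of exactly n,
#'   n = 2..nmax.
#' @export
simulate_random_runs <- function(g, m, n_sets = 20L, seed = 1L, nmax = 10L) {
  if (m > g) isc_stop("m must not exceed g", "isc_domain_error")
  counts <- matrix(0, nrow = n_sets, ncol = nmax - 1L,
                   dimnames = list(NULL, 2:nmax))
  with_seed(seed, {
    for (i in seq_len(n_sets)) {
      lens <- run_lengths_of_positions(sample.int(g, m))
      lens <- lens[lens >= 2]
      if (length(lens) > 0) {
        tab <- table(factor(pmin(lens, nmax), levels = 2:nmax))
        counts[i, ] <- as.numeric(tab)
      }
    }
  })
  colMeans(counts)
}

#' Exact expected maximal-run counts by exhaustive enumeration
#'
#' Enumerates all C(g, m) placements of m regulated genes among g positions
#' and averages the maximal-run count of each size. An oracle for small g.
#'
#' @param g total positions (enumeration capped at C(g, m) <= 1e6).
#' @param m regulated positions.
#' @return named numeric vector: exact expected count of maximal runs of
#'   exactly n, for n = 1..g.
#' @export
enumerate_exact_run_counts <- function(g, m) {
  if (m > g) isc_stop("m must not exceed g", "isc_domain_error")
  if (choose(g, m) > 1e6)
    isc_stop("C(g, m) too large to enumerate", "isc_capacity_error")
  totals <- stats::setNames(numeric(g), 1:g)
  if (m == 0) return(totals)
  combos <- utils::combn(g, m)
  for (j in seq_len(ncol(combos))) {
    lens <- run_lengths_of_positions(combos[, j])
    for (l in lens) totals[l] <- totals[l] + 1
  }
  totals / ncol(combos)
}

#' Chromosome-level enrichment of a regulated set
#'
#' For each chromosome, k = regulated genes on it, K = genes on it, against
#' n = regulated placed genes and G = all placed genes (UNPLACED genes are
#' excluded from both margins), with enrichment factor and two-tailed Fisher
#' p-value.
#'
#' @param gene_map validated gene map.
#' @param regulated character vector of regulated gene ids.
#' @return data.frame: chromosome, k, K, n, G, pct_regulated, enrichment,
#'   p_value.
#' @export
chromosome_enrichment <- function(gene_map, regulated) {
  placed <- gene_map[gene_map$chromosome != "UNPLACED", , drop = FALSE]
  G <- nrow(placed)
  reg_placed <- placed$gene_id %in% regulated
  n <- sum(reg_placed)
  chrs <- intersect(CHROMOSOME_LEVELS, unique(placed$chromosome))
  rows <- lapply(chrs, function(chr) {
    on_chr <- placed$chromosome == chr
    K <- sum(on_chr)
    if (K == 0) {
      warning("chromosome ", chr, " holds no genes; skipped")
      return(NULL)
    }
    k <- sum(on_chr & reg_placed)
    data.frame(chromosome = chr, k = k, K = K, n = n, G = G,
               pct_regulated = 100 * k / K,
               enrichment = enrichment_factor(k, K, n, G),
               p_value = fisher_two_tailed(k, K, n, G),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sliding-window density of flagged genes along each chromosome
#'
#' For every chromosome, the fraction of flagged genes in each window of
#' `window` consecutive genes (by gene order), advanced by `step` genes.
#' Windows never span chromosomes; chromosomes shorter than the window are
#' skipped with a warning.
#'
#' @param gene_map validated gene map.
#' @param flag_set character vector of flagged gene ids.
#' @param window window width in genes. Default 30.
#' @param step window advance in genes. Default 1.
#' @return data.frame: chromosome, window_start (order_index of the first
#'   gene in the window), fraction.
#' @export
sliding_window_density <- function(gene_map, flag_set, window = 30L, step = 1L) {
  placed <- gene_map[gene_map$chromosome != "UNPLACED", , drop = FALSE]
  rows <- list()
  for (chr in intersect(CHROMOSOME_LEVELS, unique(placed$chromosome))) {
    sub <- placed[placed$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$order_index), , drop = FALSE]
    nc <- nrow(sub)
    if (window > nc) {
      warning("chromosome ", chr, " has fewer genes (", nc,
              ") than the window (", window, "); skipped")
      next
    }
    flags <- as.numeric(sub$gene_id %in% flag_set)
    csum <- c(0, cumsum(flags))
    starts <- seq.int(1L, nc - window + 1L, by = step)
    frac <- (csum[starts + window] - csum[starts]) / window
    rows[[chr]] <- data.frame(chromosome = chr,
                              window_start = sub$order_index[starts],
                              fraction = frac, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed-versus-expected table for maximal run counts
#'
#' Convenience wrapper joining observed maximal-run counts with the analytic
#' null and a seeded Monte-Carlo estimate at the same f and g.
#'
#' @param run_set from [detect_runs()].
#' @param g total placed genes the null should use.
#' @param config `analysis_config` (nmax_runs, n_random_sets, rng_seed).
#' @return data.frame: n, observed, c_n, N_n_analytic, N_n_simulated.
#' @export
run_null_table <- function(run_set, g, config = analysis_config()) {
  m <- run_set$n_regulated_placed
  f <- m / g
  cn <- null_window_counts(f, g, config$nmax_runs)
  Nn <- corrected_run_counts(cn)
  sim <- simulate_random_runs(g, m, n_sets = config$n_random_sets,
                              seed = derive_seed(config$rng_seed, 202L),
                              nmax = config$nmax_runs)
  ns <- as.integer(names(cn))
  obs <- vapply(ns, function(n) {
    v <- run_set$counts_by_length[as.character(n)]
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  data.frame(n = ns, observed = obs, c_n = as.numeric(cn),
             N_n_analytic = as.numeric(Nn), N_n_simulated = as.numeric(sim))
}
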