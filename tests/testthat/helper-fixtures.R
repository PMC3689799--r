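# Fixture builders and independent oracles used across the test files.
# Everything is generated in code; no stored data.

# Tiny gene map: chromosomes named by `sizes`, ids g1, g2, ...
tiny_gene_map <- function(sizes) {
  n <- sum(sizes)
  data.frame(
    gene_id = paste0("g", seq_len(n)),
    chromosome = rep(names(sizes), sizes),
    order_index = unlist(lapply(sizes, function(k) seq_len(k) - 1L),
                         use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# Expression dataset built from per-gene per-cell means: `means` is a list
# gene_id -> named vector of cell means with names like "SI_0" or
# "CONTROL_2"; each cell gets `reps` identical replicates plus optional noise.
tiny_dataset <- function(means, reps = 2, noise = 0, floor = 0, seed = 1) {
  times <- c(0, 0.5, 1, 2, 3, 4)
  tl <- function(t) vapply(t, function(x) format(x, trim = TRUE), character(1))
  cols <- as.vector(outer(
    paste0(rep(c("SI", "CONTROL"), each = length(times)), "_",
           tl(rep(times, 2)), "h"),
    paste0("_r", seq_len(reps)), paste0))
  meta <- incompatscan::parse_sample_names(cols)
  m <- matrix(NA_real_, nrow = length(means), ncol = length(cols),
              dimnames = list(names(means), cols))
  for (gi in seq_along(means)) {
    for (j in seq_along(cols)) {
      key <- paste0(meta$strain[j], "_", tl(meta$time_h[j]))
      m[gi, j] <- means[[gi]][[key]]
    }
  }
  if (noise > 0) {
    set.seed(seed)
    m <- m + matrix(rnorm(length(m), 0, noise), nrow = nrow(m))
  }
  expression_dataset(m, detection_floor = floor)
}

# Cell-mean template: flat at `base` everywhere.
flat_cells <- function(base = 10) {
  times <- c(0, 0.5, 1, 2, 3, 4)
  tl <- vapply(rep(times, 2), function(x) format(x, trim = TRUE), character(1))
  setNames(rep(base, 2 * length(times)),
           paste0(rep(c("SI", "CONTROL"), each = length(times)), "_", tl))
}

# Brute-force average-linkage (UPGMA) oracle: returns merge heights in order
# and the list of partitions (each a list of sorted member index vectors)
# after each merge. Average distance between clusters is the mean of all
# between-pair distances in the ORIGINAL matrix, the UPGMA definition.
brute_upgma <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition for comparison: sorted list of sorted vectors.
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, function(x) x[1], numeric(1)))]
}

# Partition (list of member vectors) from a label vector.
labels_to_partition <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}

# Exhaustive two-sided Fisher oracle from explicit binomial coefficients:
# enumerate every table with the observed margins, compute its probability by
# combinatorial counting, and sum those no more probable than the observed.
fisher_oracle <- function(k, K, n, G) {
  xs <- max(0, n - (G - K)):min(K, n)
  probs <- choose(K, xs) * choose(G - K, n - xs) / choose(G, n)
  p_obs <- probs[xs == k]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Small synthetic spec for fast end-to-end tests: ~1500 genes, 3 chromosomes.
small_spec <- function(seed = 1, ...) {
  synthetic_spec(
    g = 1500L,
    chromosome_sizes = c(I = 600L, II = 500L, III = 350L),
    islands = data.frame(chromosome = c("I", "II"), start = c(50L, 100L),
                         length = c(8L, 7L), direction = "up",
                         stringsAsFactors = FALSE),
    isp_count = 10L, silenced_count = 2L,
    category_specs = data.frame(label = c("catA", "catB"), K = c(60L, 40L),
                                rr = c(3, 1), stringsAsFactors = FALSE),
    seed = seed, ...
  )
}
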