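# Synthetic-data generator: genomes, annotations, and time-course expression
# with known ground truth. The defaults emulate the structure of the
# incompatibility experiment: 10,556 genes on seven chromosomes (plus a small
# unplaced remainder), ~21% up- and ~23% down-regulated genes, planted
# islands of adjacent coregulated genes, eight archetype induction profiles,
# Gaussian log2 noise over four replicates, a detection floor with
# incompatibility-specific (off at T0, on during the reaction) and silenced
# genes, and annotation categories with controlled enrichment.

# Eight archetype time-course shapes over (0.5, 1, 2, 3, 4) h, unit peak:
# early-transient (H), early-sustained (B), lagged-plateau (C), late-rise (D),
# peaked-then-return variants (F, G) and peaked-then-decline variants (E, A).
# The shapes are chosen so that no pair exceeds Pearson correlation 0.88 —
# with five time points this is what makes the consensus clustering able to
# tell the planted classes apart at realistic noise.
ARCHETYPE_SHAPES <- rbind(
  A = c(0.08, 0.45, 1.00, 0.90, 0.60),  # peak at 2-3 h, slow decline
  B = c(0.85, 1.00, 1.00, 1.00, 0.95),  # immediate sustained
  C = c(0.15, 0.50, 0.90, 1.00, 1.00),  # lagged plateau (by 2-3 h)
  D = c(0.05, 0.12, 0.30, 0.60, 1.00),  # late rise
  E = c(0.60, 1.00, 0.85, 0.70, 0.55),  # peak at 1 h, slow decline
  F = c(0.50, 1.00, 0.45, 0.20, 0.10),  # peak at 1 h, return to baseline
  G = c(0.15, 0.55, 1.00, 0.50, 0.20),  # peak at 2 h, return toward baseline
  H = c(1.00, 0.50, 0.20, 0.10, 0.05)   # early transient (30 min spike)
)
colnames(ARCHETYPE_SHAPES) <- paste0(c(0.5, 1, 2, 3, 4), "h")

#' Synthetic-dataset specification
#'
#' @param g total gene count. Default 10556.
#' @param chromosome_sizes named vector of placed-gene counts for chromosomes
#'   I..VII; genes beyond their sum are UNPLACED. Defaults mirror the
#'   organism's seven chromosomes (sum 10394).
#' @param f_up,f_down target regulated fractions of g. Defaults 0.21 / 0.23.
#' @param islands data.frame with columns chromosome, start, length,
#'   direction ("up"/"down"): planted runs of adjacent coregulated genes.
#' @param amplitude_range log2 fold-change amplitude range for planted
#'   regulated genes. Default c(1.5, 5.5) — all planted effects clear the
#'   |FC| >= 2 call threshold, with a tail of strong inductions.
#' @param noise_sd replicate noise standard deviation on the log2 scale.
#'   Default 0.25.
#' @param replicates biological replicates per (strain, time). Default 4.
#' @param isp_count genes expressed only during the reaction. Default 116.
#' @param silenced_count genes switched off during the reaction. Default 3.
#' @param category_specs data.frame with columns label, K (category size),
#'   rr (relative risk of category membership for up-regulated genes).
#' @param ortholog_fraction fraction of genes with a one-to-one ortholog in
#'   the comparison species. Default 0.65.
#' @param secreted_fraction fraction of genes encoding predicted extracellular
#'   proteins. Default 0.075.
#' @param detection_floor log2 intensity below which a measurement is
#'   undetected. Default 5.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#'   Defaults 10 and 1.5.
#' @param seed master RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(g = 10556L,
                           chromosome_sizes = c(I = 2557L, II = 1569L, III = 1208L,
                                                IV = 1119L, V = 1447L, VI = 1277L,
                                                VII = 1217L),
                           f_up = 0.21, f_down = 0.23,
                           islands = data.frame(
                             chromosome = c("IV", "V", "V", "II"),
                             start = c(100L, 300L, 900L, 200L),
                             length = c(10L, 8L, 7L, 7L),
                             direction = "up",
                             stringsAsFactors = FALSE),
                           amplitude_range = c(1.5, 5.5),
                           noise_sd = 0.25,
                           replicates = 4L,
                           isp_count = 116L,
                           silenced_count = 3L,
                           category_specs = data.frame(
                             label = c("HET_like", "proteolysis", "neutral"),
                             K = c(130L, 250L, 300L),
                             rr = c(4, 2, 1),
                             stringsAsFactors = FALSE),
                           ortholog_fraction = 0.65,
                           secreted_fraction = 0.075,
                           detection_floor = 5,
                           baseline_mean = 10,
                           baseline_sd = 1.5,
                           seed = 1L) {
  if (sum(chromosome_sizes) > g)
    isc_stop("chromosome sizes exceed total gene count", "isc_spec_error")
  if (f_up < 0 || f_down < 0 || f_up + f_down > 1)
    isc_stop("regulated fractions must be nonnegative with sum <= 1", "isc_spec_error")
  if (nrow(islands) > 0) {
    if (!all(islands$chromosome %in% names(chromosome_sizes)))
      isc_stop("island on unknown chromosome", "isc_spec_error")
    if (any(islands$start + islands$length > chromosome_sizes[islands$chromosome]))
      isc_stop("island exceeds chromosome bounds", "isc_spec_error")
    up_budget <- round(f_up * g); down_budget <- round(f_down * g)
    if (sum(islands$length[islands$direction == "up"]) > up_budget ||
        sum(islands$length[islands$direction == "down"]) > down_budget)
      isc_stop("island lengths exceed the regulated-gene budget", "isc_spec_error")
  }
  structure(list(
    g = as.integer(g), chromosome_sizes = chromosome_sizes,
    f_up = f_up, f_down = f_down, islands = islands,
    amplitude_range = amplitude_range, noise_sd = noise_sd,
    replicates = as.integer(replicates),
    isp_count = as.integer(isp_count), silenced_count = as.integer(silenced_count),
    category_specs = category_specs, ortholog_fraction = ortholog_fraction,
    secreted_fraction = secreted_fraction, detection_floor = detection_floor,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate the ground truth: gene map and regulation truth table
#'
#' Assigns genes to chromosomes in order, plants the island runs, samples the
#' remaining regulated genes uniformly, assigns archetypes and amplitudes,
#' marks isp/silenced genes, draws annotation categories at the specified
#' relative risks (weighted sampling without replacement), and pairs a
#' fraction of genes with orthologs. Fully determined by `spec$seed`.
#'
#' @param spec `synthetic_spec`.
#' @return list with `gene_map` (validated gene map data.frame) and `truth`
#'   (data.frame: gene_id, direction, archetype, amplitude_log2, island_id,
#'   isp, silenced).
#' @export
generate_truth <- function(spec) {
  g <- spec$g
  sizes <- spec$chromosome_sizes
  n_unplaced <- g - sum(sizes)
  gene_id <- sprintf("g%05d", seq_len(g))
  chromosome <- c(rep(names(sizes), sizes), rep("UNPLACED", n_unplaced))
  order_index <- unlist(lapply(c(sizes, UNPLACED = n_unplaced),
                               function(n) seq_len(n) - 1L), use.names = FALSE)
  gm <- data.frame(gene_id = gene_id, chromosome = chromosome,
                   order_index = order_index, stringsAsFactors = FALSE)

  direction <- rep("none", g)
  island_id <- rep(NA_integer_, g)
  # row index of (chromosome, order_index)
  row_of <- function(chr, idx) which(gm$chromosome == chr)[idx + 1L]
  if (nrow(spec$islands) > 0) {
    for (i in seq_len(nrow(spec$islands))) {
      isl <- spec$islands[i, ]
      rows <- row_of(isl$chromosome, seq.int(isl$start, length.out = isl$length))
      if (any(direction[rows] != "none"))
        isc_stop("islands overlap", "isc_spec_error")
      direction[rows] <- isl$direction
      island_id[rows] <- i
    }
  }
  with_seed(derive_seed(spec$seed, 11L), {
    n_up <- round(spec$f_up * g); n_down <- round(spec$f_down * g)
    need_up <- n_up - sum(direction == "up")
    need_down <- n_down - sum(direction == "down")
    free <- which(direction == "none")
    pick <- sample(free, need_up + need_down)
    direction[pick[seq_len(need_up)]] <- "up"
    if (need_down > 0) direction[pick[need_up + seq_len(need_down)]] <- "down"

    regulated <- direction != "none"
    archetype <- rep(NA_character_, g)
    amplitude <- rep(NA_real_, g)
    archetype[regulated] <- sample(rownames(ARCHETYPE_SHAPES), sum(regulated),
                                   replace = TRUE)
    amplitude[regulated] <- stats::runif(sum(regulated),
                                         spec$amplitude_range[1],
                                         spec$amplitude_range[2])
    amplitude[direction == "down"] <- -amplitude[direction == "down"]

    isp <- rep(FALSE, g)
    up_idx <- which(direction == "up")
    if (spec$isp_count > 0)
      isp[sample(up_idx, min(spec$isp_count, length(up_idx)))] <- TRUE
    silenced <- rep(FALSE, g)
    down_idx <- which(direction == "down")
    if (spec$silenced_count > 0)
      silenced[sample(down_idx, min(spec$silenced_count, length(down_idx)))] <- TRUE

    categories <- replicate(g, character(0), simplify = FALSE)
    if (nrow(spec$category_specs) > 0) {
      # stratified allocation hits the target relative risk by construction:
      # membership probability is rr-fold higher for up-regulated genes
      for (i in seq_len(nrow(spec$category_specs))) {
        cs <- spec$category_specs[i, ]
        n_up_pool <- sum(direction == "up")
        n_rest <- g - n_up_pool
        k_up <- round(cs$K * cs$rr * n_up_pool / (cs$rr * n_up_pool + n_rest))
        members <- c(sample(which(direction == "up"), k_up),
                     sample(which(direction != "up"), cs$K - k_up))
        for (m in members) categories[[m]] <- c(categories[[m]], cs$label)
      }
    }

    secreted <- stats::runif(g) < spec$secreted_fraction
    length_aa <- pmax(50L, round(stats::rlnorm(g, log(420), 0.6)))
    cys_count <- stats::rbinom(g, size = length_aa, prob = 0.018)

    ortholog <- rep(NA_character_, g)
    has_orth <- sample.int(g, round(spec$ortholog_fraction * g))
    ortholog[has_orth] <- sprintf("nc%05d", seq_along(has_orth))
  })

  gm$length_aa <- length_aa
  gm$cys_count <- cys_count
  gm$secreted <- secreted
  gm$categories <- categories
  gm$ortholog <- ortholog
  validate_gene_map(gm)
  truth <- data.frame(gene_id = gene_id, direction = direction,
                      archetype = archetype, amplitude_log2 = amplitude,
                      island_id = island_id, isp = isp, silenced = silenced,
                      stringsAsFactors = FALSE)
  list(gene_map = gm, truth = truth)
}

#' Generate a time-course expression dataset from a truth table
#'
#' Baseline log2 intensities are Normal(baseline_mean, baseline_sd), clamped
#' above the detection floor. In the SI strain a regulated gene follows its
#' archetype's log2 fold-change trajectory (amplitude times the unit shape)
#' on top of its baseline, plus Normal(0, noise_sd) per replicate. The
#' control strain stays flat at baseline plus noise. Incompatibility-specific
#' (isp) genes sit below the detection floor at SI T0 and in the control and
#' ramp from the floor toward their baseline along their archetype; silenced
#' genes are at baseline at T0 and drop below the floor from 2 h on.
#' Deterministic given `spec$seed`.
#'
#' @param gene_map,truth from [generate_truth()].
#' @param spec `synthetic_spec`.
#' @return `expression_dataset`.
#' @export
generate_expression <- function(gene_map, truth, spec) {
  g <- nrow(gene_map)
  times <- TIME_POINTS_H
  R <- spec$replicates
  floor_val <- spec$detection_floor
  off_level <- floor_val - 2

  cols <- as.vector(outer(
    paste0(rep(c("SI", "CONTROL"), each = length(times)), "_",
           time_label(rep(times, 2)), "h"),
    paste0("_r", seq_len(R)), paste0))
  meta <- parse_sample_names(cols)

  shapes <- matrix(0, nrow = g, ncol = length(times))  # unit shape incl. t=0
  reg <- truth$direction != "none"
  shapes[reg, -1] <- ARCHETYPE_SHAPES[truth$archetype[reg], , drop = FALSE]
  amp <- ifelse(is.na(truth$amplitude_log2), 0, truth$amplitude_log2)

  with_seed(derive_seed(spec$seed, 23L), {
    baseline <- pmax(stats::rnorm(g, spec$baseline_mean, spec$baseline_sd),
                     floor_val + 1)
    # A down-regulated gene that is not planted as silenced must remain
    # detectable at the bottom of its trajectory, else detection-floor
    # crossings would masquerade as silencing.
    down_live <- truth$direction == "down" & !truth$silenced
    baseline[down_live] <- pmax(baseline[down_live],
                                floor_val + abs(amp[down_live]) + 1)
    values <- matrix(NA_real_, nrow = g, ncol = length(cols),
                     dimnames = list(gene_map$gene_id, cols))
    for (j in seq_along(cols)) {
      t_idx <- match(meta$time_h[j], times)
      mu <- if (meta$strain[j] == "SI") baseline + amp * shapes[, t_idx]
            else baseline
      if (meta$strain[j] == "SI") {
        # isp genes: off at T0, ramp from the off level toward baseline
        mu[truth$isp] <- if (times[t_idx] == 0) off_level
          else off_level + (baseline[truth$isp] - off_level) * shapes[truth$isp, t_idx]
        # silenced genes: baseline until 1 h, off from 2 h on
        sil <- truth$silenced
        if (times[t_idx] >= 2) mu[sil] <- off_level
        else mu[sil] <- baseline[sil]
      } else {
        mu[truth$isp] <- off_level
      }
      v <- mu + stats::rnorm(g, 0, spec$noise_sd)
      # keep planted "off" measurements strictly below the floor
      off <- mu <= off_level
      v[off] <- pmin(v[off], floor_val - 0.5)
      values[, j] <- v
    }
  })
  expression_dataset(values, detection_floor = floor_val)
}

#' Generate and write a complete synthetic dataset
#'
#' Writes `gene_map.tsv`, `expression.tsv`, `truth.tsv`, and
#' `ortholog_pairs.tsv` under `dir`.
#'
#' @param spec `synthetic_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, the list from [generate_truth()] plus the dataset.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- generate_truth(spec)
  ds <- generate_expression(tr$gene_map, tr$truth, spec)
  write_gene_map(tr$gene_map, file.path(dir, "gene_map.tsv"))
  write_expression(ds, file.path(dir, "expression.tsv"))
  utils::write.table(tr$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  has_orth <- !is.na(tr$gene_map$ortholog)
  utils::write.table(
    data.frame(gene_a = tr$gene_map$gene_id[has_orth],
               gene_b = tr$gene_map$ortholog[has_orth]),
    file.path(dir, "ortholog_pairs.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(c(tr, list(dataset = ds)))
}
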