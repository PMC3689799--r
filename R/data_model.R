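# Domain types and tabular I/O shared by all pipeline stages.
#
# A gene map is a data.frame with one row per gene: gene_id, chromosome
# (I..VII or UNPLACED), order_index (0-based rank along the chromosome's gene
# order), and optional annotation columns (length_aa, cys_count, secreted,
# categories, ortholog). Genomic analyses are purely gene-order based;
# base-pair coordinates are not modeled.
#
# An expression dataset holds the normalized log2 intensity matrix over
# (strain, time, replicate) samples together with a per-measurement detection
# flag, the structure left after two-color array normalization has absorbed
# the common-reference channel.

#' Validate a gene map
#'
#' Checks the invariants every downstream stage relies on: unique gene ids,
#' known chromosome labels, and order indices that are unique and contiguous
#' (0..n-1) within each placed chromosome.
#'
#' @param gene_map data.frame with columns `gene_id`, `chromosome`,
#'   `order_index` (and any annotation columns).
#' @return the validated gene map, invisibly unchanged.
#' @export
validate_gene_map <- function(gene_map) {
  required <- c("gene_id", "chromosome", "order_index")
  missing <- setdiff(required, names(gene_map))
  if (length(missing) > 0)
    isc_stop(paste0("gene map missing mandatory column(s): ",
                    paste(missing, collapse = ", ")), "isc_format_error")
  dup <- gene_map$gene_id[duplicated(gene_map$gene_id)]
  if (length(dup) > 0)
    isc_stop(paste0("duplicate gene_id(s): ", paste(unique(dup), collapse = ", ")),
             "isc_validation_error")
  bad_chr <- setdiff(unique(gene_map$chromosome), CHROMOSOME_LEVELS)
  if (length(bad_chr) > 0)
    isc_stop(paste0("unknown chromosome label(s): ", paste(bad_chr, collapse = ", ")),
             "isc_validation_error")
  for (chr in setdiff(unique(gene_map$chromosome), "UNPLACED")) {
    idx <- sort(gene_map$order_index[gene_map$chromosome == chr])
    if (anyDuplicated(idx))
      isc_stop(paste0("duplicate order_index on chromosome ", chr),
               "isc_validation_error")
    expected <- seq.int(0L, length(idx) - 1L)
    if (!identical(as.integer(idx), expected)) {
      gap <- setdiff(expected, idx)
      isc_stop(paste0("order_index not contiguous on chromosome ", chr,
                      "; missing index(es): ",
                      paste(utils::head(gap, 5), collapse = ", ")),
               "isc_validation_error")
    }
  }
  if (!is.null(gene_map$length_aa) && !is.null(gene_map$cys_count)) {
    both <- !is.na(gene_map$length_aa) & !is.na(gene_map$cys_count)
    if (any(gene_map$cys_count[both] > gene_map$length_aa[both]))
      isc_stop("cys_count exceeds length_aa for some gene(s)", "isc_validation_error")
  }
  invisible(gene_map)
}

#' Read a gene map from a tab-separated file
#'
#' Expected columns: `gene_id  chromosome  order_index` plus optional
#' `length_aa  cys_count  secreted  categories  ortholog`. The `categories`
#' column holds comma-joined labels; empty means no category.
#'
#' @param path file path.
#' @return validated gene map data.frame; `categories` is a list column of
#'   character vectors.
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_gene_map(gm)
  if (!is.null(gm$secreted)) gm$secreted <- as.logical(gm$secreted)
  if (!is.null(gm$categories)) {
    gm$categories <- lapply(strsplit(as.character(gm$categories), ","),
                            function(x) x[nzchar(x)])
  } else {
    gm$categories <- replicate(nrow(gm), character(0), simplify = FALSE)
  }
  gm
}

#' Write a gene map to a tab-separated file
#' @param gene_map validated gene map.
#' @param path destination path.
#' @export
write_gene_map <- function(gene_map, path) {
  out <- gene_map
  if (!is.null(out$categories) && is.list(out$categories))
    out$categories <- vapply(out$categories, paste, collapse = ",",
                             FUN.VALUE = character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an expression dataset
#'
#' @param values numeric matrix of normalized log2 intensities, genes in rows.
#'   Row names are gene ids; column names follow `<strain>_<time>h_r<rep>`,
#'   e.g. `SI_0.5h_r1`.
#' @param samples optional data.frame with columns `strain`, `time_h`,
#'   `replicate`; parsed from column names when omitted.
#' @param detection_floor log2 intensity; a measurement counts as detected iff
#'   strictly above it. Default: 5th percentile of control-strain values.
#' @param detected optional logical matrix overriding the floor rule.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, samples = NULL, detection_floor = NULL,
                               detected = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    isc_stop("values must be a numeric matrix", "isc_format_error")
  if (is.null(rownames(values)))
    isc_stop("values must carry gene ids as row names", "isc_format_error")
  if (is.null(samples)) samples <- parse_sample_names(colnames(values))
  if (nrow(samples) != ncol(values))
    isc_stop("samples must describe every column of values", "isc_validation_error")
  tab <- table(samples$strain, samples$time_h)
  if (any(tab > 0 & tab < 2))
    isc_stop("every (strain, time) cell needs >= 2 replicates", "isc_validation_error")
  if (is.null(detection_floor)) {
    ctrl <- values[, samples$strain == "CONTROL", drop = FALSE]
    detection_floor <- if (length(ctrl) > 0) stats::quantile(ctrl, 0.05, names = FALSE)
                       else stats::quantile(values, 0.05, names = FALSE)
  }
  if (is.null(detected)) detected <- values > detection_floor
  if (any(!is.finite(values[detected])))
    isc_stop("non-finite value flagged as detected", "isc_validation_error")
  structure(list(
    genes = rownames(values),
    samples = samples,
    values = values,
    detected = detected,
    detection_floor = detection_floor
  ), class = "expression_dataset")
}

#' Parse sample column names
#'
#' Convention: `<strain>_<time>h_r<replicate>` with time in hours ("0.5" for
#' 30 minutes), e.g. `SI_2h_r1`, `CONTROL_0.5h_r3`.
#'
#' @param x character vector of column names.
#' @return data.frame with columns `sample_id`, `strain`, `time_h`, `replicate`.
#' @export
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^(SI|CONTROL)_([0-9]*\\.?[0-9]+)h_r([0-9]+)$", x))
  bad <- x[vapply(m, length, 1L) != 4L]
  if (length(bad) > 0)
    isc_stop(paste0("unparseable sample column(s): ", paste(bad, collapse = ", "),
                    " (expected <strain>_<time>h_r<rep>, strain in {SI, CONTROL})"),
             "isc_format_error")
  data.frame(
    sample_id = x,
    strain = vapply(m, `[`, character(1), 2),
    time_h = as.numeric(vapply(m, `[`, character(1), 3)),
    replicate = as.integer(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

#' Read an expression matrix from a tab-separated file
#'
#' First column is `gene_id`; remaining columns are named per
#' [parse_sample_names()] and hold normalized log2 intensities.
#'
#' @param path file path.
#' @param detection_floor see [expression_dataset()].
#' @return `expression_dataset`.
#' @export
read_expression <- function(path, detection_floor = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    isc_stop("first column of an expression table must be gene_id", "isc_format_error")
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      isc_stop(paste0("non-numeric value at row ", bad_row, ", column '",
                      names(vals)[j], "'"), "isc_format_error")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- df$gene_id
  expression_dataset(m, detection_floor = detection_floor)
}

#' Write an expression dataset to a tab-separated file
#' @param dataset `expression_dataset`.
#' @param path destination path.
#' @export
write_expression <- function(dataset, path) {
  df <- data.frame(gene_id = dataset$genes, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", length(x$genes), "genes x", nrow(x$samples),
      "samples\n")
  cat("  strains:", paste(unique(x$samples$strain), collapse = ", "),
      "| times (h):", paste(sort(unique(x$samples$time_h)), collapse = ", "),
      "| detection floor:", signif(x$detection_floor, 4), "\n")
  invisible(x)
}

#' Read one-to-one ortholog pairs
#'
#' Two-column tab-separated file (no header requirement beyond two columns):
#' gene id in species A, gene id in species B. Each gene may appear in at
#' most one pair.
#'
#' @param path file path.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  if (nrow(df) == 0) {
    warning("ortholog pair file is empty")
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  if (ncol(df) < 2)
    isc_stop("ortholog pair file must have two columns", "isc_format_error")
  pairs <- data.frame(gene_a = as.character(df[[1]]),
                      gene_b = as.character(df[[2]]),
                      stringsAsFactors = FALSE)
  validate_ortholog_pairs(pairs)
  pairs
}

#' @rdname read_ortholog_pairs
#' @param pairs data.frame with columns gene_a, gene_b.
#' @export
validate_ortholog_pairs <- function(pairs) {
  dup_a <- pairs$gene_a[duplicated(pairs$gene_a)]
  dup_b <- pairs$gene_b[duplicated(pairs$gene_b)]
  if (length(dup_a) + length(dup_b) > 0)
    isc_stop(paste0("ortholog pairs must be one-to-one; repeated gene(s): ",
                    paste(unique(c(dup_a, dup_b)), collapse = ", ")),
             "isc_validation_error")
  invisible(pairs)
}
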