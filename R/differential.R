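# Per-gene time-course statistics: signed fold changes, moderated t-tests
# with empirical-Bayes variance shrinkage, FDR adjustment, and regulation
# calls (up / down / isp / silenced / unchanged).
#
# The design compares each post-shift time point against T0 within each
# strain. Ratios are taken on the linear intensity scale (log2 values are
# exponentiated before averaging over replicates); the t-statistic operates
# on the log2 scale where array noise is approximately homoscedastic.

#' Signed fold change from a linear-scale ratio
#'
#' Maps a ratio R to R when R > 1 and to -1/R when R < 1, so that down
#' regulation reads as a negative factor of the same magnitude convention as
#' up regulation. R = 1 maps to 1.
#'
#' @param R positive ratio (vectorized).
#' @return signed fold change, |FC| >= 1.
#' @export
signed_fold_change <- function(R) {
  if (any(!is.finite(R) | R <= 0))
    isc_stop("ratio must be a positive finite number", "isc_domain_error")
  ifelse(R >= 1, R, -1 / R)
}

#' Moderated two-sample t-test
#'
#' Classical pooled-variance two-sample t on the group means, with the pooled
#' variance shrunk toward a prior: the posterior variance is
#' (prior_df * prior_var + resid_df * s^2) / (prior_df + resid_df) and the
#' reference distribution is t with prior_df + resid_df degrees of freedom.
#' With `prior_df = 0` this is exactly the ordinary pooled t-test. The prior
#' is normally estimated across genes (see [estimate_variance_prior()]); the
#' scalar form here takes it as an argument.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 finite values.
#' @param prior_df prior degrees of freedom (>= 0). Default 0.
#' @param prior_var prior variance; required when prior_df > 0.
#' @return list with `t`, `p_value`, `df`, `posterior_var`.
#' @export
moderated_t <- function(group_a, group_b, prior_df = 0, prior_var = NA_real_) {
  if (length(group_a) < 2 || length(group_b) < 2)
    isc_stop("each group needs >= 2 values", "isc_insufficient_replicates")
  if (prior_df < 0) isc_stop("prior_df must be >= 0", "isc_domain_error")
  if (prior_df > 0 && !is.finite(prior_var))
    isc_stop("prior_var required when prior_df > 0", "isc_domain_error")
  na <- length(group_a); nb <- length(group_b)
  d <- na + nb - 2L
  s2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) / d
  if (is.finite(prior_df) && prior_df > 0) {
    post_var <- (prior_df * prior_var + d * s2) / (prior_df + d)
    df <- prior_df + d
  } else if (is.infinite(prior_df)) {
    post_var <- prior_var
    df <- Inf
  } else {
    post_var <- s2
    df <- d
  }
  se <- sqrt(post_var * (1 / na + 1 / nb))
  delta <- mean(group_a) - mean(group_b)
  tval <- if (se == 0) { if (delta == 0) 0 else sign(delta) * Inf } else delta / se
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(t = tval, p_value = p, df = df, posterior_var = post_var)
}

#' Estimate the variance prior across genes by moment matching
#'
#' Under the standard hierarchical model the per-gene sample variances follow
#' a scaled F distribution: s^2 ~ s0^2 F(d, d0). Matching the first two
#' moments of the observed s^2 gives
#'   CV^2 = 2 (d + d0 - 2) / (d (d0 - 4)),
#' solved for d0, and s0^2 = mean(s^2) (d0 - 2) / d0. When the observed
#' spread is no wider than sampling noise allows, d0 is effectively infinite
#' and the prior collapses onto the mean variance.
#'
#' @param s2 vector of per-gene pooled variances.
#' @param df residual degrees of freedom each s2 was computed with.
#' @return list with `prior_df`, `prior_var`.
#' @export
estimate_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 10)
    return(list(prior_df = 0, prior_var = NA_real_))
  m1 <- mean(s2)
  cv2 <- stats::var(s2) / m1^2
  denom <- cv2 * df - 2
  if (denom <= 0) return(list(prior_df = Inf, prior_var = m1))
  d0 <- (4 * cv2 * df + 2 * (df - 2)) / denom
  if (!is.finite(d0) || d0 > 1e6) return(list(prior_df = Inf, prior_var = m1))
  d0 <- max(d0, 0.05)
  s0 <- if (d0 > 2) m1 * (d0 - 2) / d0 else m1
  list(prior_df = d0, prior_var = s0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: order the p-values, multiply by
#' m/rank, then enforce monotonicity from the largest rank down and cap at 1.
#' Output order matches input order. NAs propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
adjust_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    isc_stop("p-values must lie in [0, 1]", "isc_domain_error")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv, decreasing = TRUE)
    adj <- pmin(1, cummin(m / (m:1) * pv[o]))
    out[ok][o] <- adj
  }
  out
}

# Per-(strain,time)-cell replicate summaries: means/vars of log2 values and
# of linear-scale intensities, plus detection counts. Internal.
cell_summaries <- function(dataset) {
  s <- dataset$samples
  cells <- unique(s[, c("strain", "time_h")])
  cells <- cells[order(cells$strain, cells$time_h), ]
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cols <- which(s$strain == cells$strain[i] & s$time_h == cells$time_h[i])
    v <- dataset$values[, cols, drop = FALSE]
    lin <- 2^v
    res[[i]] <- list(
      strain = cells$strain[i], time_h = cells$time_h[i], n = length(cols),
      mean_log = rowMeans(v),
      var_log = apply(v, 1, stats::var),
      mean_lin = rowMeans(lin),
      det_frac = rowMeans(dataset$detected[, cols, drop = FALSE]),
      det_all = rowSums(dataset$detected[, cols, drop = FALSE]) == length(cols),
      det_none = rowSums(dataset$detected[, cols, drop = FALSE]) == 0
    )
  }
  res
}

#' Call differential expression for every gene in a time-course dataset
#'
#' For each strain independently and each time point t > 0, computes the
#' linear-scale ratio of mean intensity at t over mean intensity at T0, the
#' signed fold change, a moderated-t p-value on the log2 replicates (variance
#' prior estimated across all genes of that comparison), and a BH-adjusted
#' q-value (family = all genes at that strain/time). A gene is then
#' classified as UP, DOWN, ISP (expression detected only after induction),
#' SILENCED (detected at T0, undetected at all later times from some point
#' on), or UNCHANGED; differential expression in the control strain vetoes
#' an UP/DOWN/ISP call.
#'
#' @param dataset `expression_dataset` with strains SI and CONTROL, both with
#'   a time 0 cell.
#' @param config `analysis_config`.
#' @return data.frame of class `differential_result`: one row per gene with
#'   per-time `ratio_*`, `fc_*`, `p_*`, `q_*` columns for the SI strain,
#'   `ctrl_fc_*`/`ctrl_q_*` for the control, `max_abs_fc`, `status`,
#'   `control_differential`.
#' @export
call_genes <- function(dataset, config = analysis_config()) {
  s <- dataset$samples
  for (strain in c("SI", "CONTROL"))
    if (sum(s$strain == strain & s$time_h == 0) < 2)
      isc_stop(paste0("missing or single-replicate T0 cell for strain ", strain),
               "isc_insufficient_data")
  cs <- cell_summaries(dataset)
  key <- function(strain, t) Filter(function(x) x$strain == strain && x$time_h == t, cs)[[1]]
  times <- sort(setdiff(unique(s$time_h), 0))
  ng <- length(dataset$genes)

  per_strain <- function(strain) {
    t0 <- key(strain, 0)
    out <- list()
    for (t in times) {
      ct <- key(strain, t)
      ratio <- ct$mean_lin / t0$mean_lin
      fc <- signed_fold_change(ratio)
      d <- ct$n + t0$n - 2L
      s2 <- ((ct$n - 1) * ct$var_log + (t0$n - 1) * t0$var_log) / d
      prior <- estimate_variance_prior(s2, d)
      if (is.infinite(prior$prior_df)) {
        post <- rep(prior$prior_var, ng); df <- Inf
      } else if (prior$prior_df > 0) {
        post <- (prior$prior_df * prior$prior_var + d * s2) / (prior$prior_df + d)
        df <- prior$prior_df + d
      } else {
        post <- s2; df <- d
      }
      se <- sqrt(post * (1 / ct$n + 1 / t0$n))
      tstat <- (ct$mean_log - t0$mean_log) / se
      tstat[se == 0] <- 0
      p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
      q <- adjust_bh(p)
      out[[as.character(t)]] <- list(ratio = ratio, fc = fc, p = p, q = q)
    }
    out
  }

  si <- per_strain("SI")
  ctrl <- per_strain("CONTROL")

  sig_at <- function(res, t) {
    abs(res[[as.character(t)]]$fc) >= config$fc_threshold &
      res[[as.character(t)]]$q < config$adj_p_threshold
  }
  control_diff <- Reduce(`|`, lapply(times, function(t) sig_at(ctrl, t)))

  fcs <- sapply(times, function(t) si[[as.character(t)]]$fc)
  max_abs_fc <- apply(abs(fcs), 1, max)
  si_sig <- sapply(times, function(t) sig_at(si, t))

  # detection patterns in the SI strain
  si_t0 <- key("SI", 0)
  det_frac <- sapply(times, function(t) key("SI", t)$det_frac)
  det_none <- sapply(times, function(t) key("SI", t)$det_none)

  status <- character(ng)
  for (i in seq_len(ng)) {
    up_sig <- any(si_sig[i, ] & fcs[i, ] > 0)
    down_sig <- any(si_sig[i, ] & fcs[i, ] < 0)
    isp <- si_t0$det_none[i] && any(det_frac[i, ] >= 0.5) && !control_diff[i]
    sil_from <- which(vapply(seq_along(times), function(j) all(det_none[i, j:length(times)]),
                             logical(1)))
    silenced <- si_t0$det_frac[i] >= 0.5 && length(sil_from) > 0
    status[i] <-
      if (isp) "ISP"
      else if (silenced) "SILENCED"
      else if (control_diff[i]) "UNCHANGED"
      else if (up_sig && (!down_sig || max(fcs[i, ][si_sig[i, ]]) >= -min(fcs[i, ][si_sig[i, ]]))) "UP"
      else if (down_sig) "DOWN"
      else "UNCHANGED"
  }

  res <- data.frame(gene_id = dataset$genes, stringsAsFactors = FALSE)
  tl <- function(t) format(t, trim = TRUE)
  for (j in seq_along(times)) {
    t <- times[j]
    res[[paste0("ratio_", tl(t), "h")]] <- si[[as.character(t)]]$ratio
    res[[paste0("fc_", tl(t), "h")]] <- si[[as.character(t)]]$fc
    res[[paste0("p_", tl(t), "h")]] <- si[[as.character(t)]]$p
    res[[paste0("q_", tl(t), "h")]] <- si[[as.character(t)]]$q
  }
  for (j in seq_along(times)) {
    t <- times[j]
    res[[paste0("ctrl_fc_", tl(t), "h")]] <- ctrl[[as.character(t)]]$fc
    res[[paste0("ctrl_q_", tl(t), "h")]] <- ctrl[[as.character(t)]]$q
  }
  res$max_abs_fc <- max_abs_fc
  res$status <- status
  res$control_differential <- control_diff
  attr(res, "times") <- times
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Summarize induction/repression kinetics and fold-change magnitudes
#'
#' @param results `differential_result` from [call_genes()].
#' @param config `analysis_config`.
#' @param cumulative if TRUE, a gene counts at time t when it meets the
#'   criterion at t or any earlier time (membership kinetics); if FALSE
#'   (default) counts are per time point.
#' @return list with `per_time` (data.frame time_h, n_up, n_down),
#'   `fc_histogram` (direction x bin counts over \[2,5), \[5,10), \[10,50),
#'   \[50,Inf)), and `status_counts`.
#' @export
summarize_kinetics <- function(results, config = analysis_config(),
                               cumulative = FALSE) {
  times <- attr(results, "times")
  tl <- function(t) format(t, trim = TRUE)
  up_mat <- sapply(times, function(t) {
    fc <- results[[paste0("fc_", tl(t), "h")]]
    q <- results[[paste0("q_", tl(t), "h")]]
    fc >= config$fc_threshold & q < config$adj_p_threshold & !results$control_differential
  })
  down_mat <- sapply(times, function(t) {
    fc <- results[[paste0("fc_", tl(t), "h")]]
    q <- results[[paste0("q_", tl(t), "h")]]
    fc <= -config$fc_threshold & q < config$adj_p_threshold & !results$control_differential
  })
  if (cumulative) {
    up_mat <- t(apply(up_mat, 1, cummax)) > 0
    down_mat <- t(apply(down_mat, 1, cummax)) > 0
  }
  per_time <- data.frame(time_h = times,
                         n_up = colSums(up_mat),
                         n_down = colSums(down_mat))
  bins <- c(2, 5, 10, 50, Inf)
  bin_labels <- c("[2,5)", "[5,10)", "[10,50)", "[50,Inf)")
  hist_for <- function(st) {
    v <- results$max_abs_fc[results$status == st]
    table(cut(v, breaks = bins, right = FALSE, labels = bin_labels))
  }
  fc_histogram <- rbind(UP = hist_for("UP"), DOWN = hist_for("DOWN"))
  list(per_time = per_time,
       fc_histogram = fc_histogram,
       status_counts = table(factor(results$status,
         levels = c("UP", "DOWN", "ISP", "SILENCED", "UNCHANGED"))))
}

#' Regulated gene sets from differential results
#'
#' ISP genes count as up-regulated (their expression appears only during the
#' reaction); SILENCED genes count as down-regulated.
#'
#' @param results `differential_result`.
#' @return list with character vectors `up` and `down`.
#' @export
regulated_sets <- function(results) {
  list(up = results$gene_id[results$status %in% c("UP", "ISP")],
       down = results$gene_id[results$status %in% c("DOWN", "SILENCED")])
}
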