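#' Analysis configuration
#'
#' Bundle of the thresholds and tuning parameters used across the pipeline.
#' Defaults reproduce the published analysis conventions for the
#' incompatibility time course: differential expression at |FC| >= 2 with
#' adjusted P < 0.001, clustering restricted to |FC| > 4, k-means with 12
#' classes, 30-gene sliding windows, run-length null model up to runs of 10,
#' and 20 Monte-Carlo sets for null validation.
#'
#' @param fc_threshold minimum absolute signed fold change for an up/down
#'   call (linear scale). Default 2.
#' @param adj_p_threshold maximum adjusted P-value (FDR) for an up/down call.
#'   Default 0.001.
#' @param cluster_fc_threshold minimum absolute fold change for inclusion in
#'   profile clustering. Must be >= `fc_threshold`. Default 4.
#' @param kmeans_k number of k-means classes. Default 12.
#' @param min_cluster_size minimum members for a robust cluster after the
#'   two-method intersection. Default 10.
#' @param window_size sliding-window width in genes. Default 30.
#' @param nmax_runs largest maximal-run size modeled by the null. Default 10.
#' @param n_random_sets Monte-Carlo replicate sets for null validation.
#'   Default 20.
#' @param rng_seed master seed; all stage seeds derive from it.
#' @param detection_floor log2 intensity at or below which a measurement is
#'   treated as undetected. `NULL` means: use the 5th percentile of
#'   control-strain intensities of the dataset at hand.
#' @param kmeans_restarts random restarts for k-means. Default 50.
#'
#' @return an object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(fc_threshold = 2,
                            adj_p_threshold = 0.001,
                            cluster_fc_threshold = 4,
                            kmeans_k = 12L,
                            min_cluster_size = 10L,
                            window_size = 30L,
                            nmax_runs = 10L,
                            n_random_sets = 20L,
                            rng_seed = 1L,
                            detection_floor = NULL,
                            kmeans_restarts = 50L) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 0)
    isc_stop("fc_threshold must be a positive number", "isc_param_error")
  if (!is.numeric(adj_p_threshold) || adj_p_threshold <= 0 || adj_p_threshold >= 1)
    isc_stop("adj_p_threshold must lie in (0, 1)", "isc_param_error")
  if (cluster_fc_threshold < fc_threshold)
    isc_stop("cluster_fc_threshold must be >= fc_threshold", "isc_param_error")
  if (kmeans_k < 1 || window_size < 1 || nmax_runs < 2 || n_random_sets < 1)
    isc_stop("kmeans_k, window_size, n_random_sets must be positive; nmax_runs >= 2",
             "isc_param_error")
  structure(list(
    fc_threshold = fc_threshold,
    adj_p_threshold = adj_p_threshold,
    cluster_fc_threshold = cluster_fc_threshold,
    kmeans_k = as.integer(kmeans_k),
    min_cluster_size = as.integer(min_cluster_size),
    window_size = as.integer(window_size),
    nmax_runs = as.integer(nmax_runs),
    n_random_sets = as.integer(n_random_sets),
    rng_seed = as.integer(rng_seed),
    detection_floor = detection_floor,
    kmeans_restarts = as.integer(kmeans_restarts)
  ), class = "analysis_config")
}
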