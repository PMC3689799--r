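test_that("signed fold change follows the ratio convention", {
  expect_equal(signed_fold_change(2.5), 2.5)
  expect_equal(signed_fold_change(0.25), -4.0)
  expect_equal(signed_fold_change(1), 1.0)
  expect_error(signed_fold_change(0), class = "isc_domain_error")
  expect_error(signed_fold_change(-2), class = "isc_domain_error")
  # odd map under R <-> 1/R
  for (R in c(0.1, 0.5, 1.7, 3, 42))
    expect_equal(signed_fold_change(1 / R), -signed_fold_change(R))
})

test_that("moderated t reduces to the classical pooled t at prior_df = 0", {
  # hand computation: (1,2,3) vs (4,5,6): pooled s2 = 1, se = sqrt(2/3),
  # t = -3/se = -3.6742, df = 4
  res <- moderated_t(c(1, 2, 3), c(4, 5, 6), prior_df = 0)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
  # and against R's own pooled t-test as an independent implementation
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("moderated t shrinks toward the prior as prior_df grows", {
  a <- c(1.2, 1.9, 3.1); b <- c(4.1, 5.2, 5.7)
  lim <- (mean(a) - mean(b)) / sqrt(0.5 * (1 / 3 + 1 / 3))
  res <- moderated_t(a, b, prior_df = 1e9, prior_var = 0.5)
  expect_equal(res$t, lim, tolerance = 1e-6)
  res_inf <- moderated_t(a, b, prior_df = Inf, prior_var = 0.5)
  expect_equal(res_inf$t, lim, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- moderated_t(c(1, 2), c(1, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(moderated_t(1, c(1, 2)), class = "isc_insufficient_replicates")
})

test_that("moderated t matches limma on simulated data", {
  skip_if_not_installed("limma")
  set.seed(42)
  ng <- 200
  m <- matrix(rnorm(ng * 8), ng, 8)
  m[1:20, 5:8] <- m[1:20, 5:8] + 2
  fit <- limma::lmFit(m, cbind(1, c(0, 0, 0, 0, 1, 1, 1, 1)))
  eb <- limma::eBayes(fit)
  # with limma's own prior, our posterior-variance formula reproduces its t
  for (i in c(1, 5, 100)) {
    res <- moderated_t(m[i, 5:8], m[i, 1:4],
                       prior_df = eb$df.prior, prior_var = eb$s2.prior)
    expect_equal(res$t, unname(eb$t[i, 2]), tolerance = 1e-8)
    expect_equal(res$p_value, unname(eb$p.value[i, 2]), tolerance = 1e-8)
  }
})

test_that("variance prior estimation recovers a planted prior", {
  set.seed(7)
  d0 <- 12; s0 <- 0.04; d <- 6
  s2 <- s0 * stats::rf(50000, d, d0)
  est <- estimate_variance_prior(s2, d)
  expect_equal(est$prior_df, d0, tolerance = 0.25)
  expect_equal(est$prior_var, s0, tolerance = 0.1)
  # (near-)constant variances: spread explainable by sampling alone, so the
  # prior collapses onto the mean
  esth <- estimate_variance_prior(rep(0.04, 1000), 6)
  expect_true(is.infinite(esth$prior_df))
  expect_equal(esth$prior_var, 0.04)
})

test_that("BH adjustment implements the step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(1.0), 1.0)
  expect_error(adjust_bh(c(0.5, 1.2)), class = "isc_domain_error")
  # order equivariance, idempotence, and agreement with stats::p.adjust
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- adjust_bh(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    perm <- sample(seq_along(p))
    expect_equal(adjust_bh(p[perm]), q[perm], tolerance = 1e-12)
  }
  # idempotent where the adjusted sequence is a single plateau (general
  # idempotence does not hold for step-up adjustment)
  expect_equal(adjust_bh(adjust_bh(c(0.01, 0.02, 0.03, 0.04))), rep(0.04, 4))
})

test_that("call_genes computes per-time ratios and the control veto", {
  # g_up doubles (log2 +1) in SI from 1 h on; g_flat flat; g_both doubles in
  # both strains (control veto); replicate jitter makes variances nonzero.
  up <- flat_cells(10); up[c("SI_1", "SI_2", "SI_3", "SI_4")] <- 11
  both <- up; both[c("CONTROL_1", "CONTROL_2", "CONTROL_3", "CONTROL_4")] <- 11
  ds <- tiny_dataset(list(g_up = up, g_flat = flat_cells(10), g_both = both),
                     reps = 4, noise = 0.05, floor = 0, seed = 5)
  cfg <- analysis_config(adj_p_threshold = 0.05, detection_floor = 0)
  de <- call_genes(ds, cfg)
  expect_equal(de$fc_1h[de$gene_id == "g_up"], 2, tolerance = 0.15)
  expect_false(de$control_differential[de$gene_id == "g_up"])
  expect_equal(de$status[de$gene_id == "g_up"], "UP")
  expect_equal(de$status[de$gene_id == "g_flat"], "UNCHANGED")
  expect_true(abs(de$max_abs_fc[de$gene_id == "g_flat"]) < 1.3)
  # control strain shows the same change -> vetoed
  expect_true(de$control_differential[de$gene_id == "g_both"])
  expect_equal(de$status[de$gene_id == "g_both"], "UNCHANGED")
})

test_that("isp and silenced detection patterns classify correctly", {
  # isp: below floor at SI T0 and in control, detected from 1 h on
  isp <- flat_cells(3)
  isp[c("SI_1", "SI_2", "SI_3", "SI_4")] <- 10
  # silenced: at baseline at T0, below floor from 2 h on in SI
  sil <- flat_cells(10)
  sil[c("SI_2", "SI_3", "SI_4")] <- 3
  ds <- tiny_dataset(list(g_isp = isp, g_sil = sil, g_flat = flat_cells(10)),
                     reps = 4, noise = 0.05, floor = 5, seed = 9)
  de <- call_genes(ds, analysis_config(adj_p_threshold = 0.05, detection_floor = 5))
  expect_equal(de$status[de$gene_id == "g_isp"], "ISP")
  expect_equal(de$status[de$gene_id == "g_sil"], "SILENCED")
  expect_equal(de$status[de$gene_id == "g_flat"], "UNCHANGED")
  sets <- regulated_sets(de)
  expect_true("g_isp" %in% sets$up)
  expect_true("g_sil" %in% sets$down)
})

test_that("kinetics summary counts per-time calls and bins max fold changes", {
  cells <- list()
  # 3 genes first significant at 1 h (log2 + 2 from 1 h on)
  late <- flat_cells(10); late[c("SI_1", "SI_2", "SI_3", "SI_4")] <- 12
  for (i in 1:3) cells[[paste0("up", i)]] <- late
  # one huge responder: log2 + 6 => FC 64, lands in the [50, Inf) bin
  big <- flat_cells(10); big[c("SI_0.5", "SI_1", "SI_2", "SI_3", "SI_4")] <- 16
  cells$big <- big
  cells$flat <- flat_cells(10)
  ds <- tiny_dataset(cells, reps = 4, noise = 0.05, floor = 0, seed = 2)
  cfg <- analysis_config(adj_p_threshold = 0.05, detection_floor = 0)
  kin <- summarize_kinetics(call_genes(ds, cfg), cfg)
  expect_equal(kin$per_time$n_up[kin$per_time$time_h == 0.5], 1)  # only "big"
  expect_equal(kin$per_time$n_up[kin$per_time$time_h == 1], 4)
  expect_equal(kin$per_time$n_up[kin$per_time$time_h == 4], 4)
  expect_equal(unname(kin$fc_histogram["UP", "[50,Inf)"]), 1)
  expect_equal(sum(kin$fc_histogram["UP", ]), 4)
})

test_that("planted effects are recovered at the advertised operating point", {
  # scaled-down generator world: log2 effects >= 1.5, noise 0.25, 4 replicates
  spec <- small_spec(seed = 11)
  tr <- generate_truth(spec)
  ds <- generate_expression(tr$gene_map, tr$truth, spec)
  de <- call_genes(ds, analysis_config(rng_seed = 11, detection_floor = 5))
  sets <- regulated_sets(de)
  truth_up <- tr$truth$gene_id[tr$truth$direction == "up"]
  truth_null <- tr$truth$gene_id[tr$truth$direction == "none"]
  expect_gte(mean(truth_up %in% sets$up), 0.9)
  expect_lte(mean(truth_null %in% sets$up), 0.01)
  # FC_4h of a planted log2-2.0 plateau gene lands in [3, 5.3]
  plateau <- tr$truth$gene_id[!is.na(tr$truth$archetype) &
                                tr$truth$archetype %in% c("A", "B", "C") &
                                tr$truth$direction == "up" & !tr$truth$isp]
  fc4 <- de$fc_4h[match(plateau, de$gene_id)]
  amp <- tr$truth$amplitude_log2[match(plateau, tr$truth$gene_id)]
  near2 <- abs(amp - 2) < 0.05
  if (any(near2)) expect_true(all(fc4[near2] > 3 & fc4[near2] < 5.3))
})
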