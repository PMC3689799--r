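test_that("maximal runs are detected per chromosome without spanning", {
  gm <- tiny_gene_map(c(I = 6))
  # flags U,U,N,U,U,U -> runs of 2 and 3
  rs <- detect_runs(gm, c("g1", "g2", "g4", "g5", "g6"))
  expect_setequal(rs$runs$length, c(2, 3))
  expect_equal(rs$singletons, 0)
  expect_equal(unname(rs$counts_by_length[c("2", "3")]), c(1, 1))

  # run ending at a chromosome end counts fully
  rs2 <- detect_runs(gm, c("g4", "g5", "g6"))
  expect_equal(rs2$runs$length, 3)
  expect_equal(rs2$runs$start_index, 3)

  # last gene of chr I and first of chr II: two singletons, not a run
  gm2 <- tiny_gene_map(c(I = 3, II = 3))
  rs3 <- detect_runs(gm2, c("g3", "g4"))
  expect_equal(nrow(rs3$runs), 2)
  expect_true(all(rs3$runs$length == 1))
  expect_equal(rs3$singletons, 2)

  # UNPLACED genes are excluded; unknown genes rejected
  gm3 <- rbind(gm2, data.frame(gene_id = "gx", chromosome = "UNPLACED",
                               order_index = 0))
  expect_equal(detect_runs(gm3, c("g3", "gx"))$n_regulated_placed, 1)
  expect_error(detect_runs(gm2, "nope"), class = "isc_validation_error")
})

test_that("run detection conserves the regulated gene count", {
  set.seed(8)
  for (i in 1:20) {
    sizes <- c(I = sample(5:40, 1), II = sample(5:40, 1))
    gm <- tiny_gene_map(sizes)
    reg <- sample(gm$gene_id, sample.int(nrow(gm), 1))
    rs <- detect_runs(gm, reg)
    total <- sum(as.integer(names(rs$counts_by_length)) * rs$counts_by_length) +
      rs$singletons
    expect_equal(total, length(reg))
  }
})

test_that("null window counts follow c_n = f^n * g", {
  expect_true(all(null_window_counts(0, 100) == 0))
  expect_true(all(null_window_counts(1, 100) == 100))
  cn <- null_window_counts(2231 / 10556, 10556)
  expect_equal(unname(cn["3"]), (2231 / 10556)^3 * 10556, tolerance = 1e-12)
  expect_equal(unname(cn["3"]), 99.6, tolerance = 1e-3)
  expect_error(null_window_counts(1.2, 100), class = "isc_domain_error")
})

test_that("embedded-run correction has the stated coefficients and inverts", {
  zeros <- setNames(rep(0, 9), 2:10)
  expect_true(all(corrected_run_counts(zeros) == 0))
  # contribution of N_10 to N_n: a run of 10 holds 10 - n + 1 windows of n;
  # read the coefficients off a c vector with only c_10 nonzero
  c10 <- zeros; c10["10"] <- 1
  N <- corrected_run_counts(c10)
  expect_equal(unname(N["10"]), 1)
  expect_equal(unname(N["9"]), -2)   # N_9 = c_9 - 2 N_10
  # general inversion: c_n = sum_{m >= n} (m - n + 1) N_m
  set.seed(5)
  cn <- setNames(sort(runif(9, 0, 50), decreasing = TRUE), 2:10)
  N <- corrected_run_counts(cn)
  for (n in 2:10) {
    m <- n:10
    expect_equal(sum((m - n + 1) * N[as.character(m)]), unname(cn[as.character(n)]),
                 tolerance = 1e-10)
  }
  expect_error(corrected_run_counts(setNames(1:3, c(2, 4, 5))),
               class = "isc_domain_error")
})

test_that("corrected counts approach the stationary maximal-run closed form", {
  f <- 0.2; g <- 10556
  N <- corrected_run_counts(null_window_counts(f, g, nmax = 30))
  closed <- g * f^(2:6) * (1 - f)^2
  expect_equal(unname(N[as.character(2:6)]), closed, tolerance = 0.01)
})

test_that("expected in-run fraction reproduces the published 3% and 4%", {
  expect_equal(round(100 * expected_fraction_in_runs(2231 / 10556, 10556, 4)), 3)
  expect_equal(round(100 * expected_fraction_in_runs(2441 / 10556, 10556, 4)), 4)
  expect_equal(expected_fraction_in_runs(0.5, 10, 2, 5) >= 0, TRUE)
  expect_error(expected_fraction_in_runs(0, 100, 4), class = "isc_domain_error")
})

test_that("run simulation behaves at the degenerate extremes", {
  full <- simulate_random_runs(g = 15, m = 15, n_sets = 3, seed = 1, nmax = 15)
  expect_equal(unname(full["15"]), 1)
  expect_true(all(full[as.character(2:14)] == 0))
  none <- simulate_random_runs(g = 15, m = 0, n_sets = 3, seed = 1)
  expect_true(all(none == 0))
  expect_error(simulate_random_runs(10, 11), class = "isc_domain_error")
  # determinism
  a <- simulate_random_runs(100, 30, n_sets = 5, seed = 42)
  expect_identical(a, simulate_random_runs(100, 30, n_sets = 5, seed = 42))
})

test_that("exact enumeration matches hand counts and the simulation", {
  # g = 3, m = 2: placements {12},{13},{23} -> expected runs-of-2 = 2/3
  ex <- enumerate_exact_run_counts(3, 2)
  expect_equal(unname(ex["2"]), 2 / 3)
  expect_equal(unname(ex["1"]), 2 / 3)   # {13} gives two singletons
  ex3 <- enumerate_exact_run_counts(3, 3)
  expect_equal(unname(ex3["3"]), 1)
  expect_error(enumerate_exact_run_counts(200, 100), class = "isc_capacity_error")

  # simulation agrees with enumeration within 3 standard errors on small grids
  for (gm in list(c(8, 3), c(10, 4), c(12, 5))) {
    g <- gm[1]; m <- gm[2]
    ex <- enumerate_exact_run_counts(g, m)
    n_sets <- 4000
    sim <- simulate_random_runs(g, m, n_sets = n_sets, seed = 99, nmax = g)
    for (n in 2:min(m, g)) {
      # Poisson-style bound on the Monte-Carlo standard error of the mean
      se <- sqrt(max(ex[as.character(n)], 1e-9) / n_sets)
      expect_lt(abs(sim[as.character(n)] - ex[as.character(n)]), max(3 * se, 0.02),
                label = sprintf("g=%d m=%d n=%d", g, m, n))
    }
  }
})

test_that("chromosome enrichment reproduces printed per-chromosome factors", {
  # analog of the published table: 2231 up-regulated among 10394 placed genes
  sizes <- c(I = 2557L, II = 1569L, III = 1208L, IV = 1119L, V = 1447L,
             VI = 1277L, VII = 1217L)
  up_counts <- c(I = 533L, II = 281L, III = 230L, IV = 293L, V = 372L,
                 VI = 280L, VII = 242L)
  gm <- tiny_gene_map(sizes)
  reg <- unlist(lapply(names(sizes), function(chr) {
    ids <- gm$gene_id[gm$chromosome == chr]
    ids[seq_len(up_counts[chr])]
  }))
  ce <- chromosome_enrichment(gm, reg)
  expect_equal(ce$n[1], 2231)
  expect_equal(ce$G[1], 10394)
  expect_equal(round(ce$enrichment[ce$chromosome == "I"], 2), 0.97)
  expect_equal(round(ce$enrichment[ce$chromosome == "IV"], 2), 1.22)
  expect_equal(round(ce$enrichment[ce$chromosome == "V"], 2), 1.20)
  expect_lt(ce$p_value[ce$chromosome == "IV"], 0.001)
  # uniform placement: all enrichments 1
  gmu <- tiny_gene_map(c(I = 10L, II = 10L))
  regu <- gmu$gene_id[gmu$order_index < 5]
  expect_true(all(chromosome_enrichment(gmu, regu)$enrichment == 1))
})

test_that("sliding windows scan within chromosomes", {
  gm <- tiny_gene_map(c(I = 50L, II = 10L))
  expect_warning(d <- sliding_window_density(gm, gm$gene_id, window = 30),
                 "II")
  expect_true(all(d$fraction == 1))
  expect_equal(nrow(d), 50 - 30 + 1)
  # 6 flagged in a 30-gene window -> 0.2
  flags <- gm$gene_id[gm$chromosome == "I"][1:6]
  d2 <- suppressWarnings(sliding_window_density(gm, flags, window = 30))
  expect_equal(d2$fraction[1], 0.2)
  expect_equal(d2$fraction[nrow(d2)], 0)
  # planted island: maximum fraction at windows overlapping it
  gm3 <- tiny_gene_map(c(I = 200L))
  island <- gm3$gene_id[101:120]
  set.seed(1)
  background <- sample(setdiff(gm3$gene_id, island), 10)
  d3 <- sliding_window_density(gm3, c(island, background), window = 30)
  best <- d3$window_start[which.max(d3$fraction)]
  expect_true(best >= 80 && best <= 110)
  expect_gte(max(d3$fraction), 20 / 30)
})

test_that("analytic null matches a large Monte-Carlo simulation within 10%", {
  g <- 10556; m <- 2231
  N <- corrected_run_counts(null_window_counts(m / g, g, 10))
  sim <- simulate_random_runs(g, m, n_sets = 200, seed = 7, nmax = 10)
  for (n in 2:4) {
    rel <- abs(sim[as.character(n)] - N[as.character(n)]) / N[as.character(n)]
    expect_lt(rel, 0.10, label = paste("run size", n))
  }
})
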