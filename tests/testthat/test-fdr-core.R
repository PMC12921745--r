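make_ranked <- function(scores, is_decoy = rep(FALSE, length(scores)),
                        is_modified = rep(FALSE, length(scores))) {
  rank_psms(data.table::data.table(
    file = "f", scan = seq_along(scores), charge = 2L,
    peptide = "PEPK", modifications = "", score = scores,
    is_decoy = is_decoy, is_modified = is_modified, proteins = "P1"))
}

test_that("ranking is ascending in score with stable ties and full bijection", {
  expect_equal(make_ranked(c(10, 5, 7.5))$rank, c(3L, 1L, 2L))
  expect_equal(make_ranked(rep(1, 4))$rank, 1:4)          # tie rule
  # brute-force re-sort oracle on 1000 simulated records
  sim <- simulate_psm_set(simulation_config(n_total = 1000, seed = 11))
  ranked <- rank_psms(sim)
  expect_setequal(ranked$rank, seq_len(nrow(sim)))
  ord <- order(sim$score)   # stable sort, same tie convention
  expect_equal(ranked$rank[ord], seq_len(nrow(sim)))
  expect_true(all(diff(ranked$score[order(ranked$rank)]) >= 0))
  # the four subsets partition the records
  expect_equal(sum(table(ranked$label)), nrow(sim))
  expect_error(make_ranked(c(1, NA, 2)), "non-finite")
})

test_that("count curves match hand counts and are monotone", {
  ranked <- make_ranked(1:10, is_decoy = seq_len(10) %in% c(3, 8))
  # decoys end up at ranks 3 and 8 (scores already sorted)
  cc <- count_curves(ranked, grid = c(1, 2, 4, 9))
  expect_equal(cc$D, c(2L, 2L, 1L, 0L))
  full <- count_curves(ranked, grid = "all")
  expect_equal(full$N[1], 8L)     # threshold 1: everything counted
  expect_equal(full$D[1], 2L)
  for (col in c("N", "N_k", "D", "D_k", "T")) {
    expect_true(all(diff(full[[col]]) <= 0), info = col)
  }
})

test_that("global FDR handles empty-target thresholds", {
  # top-scoring PSM is a decoy: T(N)=0 with D(N)=1 -> undefined, flagged NA
  ranked <- make_ranked(1:5, is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  cc <- count_curves(ranked, grid = "all")
  expect_true(is.na(cc$fdr[5]))
  expect_equal(cc$fdr[1], 1 / 4)
})

test_that("error propagation reproduces the closed form", {
  expect_equal(error_propagation(200, 200), 0.1, tolerance = 1e-12)
  expect_equal(error_propagation(1, 1), sqrt(2), tolerance = 1e-12)
  expect_equal(error_propagation(100, 10000),
               (100 / 10000) * sqrt(1 / 100 + 1 / 10000), tolerance = 1e-12)
  expect_true(is.na(error_propagation(0, 10)))
  expect_error(error_propagation(5, 2), "exceed")
})

test_that("gamma curve estimation applies the stability cutoff", {
  cc <- data.table::data.table(threshold = c(1L, 50L), N = c(100L, 50L),
                               N_k = c(20L, 10L), D = c(100L, 10L),
                               D_k = c(50L, 5L), T = c(120L, 60L),
                               fdr = c(100 / 120, 10 / 60))
  gc <- estimate_gamma_curve(cc, sigma_cutoff = 0.2)
  expect_equal(gc$gamma_hat, c(0.5, 0.5))
  expect_equal(gc$sigma, c(0.5 * sqrt(1 / 50 + 1 / 100),
                           0.5 * sqrt(1 / 5 + 1 / 10)))
  expect_equal(gc$stable, c(TRUE, FALSE))   # second threshold too noisy
  # constant counts give a constant gamma
  cc2 <- data.table::data.table(threshold = 1:3, N = 10L, N_k = 1L,
                                D = rep(400L, 3), D_k = rep(100L, 3),
                                T = 11L, fdr = 0.1)
  expect_equal(unique(estimate_gamma_curve(cc2,
                                           sigma_cutoff = 0.05)$gamma_hat),
               0.25)
  # no stable threshold at all is an estimation error
  cc3 <- data.table::data.table(threshold = 1:2, N = 1L, N_k = 1L,
                                D = c(4L, 2L), D_k = c(2L, 1L), T = 2L,
                                fdr = 1)
  expect_error(estimate_gamma_curve(cc3), "cutoff")
})

test_that("the sigma filter excludes exactly the thresholds the formula says", {
  sim <- simulate_gamma_observations(
    profile = list(type = "constant", value = 0.3),
    n_thresholds = 50, decoy_counts = round(seq(5000, 20, length.out = 50)),
    seed = 5)
  direct <- (sim$D_k / sim$D) * sqrt(1 / sim$D_k + 1 / sim$D)
  expect_equal(sim$stable,
               !is.na(direct) & direct <= 0.01 & sim$D_k >= 1)
})

test_that("decoy/target ratio equals element-wise division", {
  sim <- simulate_psm_set(simulation_config(n_total = 800, seed = 2))
  cc <- count_curves(rank_psms(sim))
  rho <- decoy_target_ratio(cc)
  keep <- cc$T > 0
  expect_equal(rho$rho, cc$D[keep] / cc$T[keep], tolerance = 1e-15)
  # all-target set: ratio identically zero
  allt <- make_ranked(1:10)
  expect_true(all(decoy_target_ratio(count_curves(allt, grid = "all"))$rho == 0))
})

test_that("inflection search finds the slope break of a kinked ratio", {
  # shallow then steep: derivative minimum plateau starts at the join
  grid <- 1:1000
  rho <- ifelse(grid <= 500, 0.8 - 1e-4 * grid,
                0.8 - 1e-4 * 500 - 2e-3 * (grid - 500))
  anchor <- find_inflection_rank(data.frame(threshold = grid, rho = rho),
                                 smoothing_sigma = 10)
  # the minimum plateau begins once the kernel (half-width 4 sigma) has
  # fully entered the steep segment
  expect_lt(abs(anchor - 500), 8 * 10)
  # strictly linear ratio: constant derivative, tie -> smallest rank
  lin <- find_inflection_rank(data.frame(threshold = grid,
                                         rho = 1 - 5e-4 * grid),
                              smoothing_sigma = 10)
  expect_equal(lin, 1)
  # vanishing smoothing equals the argmin of the raw finite differences
  set.seed(1)
  wiggly <- 0.5 - 3e-4 * grid + 0.02 * sin(grid / 40)
  raw_d <- c(diff(wiggly)[1],
             (wiggly[3:1000] - wiggly[1:998]) / 2,
             diff(wiggly)[999])
  expect_equal(find_inflection_rank(data.frame(threshold = grid,
                                               rho = wiggly),
                                    smoothing_sigma = 1e-9),
               grid[which.min(raw_d)])
  expect_error(find_inflection_rank(data.frame(threshold = 1:4,
                                               rho = rep(1, 4))),
               "fewer than 5")
})

test_that("linear gamma fit recovers exact lines and matches the OLS oracle", {
  gc <- data.table::data.table(threshold = 1:100, D = 1000L, D_k = 500L,
                               gamma_hat = 0.001 * (1:100),
                               sigma = 0.001, stable = TRUE)
  fit <- fit_linear_gamma(gc)
  expect_equal(fit$b, 0.001, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
  gc$gamma_hat <- 0.3
  flat <- fit_linear_gamma(gc)
  expect_equal(flat$a, 0.3, tolerance = 1e-12)
  expect_equal(flat$b, 0, tolerance = 1e-12)
  set.seed(9)
  gc$gamma_hat <- 0.2 + 0.0005 * gc$threshold + rnorm(100, sd = 0.01)
  noisy <- fit_linear_gamma(gc)
  ora <- oracle_ols(gc$threshold, gc$gamma_hat)
  expect_equal(noisy$a, unname(ora["a"]), tolerance = 1e-9)
  expect_equal(noisy$b, unname(ora["b"]), tolerance = 1e-9)
  expect_error(fit_linear_gamma(gc[1, ]), "at least 2")
})

test_that("spline fit recovers an exact two-segment model through the anchor", {
  grid <- 1:200
  truth <- ifelse(grid <= 120, 0.1 + 0.002 * grid,
                  0.1 + 0.002 * 120 - 0.001 * (grid - 120))
  gc <- data.table::data.table(threshold = grid, D = 10000L, D_k = 100L,
                               gamma_hat = truth, sigma = 0.001,
                               stable = TRUE)
  fit <- fit_spline_linear_gamma(gc, anchor = 120, n_interior_knots = 1L)
  expect_true(120 %in% fit$nodes)
  expect_equal(fit$b, c(0.002, -0.001), tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)
  expect_true(fit$anchored)
})

test_that("a zero-knot spline collapses to the linear fit", {
  set.seed(4)
  gc <- data.table::data.table(threshold = 1:80, D = 1000L, D_k = 300L,
                               gamma_hat = 0.3 + rnorm(80, sd = 0.01),
                               sigma = 0.005, stable = TRUE)
  s <- fit_spline_linear_gamma(gc, anchor = 40, n_interior_knots = 0L)
  l <- fit_linear_gamma(gc)
  expect_equal(s$a, l$a, tolerance = 1e-9)
  expect_equal(s$b, l$b, tolerance = 1e-9)
})

test_that("an anchor outside the stable range falls back with a flag", {
  set.seed(6)
  gc <- data.table::data.table(threshold = 1:60, D = 1000L, D_k = 300L,
                               gamma_hat = 0.3 + rnorm(60, sd = 0.01),
                               sigma = 0.005, stable = TRUE)
  expect_warning(fit <- fit_spline_linear_gamma(gc, anchor = 500,
                                                n_interior_knots = 2L),
                 "outside")
  expect_false(fit$anchored)
  expect_length(fit$a, 3L)
})

test_that("gamma evaluation is continuous, extrapolates, and clips", {
  m <- fake_gamma_model()
  # continuity at the interior knot
  eps <- 1e-9
  expect_equal(evaluate_gamma(m, 300 - eps), evaluate_gamma(m, 300 + eps),
               tolerance = 1e-6)
  # extrapolation past the last node uses the last segment
  m2 <- m; m2$a <- c(0.2, 0.05); m2$b <- c(5e-4, -1e-5)
  expect_equal(evaluate_gamma(m2, 2000, clip = FALSE), 0.05 - 1e-5 * 2000,
               tolerance = 1e-12)
  # a segment predicting negative gamma clips to zero
  expect_equal(evaluate_gamma(m2, 1e6), 0)
  expect_equal(evaluate_gamma(m, c(1, 150, 999)),
               oracle_piecewise(m$nodes, m$a, m$b, c(1, 150, 999)))
})

test_that("model continuity holds at every interior knot of a noisy fit", {
  sim <- simulate_gamma_observations(
    profile = list(type = "logistic", lo = 0.1, hi = 0.4, midpoint = 0.5,
                   slope = 8),
    n_thresholds = 300,
    decoy_counts = round(seq(60000, 6000, length.out = 300)), seed = 13)
  fit <- fit_spline_linear_gamma(sim, anchor = 150, n_interior_knots = 3L)
  for (k in fit$nodes[-c(1, length(fit$nodes))]) {
    expect_equal(evaluate_gamma(fit, k - 1e-9), evaluate_gamma(fit, k + 1e-9),
                 tolerance = 1e-10)
  }
})

test_that("transferred FDR reproduces the defining arithmetic", {
  cc <- data.table::data.table(threshold = 1L, N = 900L, N_k = 100L,
                               D = 10L, D_k = 1L, T = 1000L, fdr = 0.01)
  m <- fake_gamma_model(); m$a <- c(0.1, 0.1); m$b <- c(0, 0)
  tf <- transferred_fdr_curve(cc, m)
  expect_equal(tf$fdr_k, (900 / 100) * 0.1 * 0.01, tolerance = 1e-12)
  # zero gamma nullifies the curve
  m0 <- fake_gamma_model(); m0$a <- c(0, 0); m0$b <- c(0, 0)
  expect_equal(transferred_fdr_curve(cc, m0)$fdr_k, 0)
  # thresholds without modified targets are skipped
  cc2 <- rbind(cc, data.table::data.table(threshold = 2L, N = 10L, N_k = 0L,
                                          D = 1L, D_k = 0L, T = 10L,
                                          fdr = 0.1))
  expect_equal(nrow(transferred_fdr_curve(cc2, m)), 1L)
  # all-targets numerator switch
  expect_equal(transferred_fdr_curve(cc, m, n_definition = "all_targets")$fdr_k,
               (1000 / 100) * 0.1 * 0.01, tolerance = 1e-12)
})

test_that("separate FDR matches a subset-only hand count", {
  # 99 modified targets, 1 modified decoy scoring worst
  scores <- c(1, seq(2, by = 1, length.out = 99))
  ranked <- make_ranked(scores,
                        is_decoy = c(TRUE, rep(FALSE, 99)),
                        is_modified = rep(TRUE, 100))
  sep <- separate_fdr_curve(ranked)
  expect_equal(sep$fdr_sep[sep$threshold == 1], 1 / 99)
  expect_true(all(sep$q[sep$threshold > 1] == 0))
  # only decoys: empty output
  alldec <- make_ranked(1:5, is_decoy = rep(TRUE, 5),
                        is_modified = rep(TRUE, 5))
  expect_equal(nrow(separate_fdr_curve(alldec)), 0L)
  # oracle equality on a simulated subset
  sim <- simulate_psm_set(simulation_config(n_total = 600, seed = 8))
  r <- rank_psms(sim)
  got <- separate_fdr_curve(r)
  ora <- oracle_separate(r)
  expect_equal(got$fdr_sep, ora$fdr_sep, tolerance = 1e-12)
})

test_that("q-values monotonize the curve and set the rank threshold", {
  # values listed worst-to-best threshold: the running minimum over more
  # permissive thresholds gives (0.03, 0.008, 0.008)
  cur <- data.table::data.table(threshold = c(10L, 20L, 30L),
                                fdr_k = c(0.03, 0.008, 0.02))
  res <- qvalues_and_threshold(cur, alpha = 0.01)
  expect_equal(res$curve$q, c(0.03, 0.008, 0.008))
  expect_equal(res$threshold_rank, 20L)
  expect_true(all(diff(res$curve$q) <= 0 + 1e-15))
  # nothing below alpha: no acceptance
  none <- qvalues_and_threshold(data.table::data.table(
    threshold = 1:3, fdr_k = c(0.5, 0.2, 0.3)), alpha = 0.01)
  expect_true(is.na(none$threshold_rank))
  expect_false(any(none$curve$accepted))
})

test_that("q-values are non-increasing with rank on random curves", {
  for (s in 1:5) {
    set.seed(s)
    cur <- data.table::data.table(threshold = sort(sample(1:500, 60)),
                                  fdr_k = runif(60, 0, 0.3))
    q <- qvalues_and_threshold(cur)$curve$q
    expect_true(all(diff(q) <= 1e-15))
  }
})

test_that("per-PSM annotations agree with the rank threshold rule", {
  sim <- simulate_psm_set(simulation_config(n_total = 2000, seed = 21))
  ranked <- rank_psms(sim)
  cc <- count_curves(ranked)
  gc <- estimate_gamma_curve(cc, sigma_cutoff = 0.05)
  m <- fit_linear_gamma(gc)
  tf <- transferred_fdr_curve(cc, m)
  res <- qvalues_and_threshold(tf, alpha = 0.01, ranked = ranked)
  ann <- res$annotations
  expect_equal(nrow(ann), sum(!sim$is_decoy & sim$is_modified))
  if (!is.na(res$threshold_rank)) {
    expect_equal(ann$accepted, ann$rank >= res$threshold_rank)
    expect_true(all(ann$q_value[ann$accepted] <= 0.01 + 1e-12))
  }
})
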