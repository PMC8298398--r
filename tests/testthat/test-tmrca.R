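test_that("pairwise differences count joint coverage and mismatches", {
  a <- make_consensus(1:100, rep("A", 100), "S1")
  b <- make_consensus(1:100, rep("A", 100), "S2")
  pd <- pairwise_differences(a, b)
  expect_equal(pd$n_overlap, 100)
  expect_equal(pd$d, 0)
  expect_equal(pd$relative_divergence, 0)

  disjoint <- pairwise_differences(make_consensus(1:5, rep("A", 5), "S1"),
                                   make_consensus(6:10, rep("A", 5), "S2"))
  expect_equal(disjoint$n_overlap, 0)
  expect_false(disjoint$usable)
  expect_true(is.na(disjoint$relative_divergence))

  mix <- pairwise_differences(
    make_consensus(1:4, c("A", "C", "G", "T"), "S1"),
    make_consensus(c(2, 3, 4, 9), c("T", "G", "A", "C"), "S2"))
  expect_equal(mix$n_overlap, 3)
  expect_equal(mix$d, 2)
})

test_that("the damage-exclusion mode drops transition-type mismatches", {
  a <- make_consensus(1:4, c("C", "G", "A", "A"), "S1")
  b <- make_consensus(1:4, c("T", "A", "C", "A"), "S2")
  plain <- pairwise_differences(a, b)
  expect_equal(plain$d, 3)
  strict <- pairwise_differences(a, b, exclude_damage_pairs = TRUE)
  expect_equal(strict$d, 1)          # A/C transversion kept
  expect_equal(strict$n_overlap, 2)  # C/T and G/A sites not comparable
})

test_that("simulated pairwise differences match the Poisson closed form", {
  mu <- 1e-8
  L <- 5e4
  T_split <- 40000
  tr <- simulate_tree(2, T_split, seed = 401)
  n_rep <- 200
  d <- n <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    truth <- place_mutations(tr, mu = mu, L = L, seed = 5000 + r)
    em <- emit_pileups(truth, mean_depth = 10, missing_frac = 0.2,
                       damage_rate = 0, seed = 6000 + r)
    cs <- lapply(em$pileups, consensus_sequence)
    pd <- pairwise_differences(cs[[1]], cs[[2]])
    d[r] <- pd$d
    n[r] <- pd$n_overlap
  }
  lambda <- 2 * mu * mean(n) * T_split
  expect_lt(abs(mean(d) - lambda), 3 * sqrt(lambda / n_rep))
})

test_that("calibration algebra is exact on the anchor", {
  one <- list(list(n_overlap = 50000, d = 100))   # relative divergence 0.001
  cal <- calibrate(one, anchor_years = 161300)
  expect_equal(cal$c_years, 161300 / 0.001)
  # applying the calibration back to the anchor pairs reproduces the anchor
  est <- estimate_tmrca(one[[1]], cal)
  expect_equal(est$tmrca_years, 161300)

  several <- list(list(n_overlap = 1e4, d = 30), list(n_overlap = 2e4, d = 50),
                  list(n_overlap = 5e3, d = 9))
  cal2 <- calibrate(several, anchor_years = 161300)
  mean_est <- mean(vapply(several, function(p)
    estimate_tmrca(p, cal2)$tmrca_years, 0))
  expect_equal(mean_est, 161300)
  expect_error(calibrate(list(list(n_overlap = 0, d = 0))), "usable")
})

test_that("TMRCA confidence intervals are the mapped exact Poisson intervals", {
  cal <- structure(list(c_years = 1e6, anchor_years = 161300,
                        anchor_label = NULL, n_pairs = 1),
                   class = "calibration_anchor")
  est <- estimate_tmrca(list(n_overlap = 10000, d = 4), cal)
  expect_equal(est$tmrca_years, 200)
  # oracle: Garwood endpoints via chi-square/gamma quantiles
  expect_equal(est$ci_low, 1e6 * qgamma(0.025, 4) / 20000)
  expect_equal(est$ci_high, 1e6 * qgamma(0.975, 5) / 20000)
  expect_lt(est$ci_low, est$tmrca_years)
  expect_gt(est$ci_high, est$tmrca_years)

  zero <- estimate_tmrca(list(n_overlap = 10000, d = 0), cal)
  expect_equal(zero$tmrca_years, 0)
  expect_equal(zero$ci_low, 0)
  expect_gt(zero$ci_high, 0)

  cal2 <- cal
  cal2$c_years <- 2e6
  est2 <- estimate_tmrca(list(n_overlap = 10000, d = 4), cal2)
  expect_equal(est2$tmrca_years, 2 * est$tmrca_years)   # scale equivariance
  expect_equal(est2$ci_high, 2 * est$ci_high)

  expect_error(estimate_tmrca(list(n_overlap = 0, d = 0), cal), "jointly")
})

test_that("calibration recovers the inverse substitution rate on simulations", {
  mu <- 8e-9
  tr <- simulate_tree(2, 161300, seed = 421)
  truth <- place_mutations(tr, mu = mu, L = 1e6, seed = 422)
  em <- emit_pileups(truth, mean_depth = 10, missing_frac = 0.1,
                     damage_rate = 0, seed = 423)
  cs <- lapply(em$pileups, consensus_sequence)
  cal <- calibrate(list(pairwise_differences(cs[[1]], cs[[2]])),
                   anchor_years = 161300)
  expect_lt(abs(cal$c_years * mu - 1), 0.1)   # c ~ 1/mu within sampling error
})

test_that("estimates ignore missing-only positions", {
  a <- make_consensus(1:10, rep(c("A", "G"), 5), "S1")
  b <- make_consensus(1:10, rep("A", 10), "S2")
  a2 <- make_consensus(c(1:10, 50:59), c(rep(c("A", "G"), 5), rep("C", 10)), "S1")
  pd <- pairwise_differences(a, b)
  pd2 <- pairwise_differences(a2, b)
  expect_equal(pd2$n_overlap, pd$n_overlap)
  expect_equal(pd2$d, pd$d)
})

test_that("SNP-panel consensuses are refused for TMRCA unless overridden", {
  cal <- structure(list(c_years = 1e6, anchor_years = 161300,
                        anchor_label = NULL, n_pairs = 1),
                   class = "calibration_anchor")
  cons <- list(S1 = make_consensus(1:50, rep("A", 50), "S1", mode = "shotgun"),
               S2 = make_consensus(1:50, rep(c("A", "G"), 25), "S2",
                                   mode = "snp-panel"))
  expect_error(tmrca_pairs(cons, cal), "panel")
  ok <- tmrca_pairs(cons, cal, allow_snp_panel = TRUE)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$d, 25)
})

test_that("clade summaries average cross-group pairs after same-site exclusion", {
  pairs <- data.frame(sample_a = c("A1", "A1", "A2"),
                      sample_b = c("B1", "B2", "B1"),
                      n_overlap = 100, d = 2,
                      tmrca_years = c(10000, 12000, 14000),
                      ci_low = 9000, ci_high = 15000,
                      same_site = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  groups <- data.frame(sample = c("A1", "A2", "B1", "B2"),
                       group = c("H2d", "H2d", "H2m", "H2m"))
  s <- clade_summary(pairs, groups, "H2d", "H2m")
  expect_equal(s$n_pairs, 2)
  expect_equal(s$mean_tmrca_years, 11000)

  all_same <- pairs
  all_same$same_site <- TRUE
  expect_error(clade_summary(all_same, groups, "H2d", "H2m"), "same-site")
  s2 <- clade_summary(all_same, groups, "H2d", "H2m", exclude_same_site = FALSE)
  expect_equal(s2$n_pairs, 3)
})
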