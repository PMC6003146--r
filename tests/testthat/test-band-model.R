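test_that("step probability follows the two-read indel rate formula", {
  expect_equal(step_probability(error_set(1)), 0.22470)
  expect_equal(step_probability(error_set(2)), 0.116, tolerance = 1e-12)
  expect_equal(step_probability(error_profile(1, 0, 0, 0)), 0)
  expect_equal(step_probability(error_profile_pacbio()), 0.2070,
               tolerance = 1e-12)
})

test_that("sigma_d matches the closed form and its benchmark values", {
  expect_equal(round(sigma_d(error_set(1), 2000), 1), 30.0)
  expect_equal(round(sigma_d(error_set(3), 6000), 1), 45.3)
  expect_equal(round(sigma_d(error_profile_pacbio(), 30000)), 111)
  # monotone in N and in the indel rates
  expect_true(all(diff(sigma_d(error_set(2), c(1, 10, 100, 5000))) > 0))
  s_by_pi <- vapply(c(0.01, 0.03, 0.05),
                    function(pi) sigma_d(error_profile(0.9 - pi, 0.05, pi,
                                                       0.05), 1000),
                    numeric(1))
  expect_true(all(diff(s_by_pi) > 0))
  s_by_pd <- vapply(c(0.01, 0.03, 0.05),
                    function(pd) sigma_d(error_profile(0.9 - pd, 0.05, 0.05,
                                                       pd), 1000),
                    numeric(1))
  expect_true(all(diff(s_by_pd) > 0))
})

test_that("asymmetric walk variance reduces to 2Np and matches sampling", {
  p <- 0.17
  expect_equal(walk_displacement_variance(p, p, 1500), 2 * 1500 * p,
               tolerance = 1e-12)
  # multinomial sampling check, asymmetric case
  set.seed(11)
  N <- 200; pr <- 0.2; pl <- 0.1
  counts <- stats::rmultinom(1e5, N, c(pr, pl, 1 - pr - pl))
  d <- counts[1, ] - counts[2, ]
  expect_equal(mean(d), N * (pr - pl), tolerance = 0.02)
  expect_equal(var(d), walk_displacement_variance(pr, pl, N),
               tolerance = 0.02)
})

test_that("the normal-model band exit chance at 3 sigma is under 0.3%", {
  expect_lt(2 * (1 - pnorm(3)), 0.003)
  expect_equal(2 * (1 - pnorm(3)), 0.0027, tolerance = 0.01)
})

test_that("band schedule widens by sigma then doubles, capped at l2", {
  expect_equal(band_schedule(26.2, 2000, 2000),
               c(27, 53, 79, 158, 316, 632, 1264, 2000))
  expect_equal(band_schedule(10, 30, 25), c(10, 20, 25))
  expect_equal(band_schedule(1, 1, 1), 1)
  set.seed(21)
  for (k in 1:20) {
    l2 <- sample(10:3000, 1)
    ws <- band_schedule(runif(1, 0.5, 60), l2 + sample(0:50, 1), l2)
    expect_true(all(diff(ws) > 0))
    expect_equal(ws[length(ws)], min(l2, ws[length(ws)]))
    expect_gte(ws[length(ws)], min(l2, ws[length(ws)]))
    expect_equal(ws[length(ws)], l2)
  }
})

test_that("expected schedule cost reproduces the 3.52 coefficient", {
  expect_equal(expected_cost_coefficient(c(0.68, 0.28, 0.04)), 3.52)
  expect_equal(expected_cost_coefficient(1), 2)
  expect_equal(expected_cost_coefficient(c(0, 0, 1)), 12)
  expect_error(expected_cost_coefficient(c(0.5, 0.2)), "sum to 1")
})

test_that("best_out bound evaluates the out-of-band score cap", {
  expect_equal(best_out_score(3, 20, 12), 24)
  # w = l2 - 1: the match term vanishes
  sc <- scoring_scheme()
  expect_equal(best_out_score(11, 20, 12, sc), (2 * 12 - 8) * sc$gap)
  # one step wider changes the bound by 2g - m
  b <- vapply(3:8, best_out_score, numeric(1), l1 = 20, l2 = 12,
              scoring = sc)
  expect_true(all(diff(b) == 2 * sc$gap - sc$match))
  expect_true(is.na(best_out_score(12, 20, 12)))
})

test_that("global certification compares the banded score to best_out", {
  d1 <- certify_global(30, 3, 20, 12)
  expect_true(d1$accepted); expect_equal(d1$reason, "global_bound_certified")
  d2 <- certify_global(24, 3, 20, 12)
  expect_true(d2$accepted)
  d3 <- certify_global(23, 3, 20, 12)
  expect_false(d3$accepted); expect_equal(d3$reason, "global_bound_failed")
  expect_equal(d3$threshold_used, 24)
  # a band no path can leave certifies unconditionally
  expect_true(certify_global(-100, 12, 20, 12)$accepted)
})

test_that("match-count bounds implement the binomial 99% half-interval", {
  b <- match_count_bounds(error_set(3), 2000)
  expect_equal(b[["mean"]], 1780)
  expect_equal(b[["sd"]], sqrt(2000 * 0.89 * 0.11), tolerance = 1e-12)
  expect_equal(b[["lower_threshold"]], 1780 - 3 * b[["sd"]])
  expect_equal(unname(match_count_bounds(error_profile(1, 0, 0, 0), 500)),
               c(500, 0, 500))
  expect_equal(unname(match_count_bounds(error_profile(0, 1, 0, 0), 500)[
    c("mean", "sd", "lower_threshold")]), c(0, 0, 0))
})

test_that("semi-global certification applies edge then match-count", {
  prof <- error_set(3)
  # criterion i has priority even with a huge match count
  d1 <- certify_semiglobal(fake_alignment(1950, TRUE), prof, N = 2000)
  expect_false(d1$accepted); expect_equal(d1$reason, "edge_touched")
  # 1750 matches clears the ~1738 threshold
  d2 <- certify_semiglobal(fake_alignment(1750, FALSE), prof, N = 2000)
  expect_true(d2$accepted); expect_equal(d2$reason, "in_band_certified")
  # 1700 does not
  d3 <- certify_semiglobal(fake_alignment(1700, FALSE), prof, N = 2000)
  expect_false(d3$accepted); expect_equal(d3$reason, "match_count_low")
  expect_equal(d3$threshold_used, 1780 - 3 * sqrt(2000 * 0.89 * 0.11))
})

test_that("adaptive alignment accepts identical reads at the first stage", {
  s <- random_sequence(800, seed = 31)
  ad <- align_adaptive(s, s, error_set(2))
  expect_length(ad$stages_used, 1)
  expect_true(ad$decision$accepted)
  expect_equal(ad$result$score, 3L * 800L)
})

test_that("adaptive alignment falls back to the exact full-matrix result", {
  # reversing half of one read destroys the diagonal structure entirely
  set.seed(41)
  a <- random_dna(600)
  half <- paste0(substr(a, 1, 300),
                 paste(rev(strsplit(substr(a, 301, 600), "")[[1]]),
                       collapse = ""))
  ad <- align_adaptive(a, half, error_set(3))
  f <- full_dp_align(a, half, mode = "semiglobal")
  expect_equal(ad$result$score, f$score)
  # never certified, so the last stage is the full-matrix band
  expect_equal(ad$stages_used[length(ad$stages_used)], 600L)
  # in global mode the score bound may certify at an earlier stage, but an
  # accepted score is optimal by construction
  adg <- align_adaptive(a, half, error_set(3), mode = "global")
  expect_equal(adg$result$score, full_dp_align(a, half)$score)
})

test_that("adaptive final score dominates any single-stage banded score", {
  set.seed(51)
  prof <- error_set(1)
  for (k in 1:5) {
    p <- make_pair(400, prof)
    ad <- align_adaptive(p$seq_a, p$seq_b, prof)
    for (w in c(3L, 10L, 25L)) {
      b <- banded_dp_align(p$seq_a, p$seq_b, mode = "semiglobal", band = w)
      expect_gte(ad$result$score, b$score)
    }
  }
})
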