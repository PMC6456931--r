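test_that("k-mer match probability inside an overlap follows the two-error model", {
  expect_identical(match_probability(0, 15), 1)
  expect_equal(match_probability(0.15, 1), 0.85^2 + 0.15^2 / 3)
  expect_equal(match_probability(0.15, 1), 0.73)
  expect_equal(match_probability(0.15, 15), 0.73^15)
  expect_equal(match_probability(0.15, 15), 8.91e-3, tolerance = 5e-3)
  expect_error(match_probability(1.2, 9))
  expect_error(match_probability(0.1, 0))
})

test_that("expected random and in-overlap hit counts follow the positional model", {
  expect_identical(expected_random_hits(0, 0, 15), 0)
  expect_equal(expected_random_hits(1, 1, 1), 0.25)
  expect_equal(expected_random_hits(2000, 2000, 15), 4e6 / 4^15)
  # asymmetric lengths
  expect_equal(expected_random_hits(1000, 3000, 15), 3e6 / 4^15)
  expect_equal(
    expected_overlap_hits(500, 2000, 2000, 0.15, 15),
    0.73^15 * 500 + 4e6 / 4^15)
  expect_equal(expected_overlap_hits(500, 2000, 2000, 0.15, 15), 4.46,
               tolerance = 1e-3)
  # error-free overlap: every aligned k-mer position matches
  expect_equal(expected_overlap_hits(300, 1000, 1000, 0, 15),
               300 + expected_random_hits(1000, 1000, 15))
  expect_error(expected_overlap_hits(3000, 2000, 2000, 0.15, 15))
})

test_that("zero overlap reduces the in-overlap expectation to the random one", {
  for (len in c(500, 2000, 9000)) {
    for (k in c(9, 11, 15)) {
      for (eps in c(0, 0.1, 0.2)) {
        expect_identical(expected_overlap_hits(0, len, len, eps, k),
                         expected_random_hits(len, len, k))
      }
    }
  }
})

test_that("waiting-time distribution matches the run-length model", {
  wt <- waiting_time_distribution(0.85, 9, 400)
  expect_true(all(wt$mass[wt$x < 9] == 0))
  expect_equal(wt$mass[wt$x == 9], 0.85^9)
  expect_equal(wt$mass[wt$x == 9], 0.23162, tolerance = 1e-4)
  # degenerate: p = 1 puts all mass at x = k
  wt1 <- waiting_time_distribution(1, 9, 50)
  expect_equal(wt1$mass[wt1$x == 9], 1)
  expect_equal(sum(wt1$mass), 1)
  expect_error(waiting_time_distribution(0.85, 9, 5))
  # exact law: agrees with the absorbing Markov chain over run lengths
  p <- 0.7; k <- 4
  M <- matrix(0, k + 1, k + 1)
  for (s in 0:(k - 1)) { M[s + 1, 1] <- 1 - p; M[s + 1, s + 2] <- p }
  M[k + 1, k + 1] <- 1
  v <- c(1, rep(0, k))
  cum_mc <- numeric(100)
  for (t in 1:100) { v <- v %*% M; cum_mc[t] <- v[k + 1] }
  wt2 <- waiting_time_distribution(p, k, 100)
  expect_equal(cumsum(wt2$mass)[-1], cum_mc, tolerance = 1e-12)
})

test_that("waiting-time cumulative mass is monotone, bounded, and complete", {
  for (p in c(0.7, 0.85, 0.95)) {
    for (k in c(5, 9)) {
      wt <- waiting_time_distribution(p, k, 5000)
      cum <- cumsum(wt$mass)
      expect_true(all(diff(cum) >= 0))
      expect_true(all(cum <= 1 + 1e-9))
      expect_gt(max(cum), 1 - 1e-6)
    }
  }
})

test_that("rho calibration reproduces the strict-bound convention", {
  expect_identical(solve_rho(0.85, 9, 0.05), 54L)
  # degenerate p = 1: all mass at k, strict bound is the next integer
  expect_identical(solve_rho(1, 9, 0.05), 10L)
  # geometric case k = 1, p = 0.5 against a Monte-Carlo oracle:
  # empirical strict bound = smallest r with P[W <= r - 1] >= 0.95
  set.seed(11)
  w <- groupseed:::sample_run_waits_cpp(0.5, 1L, 1000000L)
  emp <- which(cumsum(tabulate(w, nbins = 64)) / length(w) >= 0.95)[1] + 1L
  expect_identical(solve_rho(0.5, 1, 0.05), as.integer(emp))
  expect_identical(solve_rho(0.5, 1, 0.05), 6L)  # 1 - 2^-5 = 0.969 >= 0.95
  expect_error(solve_rho(0.01, 9, 0.05, max_support = 10000L))
})

test_that("rho is monotone in p, k and alpha", {
  rho_p <- vapply(c(0.7, 0.8, 0.9, 0.99), function(p) solve_rho(p, 9), 0L)
  expect_true(all(diff(rho_p) <= 0))
  rho_k <- vapply(c(5, 7, 9, 11), function(k) solve_rho(0.85, k), 0L)
  expect_true(all(diff(rho_k) >= 0))
  rho_a <- vapply(c(0.01, 0.05, 0.1, 0.2),
                  function(a) solve_rho(0.85, 9, a), 0L)
  expect_true(all(diff(rho_a) <= 0))
})

test_that("diagonal-shift distribution is the lazy random walk law", {
  d0 <- diagonal_shift_distribution(0, 10)
  expect_equal(d0$mass[d0$shift == 0], 1)
  d1 <- diagonal_shift_distribution(0.06, 1)
  expect_equal(d1$mass, c(0.06, 0.88, 0.06))
  d2 <- diagonal_shift_distribution(0.06, 2)
  expect_equal(d2$mass[d2$shift == 0], 0.88^2 + 2 * 0.06^2)
  expect_equal(d2$mass[d2$shift == 1], 2 * 0.88 * 0.06)
  expect_equal(d2$mass[d2$shift == -2], 0.06^2)
  expect_error(diagonal_shift_distribution(0.5, 10))
  # symmetry, normalization, mode at zero
  for (q in c(0.01, 0.2)) {
    d <- diagonal_shift_distribution(q, 33)
    expect_equal(d$mass, rev(d$mass))
    expect_equal(sum(d$mass), 1, tolerance = 1e-12)
    expect_true(all(d$mass[d$shift == 0] >= d$mass))
  }
})

test_that("closed-form diagonal shift equals the convolution", {
  for (q in c(0.01, 0.06, 0.2)) {
    for (l in c(1, 5, 20, 54, 60)) {
      conv <- diagonal_shift_distribution(q, l)
      closed <- diagonal_shift_distribution(q, l, method = "closed")
      expect_equal(closed$mass, conv$mass, tolerance = 1e-12)
    }
  }
})

test_that("delta calibration accumulates shifts to the confidence level", {
  expect_identical(solve_delta(0.06, 54, 0.05), 5L)
  expect_identical(solve_delta(0, 54, 0.05), 0L)
  expect_identical(solve_delta(0, 7, 0.2), 0L)
  # independent cumulative from the polynomial-multiplication oracle
  mass <- oracle_walk_mass(0.06, 20)
  shifts <- -20:20
  cum <- vapply(0:20, function(d) sum(mass[abs(shifts) <= d]), 0)
  expect_identical(solve_delta(0.06, 20, 0.05),
                   as.integer(which(cum >= 0.95)[1] - 1))
})

test_that("delta is monotone in q and l", {
  d_q <- vapply(c(0.01, 0.06, 0.12, 0.2), function(q) solve_delta(q, 54), 0L)
  expect_true(all(diff(d_q) >= 0))
  d_l <- vapply(c(10, 30, 54, 100), function(l) solve_delta(0.06, l), 0L)
  expect_true(all(diff(d_l) >= 0))
})

test_that("filter threshold recommendation separates noise from signal", {
  # long-read profile: random 15-mer hits are rare even for the longest pair
  set.seed(5)
  long_lengths <- pmin(pmax(round(rnorm(2000, 8000, 2500)), 500), 30000)
  t_long <- recommend_filter_threshold(long_lengths)
  expect_identical(as.integer(t_long), 2L)
  expect_false(attr(t_long, "low_confidence"))
  # short-read profile (mean ~1700): shorter k, higher random expectation
  short_lengths <- round(qnorm(ppoints(3000), 1696, 420))
  t_short <- recommend_filter_threshold(short_lengths, k_filter = 11,
                                        epsilon = 0.1414)
  expect_identical(as.integer(t_short), 3L)
  # error-free, huge overlap: threshold floor stays at 2
  t_floor <- recommend_filter_threshold(rep(2000, 10), epsilon = 0,
                                        overlap_fraction = 1)
  expect_identical(as.integer(t_floor), 2L)
  expect_true(attr(t_floor, "expected_overlap") >= 2)
  # impossible separation warns and falls back
  expect_warning(
    t_bad <- recommend_filter_threshold(rep(50000, 5), k_filter = 9,
                                        epsilon = 0.45,
                                        overlap_fraction = 0.01,
                                        length_floor = 0),
    "low confidence")
  expect_identical(as.integer(t_bad), 2L)
  expect_true(attr(t_bad, "low_confidence"))
})

test_that("calibration report round-trips as key=value text", {
  cal <- calibrate()
  expect_identical(cal$rho, 54L)
  expect_identical(cal$delta, 5L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, path)
  kv <- strsplit(readLines(path), "=")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  expect_identical(as.integer(vals[["rho"]]), 54L)
  expect_identical(as.integer(vals[["delta"]]), 5L)
  expect_identical(as.integer(vals[["filter_threshold"]]), 2L)
})

test_that("error model validates its parameter ranges", {
  em <- error_model()
  expect_s3_class(em, "error_model")
  expect_error(error_model(epsilon = 1))
  expect_error(error_model(q = 0.5))
  expect_error(error_model(alpha = 0))
  expect_error(error_model(alphabet_size = 1))
})
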