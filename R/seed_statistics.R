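#' Error model for read-vs-read comparison
#'
#' Bundles the statistical parameters that drive seed calibration and the
#' filtration analysis: `epsilon`, the per-base sequencing error rate of a
#' single read; `p`, the per-base match probability along the implied
#' alignment of two overlapping reads; `q`, the per-base indel probability
#' in a read-vs-read comparison (insertions and deletions are
#' interchangeable when comparing two reads, so a single rate is used);
#' `alpha`, the significance level for threshold calibration; and the
#' alphabet size (4 for DNA).
#'
#' Defaults follow typical uncorrected PacBio-like data: `p = 0.85`,
#' `q = 0.06`, `alpha = 0.05`, `epsilon = 0.15`. `p` is deliberately a free
#' parameter and is not derived from `epsilon`.
#'
#' @param epsilon Per-base read error rate in `[0, 1)`.
#' @param p Per-base match probability in `(0, 1]`.
#' @param q Per-base indel probability in `[0, 0.5)` (the stay probability
#'   `1 - 2q` must be positive).
#' @param alpha Significance level in `(0, 1)`.
#' @param alphabet_size Alphabet size, at least 2.
#' @return An object of class `error_model`.
#' @export
error_model <- function(epsilon = 0.15, p = 0.85, q = 0.06, alpha = 0.05,
                        alphabet_size = 4) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1,
            epsilon >= 0, epsilon < 1)
  stopifnot(is.numeric(p), length(p) == 1, p > 0, p <= 1)
  stopifnot(is.numeric(q), length(q) == 1, q >= 0, q < 0.5)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  stopifnot(alphabet_size >= 2)
  structure(list(epsilon = epsilon, p = p, q = q, alpha = alpha,
                 alphabet_size = as.integer(alphabet_size)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Error model: epsilon =", x$epsilon, " p =", x$p, " q =", x$q,
      " alpha =", x$alpha, " |Sigma| =", x$alphabet_size, "\n")
  invisible(x)
}

#' Probability that a k-mer matches at an aligned position inside an overlap
#'
#' A position aligned between two overlapping reads carries the same base
#' either when both reads are correct, probability `(1 - epsilon)^2`, or
#' when both are errors substituted by the same character, probability
#' `epsilon^2 / (alphabet_size - 1)`. A k-mer match requires k such
#' positions in a row, so
#' `P_o = ((1 - epsilon)^2 + epsilon^2 / (|Sigma| - 1))^k`.
#'
#' @param epsilon Per-base read error rate in `[0, 1)`.
#' @param k k-mer length, at least 1.
#' @param alphabet_size Alphabet size (default 4).
#' @return The match probability, a number in `(0, 1]`.
#' @examples
#' match_probability(0, 15)      # error-free reads always match: 1
#' match_probability(0.15, 1)    # 0.85^2 + 0.15^2/3 = 0.73
#' @export
match_probability <- function(epsilon, k, alphabet_size = 4) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1,
            epsilon >= 0, epsilon < 1)
  stopifnot(k >= 1, alphabet_size >= 2)
  ((1 - epsilon)^2 + epsilon^2 / (alphabet_size - 1))^k
}

#' Expected number of positional k-mer hits between two unrelated reads
#'
#' Hits are counted by position pair, not by distinct k-mer, so each of the
#' roughly `len_a * len_b` position pairs matches independently with
#' probability `(1/|Sigma|)^k`:
#' `E[X_r] = (1/|Sigma|)^k * len_a * len_b`.
#'
#' @param len_a,len_b Read lengths (non-negative).
#' @param k k-mer length.
#' @param alphabet_size Alphabet size (default 4).
#' @return Expected hit count.
#' @examples
#' expected_random_hits(2000, 2000, 15)  # ~3.7e-3
#' @export
expected_random_hits <- function(len_a, len_b, k, alphabet_size = 4) {
  stopifnot(len_a >= 0, len_b >= 0, k >= 1, alphabet_size >= 2)
  (1 / alphabet_size)^k * len_a * len_b
}

#' Expected number of positional k-mer hits between two overlapping reads
#'
#' Signal plus noise: `E[X_o] = P_o * M + (1/|Sigma|)^k * len_a * len_b`,
#' where `M` is the overlap size and `P_o` is [match_probability()]. This
#' slightly over-counts because a random hit inside the overlap can
#' coincide with an aligned-position hit (probability
#' `P_o * (1/|Sigma|)^k`, negligible for the k used in filtration).
#'
#' @param overlap_size Overlap length `M`, with
#'   `0 <= overlap_size <= min(len_a, len_b)`.
#' @param len_a,len_b Read lengths.
#' @param epsilon Per-base read error rate.
#' @param k k-mer length.
#' @param alphabet_size Alphabet size (default 4).
#' @return Expected hit count.
#' @export
expected_overlap_hits <- function(overlap_size, len_a, len_b, epsilon, k,
                                  alphabet_size = 4) {
  stopifnot(overlap_size >= 0)
  if (overlap_size > min(len_a, len_b))
    stop("overlap_size exceeds a read length")
  match_probability(epsilon, k, alphabet_size) * overlap_size +
    expected_random_hits(len_a, len_b, k, alphabet_size)
}

#' Waiting-time distribution of the inter-seed distance
#'
#' Models k-mer matches along the alignment of two overlapping reads as
#' runs of k successes in Bernoulli(p) trials. The distance `D_k` to the
#' completion of the next k-run has mass 0 for `x < k`, `p^k` at `x = k`,
#' and for `x > k` the recursion
#' `P[D_k = x] = (1 - p) p^k (1 - sum_{i <= x-k-1} P[D_k = i])`:
#' a failure at position `x - k`, a fresh k-run ending at `x`, and no
#' earlier completed run. This recursion is the exact law of the first
#' k-run completion time (it matches the absorbing Markov chain over run
#' lengths to machine precision).
#'
#' @param p Per-base match probability in `(0, 1]`.
#' @param k Seed length, at least 1.
#' @param support_bound Largest distance tabulated (at least `k`).
#' @return An object of class `waiting_time_distribution` with fields `p`,
#'   `k`, `x` (0..support_bound) and `mass`.
#' @export
waiting_time_distribution <- function(p, k, support_bound) {
  stopifnot(p > 0, p <= 1, k >= 1)
  if (support_bound < k) stop("support_bound must be at least k")
  k <- as.integer(k)
  support_bound <- as.integer(support_bound)
  mass <- numeric(support_bound + 1)    # index x + 1
  mass[k + 1] <- p^k
  if (support_bound > k) {
    tail_coef <- (1 - p) * p^k
    cum <- numeric(support_bound + 1)
    cum[seq_len(k + 1)] <- c(rep(0, k), p^k)
    for (x in (k + 1):support_bound) {
      excluded <- cum[x - k]            # sum of mass over 0..x-k-1
      mass[x + 1] <- tail_coef * (1 - excluded)
      cum[x + 1] <- cum[x] + mass[x + 1]
    }
  }
  structure(list(p = p, k = k, x = 0:support_bound, mass = mass),
            class = "waiting_time_distribution")
}

#' @export
print.waiting_time_distribution <- function(x, ...) {
  cat("Waiting-time distribution: p =", x$p, " k =", x$k,
      " support 0..", max(x$x), " total mass ", sum(x$mass), "\n", sep = "")
  invisible(x)
}

#' Calibrate the maximum inter-seed distance rho
#'
#' Returns the smallest integer bound `rho` such that the inter-seed
#' distance falls strictly below it with probability at least `1 - alpha`,
#' i.e. `P[D_k < rho] >= 1 - alpha` under [waiting_time_distribution()].
#' The bound is exclusive-strict: calibration guarantees "distance less
#' than rho" at confidence `1 - alpha` (at `p = 0.85`, `k = 9`,
#' `alpha = 0.05` this gives `rho = 54`; the inclusive reading would give
#' 53 because the cumulative sits within 4e-4 of the level there, and for
#' a degenerate `p = 1` it gives `k + 1`). Seed grouping itself applies
#' `D <= rho`, so the strict bound is the more permissive, sensitivity-
#' preserving choice.
#'
#' @param p Per-base match probability.
#' @param k Seed length.
#' @param alpha Significance level (default 0.05).
#' @param max_support Safety cap on the tabulated support; calibration
#'   fails if the cumulative cannot reach `1 - alpha` within it (p far too
#'   small for k).
#' @return Integer threshold `rho >= k`.
#' @export
solve_rho <- function(p, k, alpha = 0.05, max_support = 1000000L) {
  stopifnot(p > 0, p <= 1, k >= 1, alpha > 0, alpha < 1)
  mean_wait <- (1 - p^k) / max((1 - p) * p^k, 1e-300)
  support <- as.integer(min(max(4 * mean_wait, 2 * k), max_support))
  repeat {
    wt <- waiting_time_distribution(p, k, support)
    cum <- cumsum(wt$mass)
    hit <- which(cum >= 1 - alpha)
    if (length(hit) > 0) return(as.integer(hit[1]))  # x + 1: strict bound
    if (support >= max_support)
      stop("cumulative waiting-time mass cannot reach 1 - alpha within ",
           max_support, " positions; p is too small for this k")
    support <- as.integer(min(4 * as.numeric(support), max_support))
  }
}

#' Exact distribution of the diagonal shift after l random-walk steps
#'
#' Cumulative indel drift between two overlapping reads is a lazy
#' one-dimensional random walk: at each of `l` aligned positions the
#' diagonal moves +1 (insertion) with probability `q`, -1 (deletion) with
#' probability `q`, and stays with probability `1 - 2q`. The reference
#' implementation is the `l`-fold convolution of the single-step
#' distribution; `method = "closed"` evaluates the equivalent closed form
#' `P[i, l] = sum_{n_d} C(l, i + 2 n_d) C(i + 2 n_d, i + n_d)
#' q^{2 n_d + i} (1 - 2q)^{l - i - 2 n_d}` in log-space (binomial
#' coefficients overflow ordinary doubles well before `l = 60`).
#'
#' @param q Per-base indel probability in `[0, 0.5)`.
#' @param l Number of steps (non-negative integer).
#' @param method `"convolution"` (reference) or `"closed"`.
#' @return An object of class `diagonal_shift_distribution` with fields
#'   `q`, `l`, `shift` (-l..l) and `mass`.
#' @export
diagonal_shift_distribution <- function(q, l,
                                        method = c("convolution", "closed")) {
  method <- match.arg(method)
  stopifnot(q >= 0, l >= 0)
  if (q >= 0.5) stop("q must be below 0.5")
  l <- as.integer(l)
  if (l == 0L) {
    mass <- 1
  } else if (method == "convolution") {
    v <- 1
    for (s in seq_len(l)) {
      n <- length(v)
      nv <- numeric(n + 2)
      nv[1:n] <- nv[1:n] + v * q
      nv[2:(n + 1)] <- nv[2:(n + 1)] + v * (1 - 2 * q)
      nv[3:(n + 2)] <- nv[3:(n + 2)] + v * q
      v <- nv
    }
    mass <- v
  } else {
    half <- vapply(0:l, function(i) .diag_shift_closed_one(q, l, i), 0)
    mass <- c(rev(half[-1]), half)
  }
  structure(list(q = q, l = l, shift = (-l):l, mass = mass),
            class = "diagonal_shift_distribution")
}

# Closed-form P[i, l] for i >= 0, log-space sum over the deletion count.
.diag_shift_closed_one <- function(q, l, i) {
  if (q == 0) return(as.numeric(i == 0))
  nd <- 0:((l - i) %/% 2)
  terms <- lchoose(l, i + 2 * nd) + lchoose(i + 2 * nd, i + nd) +
    (2 * nd + i) * log(q) + (l - i - 2 * nd) * log(1 - 2 * q)
  sum(exp(terms))
}

#' @export
print.diagonal_shift_distribution <- function(x, ...) {
  cat("Diagonal-shift distribution: q =", x$q, " l =", x$l,
      " total mass ", sum(x$mass), "\n", sep = "")
  invisible(x)
}

#' Calibrate the maximum diagonal shift delta
#'
#' Accumulates the diagonal-shift mass over `i = 0, +/-1, +/-2, ...` and
#' returns the smallest `delta` with
#' `sum_{|i| <= delta} P[i, l] >= 1 - alpha`. The number of steps `l` is
#' typically set to the calibrated `rho`, the largest inter-seed distance
#' tolerated within a group.
#'
#' @param q Per-base indel probability.
#' @param l Number of random-walk steps.
#' @param alpha Significance level (default 0.05).
#' @return Integer threshold `delta` in `0..l`.
#' @export
solve_delta <- function(q, l, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  d <- diagonal_shift_distribution(q, l)
  cum <- cumsum(c(d$mass[d$shift == 0],
                  2 * d$mass[d$shift > 0][order(d$shift[d$shift > 0])]))
  as.integer(which(cum >= 1 - alpha)[1] - 1L)
}

#' Group-seed criteria: k, rho, delta
#'
#' Calibrates both grouping thresholds from the error model: `rho` from
#' the waiting-time model via [solve_rho()] and `delta` from the
#' random-walk model via [solve_delta()] with `l = rho`.
#'
#' @param p Per-base match probability (default 0.85).
#' @param q Per-base indel probability (default 0.06).
#' @param alpha Significance level (default 0.05).
#' @param k Group-seed k-mer length (default 9).
#' @return An object of class `group_criteria` with fields `k`, `rho`,
#'   `delta` (plus the inputs).
#' @examples
#' group_criteria()  # k = 9, rho = 54, delta = 5
#' @export
group_criteria <- function(p = 0.85, q = 0.06, alpha = 0.05, k = 9) {
  rho <- solve_rho(p, k, alpha)
  delta <- solve_delta(q, rho, alpha)
  structure(list(k = as.integer(k), rho = rho, delta = delta,
                 p = p, q = q, alpha = alpha),
            class = "group_criteria")
}

#' @export
print.group_criteria <- function(x, ...) {
  cat("Group criteria: k =", x$k, " rho =", x$rho, " delta =", x$delta,
      " (p =", x$p, ", q =", x$q, ", alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Recommend a shared-k-mer count threshold for filtration
#'
#' Picks the smallest integer count that is above the random-hit
#' expectation for the longest read pair yet still at or below the
#' expected in-overlap hit count for the shortest read considered, with
#' the overlap set to `overlap_fraction` of that read's length (the
#' hard small-overlap regime). Reads shorter than `length_floor` are
#' excluded from the "shortest considered" side when longer reads exist;
#' the floor matches the usual practice of ignoring very short long-read
#' sequencing artifacts. The returned threshold is never below 2. When no
#' integer separates noise from signal the function warns, returns 2, and
#' flags the result with `attr(, "low_confidence")`.
#'
#' @param read_lengths Non-empty numeric vector of read lengths.
#' @param k_filter Filtration k-mer length (default 15).
#' @param epsilon Per-base read error rate (default 0.15).
#' @param overlap_fraction Overlap size as a fraction of the shortest
#'   considered read (default 0.25).
#' @param alphabet_size Alphabet size (default 4).
#' @param length_floor Shortest read length considered for the signal side
#'   (default 2000).
#' @return Integer threshold (>= 2) with attributes `expected_random`,
#'   `expected_overlap` and `low_confidence`.
#' @export
recommend_filter_threshold <- function(read_lengths, k_filter = 15,
                                       epsilon = 0.15,
                                       overlap_fraction = 0.25,
                                       alphabet_size = 4,
                                       length_floor = 2000) {
  stopifnot(length(read_lengths) > 0, all(read_lengths > 0))
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  l_max <- max(read_lengths)
  considered <- read_lengths[read_lengths >= length_floor]
  l_min <- if (length(considered) > 0) min(considered) else min(read_lengths)
  e_r <- expected_random_hits(l_max, l_max, k_filter, alphabet_size)
  e_o <- expected_overlap_hits(overlap_fraction * l_min, l_min, l_min,
                               epsilon, k_filter, alphabet_size)
  t <- max(floor(e_r) + 1, 2)
  low_confidence <- FALSE
  if (t > e_o) {
    warning("no k-mer count threshold separates random from in-overlap ",
            "expectations (E[random] = ", signif(e_r, 3), ", E[overlap] = ",
            signif(e_o, 3), "); falling back to 2 with low confidence")
    t <- 2
    low_confidence <- TRUE
  }
  structure(as.integer(t), expected_random = e_r, expected_overlap = e_o,
            low_confidence = low_confidence)
}

#' Calibrate all seeding parameters and summarize them
#'
#' One-stop calibration: group criteria (`rho`, `delta`) from the error
#' model and, when read lengths are supplied, a filtration threshold
#' recommendation.
#'
#' @param p,q,alpha,k See [group_criteria()].
#' @param filter_k Filtration k-mer length (default 15).
#' @param read_lengths Optional read lengths for
#'   [recommend_filter_threshold()]; without them the stock threshold 2 is
#'   reported.
#' @param epsilon Per-base error rate used for the filtration analysis.
#' @return An object of class `calibration` (a named list with fields
#'   `k`, `p`, `q`, `alpha`, `rho`, `delta`, `filter_k`,
#'   `filter_threshold`).
#' @export
calibrate <- function(p = 0.85, q = 0.06, alpha = 0.05, k = 9,
                      filter_k = 15, read_lengths = NULL, epsilon = 0.15) {
  gc <- group_criteria(p = p, q = q, alpha = alpha, k = k)
  threshold <- if (is.null(read_lengths)) 2L else
    as.integer(recommend_filter_threshold(read_lengths, k_filter = filter_k,
                                          epsilon = epsilon))
  structure(list(k = gc$k, p = p, q = q, alpha = alpha,
                 rho = gc$rho, delta = gc$delta,
                 filter_k = as.integer(filter_k),
                 filter_threshold = threshold),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  for (f in names(unclass(x))) cat(f, "=", x[[f]], "\n")
  invisible(x)
}

#' Write a calibration report as key=value text
#'
#' @param x A `calibration` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "calibration"))
  writeLines(paste0(names(unclass(x)), "=",
                    vapply(unclass(x), format, "", scientific = FALSE)), path)
  invisible(path)
}
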