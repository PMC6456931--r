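#' Chain group seeds by sparse dynamic programming
#'
#' Finds the chain of group seeds maximizing the total matched bases under
#' strict precedence: a group may follow another only when its spans start
#' at or after the predecessor's spans end, on both reads. There is no gap
#' penalty. Ties are broken deterministically (earliest `a_start`, then
#' `b_start`).
#'
#' @param groups A [group_summary()] table (at least one row).
#' @return An object of class `seed_chain`: list with `groups` (the
#'   chained rows, in chain order) and `score` (total matched bases).
#' @export
chain_groups <- function(groups) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1)
  sel <- chain_groups_cpp(as.integer(groups$a_start),
                          as.integer(groups$a_end),
                          as.integer(groups$b_start),
                          as.integer(groups$b_end),
                          as.numeric(groups$matched_bases))
  chained <- groups[sel, , drop = FALSE]
  rownames(chained) <- NULL
  structure(list(groups = chained, score = sum(chained$matched_bases)),
            class = "seed_chain")
}

#' @export
print.seed_chain <- function(x, ...) {
  cat("Seed chain:", nrow(x$groups), "groups, score", x$score,
      " a:[", min(x$groups$a_start), ",", max(x$groups$a_end),
      ") b:[", min(x$groups$b_start), ",", max(x$groups$b_end), ")\n")
  invisible(x)
}

#' Trim a chain to its collinear core
#'
#' An optimal chain occasionally picks up a far-off-diagonal group at an
#' end, which inflates the estimated overlap. This keeps the contiguous
#' sub-chain with the highest retained score whose representative
#' diagonals all lie within a band of half-width
#' `delta + ceiling(q * span)` around the sub-chain's median diagonal
#' (`delta` bounds local indel drift between neighboring seeds; `q * span`
#' bounds cumulative drift across the sub-chain's read-1 extent). A
#' single-group window is always valid, so the result is never empty, and
#' trimming can only shrink the chain's extent.
#'
#' @param chain A [chain_groups()] result.
#' @param delta Calibrated diagonal-shift bound.
#' @param q Per-base indel probability.
#' @return A `seed_chain` restricted to the retained groups.
#' @export
trim_collinear <- function(chain, delta, q) {
  stopifnot(inherits(chain, "seed_chain"), nrow(chain$groups) >= 1)
  g <- chain$groups
  st <- trim_collinear_cpp(as.numeric(g$diag_med), as.integer(g$a_start),
                           as.integer(g$a_end),
                           as.numeric(g$matched_bases),
                           as.numeric(delta), as.numeric(q))
  kept <- g[st[1]:st[2], , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(groups = kept, score = sum(kept$matched_bases)),
            class = "seed_chain")
}

#' Estimate the overlap region implied by a chain
#'
#' Extends the chain's bounding box to the read ends along the alignment
#' direction (slope one): each side is extended by the smaller of the two
#' remaining read margins, which clips the extension at whichever read
#' boundary is hit first. The estimated overlap length `L_O` is the
#' extended span on read 1.
#'
#' @param chain A (preferably trimmed) `seed_chain`.
#' @param len_a,len_b Read lengths.
#' @return A list with `a_start`, `a_end`, `b_start`, `b_end` (0-based,
#'   half-open, within read bounds) and `l_o`.
#' @export
estimate_overlap_region <- function(chain, len_a, len_b) {
  stopifnot(inherits(chain, "seed_chain"), nrow(chain$groups) >= 1)
  g <- chain$groups
  a0 <- min(g$a_start); a1 <- max(g$a_end)
  b0 <- min(g$b_start); b1 <- max(g$b_end)
  stopifnot(a1 <= len_a, b1 <= len_b)
  ext_left <- min(a0, b0)
  ext_right <- min(len_a - a1, len_b - b1)
  list(a_start = a0 - ext_left, a_end = a1 + ext_right,
       b_start = b0 - ext_left, b_end = b1 + ext_right,
       l_o = (a1 + ext_right) - (a0 - ext_left))
}

#' Expected matched bases required to accept a chain
#'
#' `n_e = (1 / c) * (L_O / rho) * k`: over an overlap of length `L_O` one
#' group seed is expected roughly every `rho` bases, each contributing at
#' least `k` matched bases; `c` relaxes the requirement (larger `c`, more
#' sensitive, less precise).
#'
#' @param l_o Estimated overlap length.
#' @param c Acceptance coefficient (> 0, default 2).
#' @param rho Calibrated inter-seed distance bound.
#' @param k_group Seed length (default 9).
#' @return The expected matched-bases threshold.
#' @export
expected_chain_bases <- function(l_o, c = 2, rho, k_group = 9) {
  if (c <= 0) stop("c must be positive")
  stopifnot(rho >= k_group)
  (1 / c) * (l_o / rho) * k_group
}

#' Accept or reject a chained overlap
#'
#' Two rules: (1) the chain's matched bases `n` must reach the expectation
#' `n_e` from [expected_chain_bases()]; (2) the chained region must cover
#' similar extents on both reads:
#' `|span_a - span_b| <= size_similarity_tau * max(span_a, span_b)`.
#'
#' @param chain A (trimmed) `seed_chain`.
#' @param l_o Estimated overlap length from [estimate_overlap_region()].
#' @param c Acceptance coefficient (default 2).
#' @param rho Calibrated inter-seed distance bound.
#' @param k_group Seed length (default 9).
#' @param size_similarity_tau Relative span-difference tolerance
#'   (default 0.3).
#' @return A list with `accepted`, `n_matched`, `n_e`, and `reason`
#'   (`"ok"`, `"below_n_e"` or `"size_dissimilar"`).
#' @export
decide_overlap <- function(chain, l_o, c = 2, rho, k_group = 9,
                           size_similarity_tau = 0.3) {
  stopifnot(inherits(chain, "seed_chain"))
  n_e <- expected_chain_bases(l_o, c, rho, k_group)
  n <- chain$score
  g <- chain$groups
  span_a <- max(g$a_end) - min(g$a_start)
  span_b <- max(g$b_end) - min(g$b_start)
  size_ok <- abs(span_a - span_b) <=
    size_similarity_tau * max(span_a, span_b)
  reason <- if (n < n_e) "below_n_e" else if (!size_ok) "size_dissimilar"
            else "ok"
  list(accepted = n >= n_e && size_ok, n_matched = n, n_e = n_e,
       reason = reason)
}
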