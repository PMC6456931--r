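#' Enumerate exact k-mer hits between two sequences
#'
#' Every position pair `(i, j)` (0-based) with
#' `seq_a[i..i+k-1] == seq_b[j..j+k-1]` is reported; windows containing
#' non-ACGT characters never match. Equivalent to a brute-force double
#' loop, implemented with a hash index over `seq_a`.
#'
#' @param seq_a,seq_b Nucleotide strings (uppercase).
#' @param k_group Seed length (default 9).
#' @return A data frame with columns `i`, `j` (0-based start positions),
#'   sorted by `(i, j)`, with the seed length in `attr(, "k")`.
#' @export
enumerate_hits <- function(seq_a, seq_b, k_group = 9) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            nchar(seq_a) > 0, nchar(seq_b) > 0, k_group >= 1, k_group <= 31)
  m <- enumerate_hits_cpp(seq_a, seq_b, as.integer(k_group))
  structure(data.frame(i = m[, 1], j = m[, 2]), k = as.integer(k_group))
}

#' Cluster k-mer hits into group seeds
#'
#' Two hits belong together when their inter-seed distance
#' `D = max(|i2 - i1|, |j2 - j1|)` is at most `rho` and their diagonal
#' shift `|(j2 - i2) - (j1 - i1)|` is at most `delta`; membership is
#' closed transitively, so groups are the connected components of the
#' constraint graph (single linkage). The result does not depend on the
#' input order of the hits. Duplicate hits are dropped defensively.
#'
#' @param hits Data frame with 0-based columns `i`, `j` (e.g. from
#'   [enumerate_hits()]).
#' @param rho Maximum inter-seed distance.
#' @param delta Maximum diagonal-shift magnitude.
#' @param k Seed length; taken from `attr(hits, "k")` when absent.
#' @return An object of class `seed_groups`: the hit table with a `group`
#'   label column, plus `k`, `rho`, `delta` attributes. Use
#'   [group_summary()] for per-group geometry.
#' @export
group_hits <- function(hits, rho, delta, k = attr(hits, "k")) {
  stopifnot(!is.null(k), rho >= k, delta >= 0)
  hits <- unique(hits[, c("i", "j")])
  if (nrow(hits) == 0) {
    out <- data.frame(i = integer(), j = integer(), group = integer())
  } else {
    lab <- group_hits_cpp(as.integer(hits$i), as.integer(hits$j),
                          as.integer(rho), as.integer(delta))
    out <- data.frame(i = hits$i, j = hits$j, group = lab)
    out <- out[order(out$group, out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, k = as.integer(k), rho = as.integer(rho),
            delta = as.integer(delta), class = c("seed_groups", "data.frame"))
}

#' Matched bases covered by a set of k-mer start positions
#'
#' The number of distinct read-1 positions covered by the union of the
#' intervals `[i, i + k)`; overlapping seeds are not double-counted.
#' Read 1 is the fixed reference side for scoring (the read-2 union can
#' differ by indels).
#'
#' @param i_positions Integer vector of 0-based k-mer start positions.
#' @param k Seed length.
#' @return Integer count (>= k for a non-empty group).
#' @export
group_matched_bases <- function(i_positions, k) {
  stopifnot(length(i_positions) > 0, k >= 1)
  s <- sort(unique(as.integer(i_positions)))
  if (length(s) == 1) return(as.integer(k))
  gaps <- diff(s)
  as.integer(k + sum(pmin(gaps, k)))
}

#' Summarize seed groups
#'
#' Per-group geometry used by chaining: covered half-open spans on both
#' reads, matched bases (read-1 interval union), hit count, and the
#' diagonal range plus the representative (median) diagonal.
#'
#' @param groups A [group_hits()] result.
#' @return A data frame with one row per group: `group`, `hit_count`,
#'   `a_start`, `a_end`, `b_start`, `b_end`, `matched_bases`, `diag_min`,
#'   `diag_max`, `diag_med`.
#' @export
group_summary <- function(groups) {
  stopifnot(inherits(groups, "seed_groups"))
  k <- attr(groups, "k")
  if (nrow(groups) == 0) {
    return(data.frame(group = integer(), hit_count = integer(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      matched_bases = integer(), diag_min = integer(),
                      diag_max = integer(), diag_med = numeric()))
  }
  parts <- split(seq_len(nrow(groups)), groups$group)
  rows <- lapply(parts, function(ix) {
    i <- groups$i[ix]; j <- groups$j[ix]
    d <- j - i
    mb <- group_matched_bases(i, k)
    stopifnot(mb >= k)  # impossible to cover fewer than k bases
    data.frame(group = groups$group[ix[1]], hit_count = length(ix),
               a_start = min(i), a_end = max(i) + k,
               b_start = min(j), b_end = max(j) + k,
               matched_bases = mb, diag_min = min(d), diag_max = max(d),
               diag_med = stats::median(d))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-pair group debug table as TSV
#'
#' @param summary A [group_summary()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
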