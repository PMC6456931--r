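# Independent brute-force oracles used across the suite. These mirror the
# definitions, not the implementations: hash joins over substrings, full
# pairwise closures, exhaustive chain enumeration, polynomial convolution.

oracle_random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# All k-mer start-position pairs shared by two sequences (brute force).
oracle_hits <- function(seq_a, seq_b, k) {
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na < k || nb < k) return(data.frame(i = integer(), j = integer()))
  ka <- substring(seq_a, 1:(na - k + 1), k:na)
  kb <- substring(seq_b, 1:(nb - k + 1), k:nb)
  ok_a <- !grepl("[^ACGT]", ka)
  ok_b <- !grepl("[^ACGT]", kb)
  out <- do.call(rbind, lapply(which(ok_a), function(i) {
    j <- which(kb == ka[i] & ok_b)
    if (length(j) == 0) NULL else data.frame(i = i - 1L, j = j - 1L)
  }))
  if (is.null(out)) data.frame(i = integer(), j = integer()) else
    out[order(out$i, out$j), , drop = FALSE]
}

oracle_shared_count <- function(seq_a, seq_b, k) nrow(oracle_hits(seq_a, seq_b, k))

# Positional shared k-mer counts for every oriented pair of a read set.
oracle_pair_counts <- function(ids, seqs, k) {
  n <- length(ids)
  rows <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      plus <- oracle_shared_count(seqs[a], seqs[b], k)
      minus <- oracle_shared_count(seqs[a], oracle_revcomp(seqs[b]), k)
      id_a <- min(ids[a], ids[b]); id_b <- max(ids[a], ids[b])
      if (plus > 0)
        rows[[length(rows) + 1]] <- data.frame(
          id_a = id_a, id_b = id_b, strand = "+", shared_kmers = plus)
      if (minus > 0)
        rows[[length(rows) + 1]] <- data.frame(
          id_a = id_a, id_b = id_b, strand = "-", shared_kmers = minus)
    }
  }
  if (length(rows) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      strand = character(), shared_kmers = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(out$id_a, out$id_b, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Transitive closure of the group criteria over all hit pairs (BFS on the
# full pairwise adjacency matrix).
oracle_group_labels <- function(i, j, rho, delta) {
  n <- length(i)
  if (n == 0) return(integer())
  D <- pmax(abs(outer(i, i, "-")), abs(outer(j, j, "-")))
  S <- abs(outer(j - i, j - i, "-"))
  adj <- D <= rho & S <= delta
  lab <- rep(NA_integer_, n)
  nxt <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    nxt <- nxt + 1L
    frontier <- s
    lab[s] <- nxt
    while (length(frontier) > 0) {
      reach <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & is.na(lab))
      lab[reach] <- nxt
      frontier <- reach
    }
  }
  lab
}

# Exhaustive maximum-score chain over all subsets of groups; a subset forms
# a chain iff, sorted by a_start, consecutive members satisfy strict
# precedence on both reads (pairwise comparability follows).
oracle_best_chain_score <- function(g) {
  n <- nrow(g)
  best <- 0
  for (mask in 1:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sel <- sel[order(g$a_start[sel], g$b_start[sel])]
    ok <- TRUE
    if (length(sel) > 1) {
      for (t in 2:length(sel)) {
        if (g$a_end[sel[t - 1]] > g$a_start[sel[t]] ||
            g$b_end[sel[t - 1]] > g$b_start[sel[t]]) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(g$matched_bases[sel]))
  }
  best
}

# l-step lazy random walk mass via polynomial multiplication (independent
# of the package's incremental convolution).
oracle_walk_mass <- function(q, l) {
  step <- c(q, 1 - 2 * q, q)
  mass <- 1
  for (s in seq_len(l)) {
    padded <- c(0, 0, mass, 0, 0)
    mass <- vapply(seq_len(length(mass) + 2), function(t)
      sum(padded[t:(t + 2)] * rev(step)), 0)
  }
  mass  # over shifts -l..l
}

# Random group geometries with plausible span/score structure.
oracle_random_groups <- function(n, coord_max = 1000, span_max = 60) {
  a0 <- sample.int(coord_max, n, replace = TRUE)
  b0 <- sample.int(coord_max, n, replace = TRUE)
  alen <- sample.int(span_max, n, replace = TRUE) + 8L
  blen <- pmax(9L, alen + sample(-5:5, n, replace = TRUE))
  data.frame(group = seq_len(n), hit_count = 1L,
             a_start = a0, a_end = a0 + alen,
             b_start = b0, b_end = b0 + blen,
             matched_bases = as.numeric(pmax(9L, alen - sample(0:5, n,
                                                               replace = TRUE))),
             diag_min = b0 - a0, diag_max = b0 - a0,
             diag_med = as.numeric(b0 - a0))
}
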