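#' Configuration for the synthetic long-read simulator
#'
#' Defaults emulate an uncorrected PacBio-like run over a small genome:
#' indel-dominated errors at 8.6% insertions, 4.4% deletions and 1.4%
#' substitutions (14.4% total), reads of mean length 8000 sampled to 10X
#' coverage from a 100 kb genome. Read lengths are truncated-normal
#' (floor 200) with standard deviation `length_sd`.
#'
#' @param genome_length Genome length in bases.
#' @param coverage Sequencing depth (fold).
#' @param mean_read_length,length_sd Read length distribution parameters.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities; their
#'   sum must stay below 1.
#' @param min_truth_overlap Smallest genomic intersection recorded as a
#'   true overlap (default 100 bases).
#' @param seed RNG seed for reproducibility (optional).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 100000, coverage = 10,
                              mean_read_length = 8000,
                              length_sd = mean_read_length / 4,
                              sub_rate = 0.014, ins_rate = 0.086,
                              del_rate = 0.044, min_truth_overlap = 100,
                              seed = NULL) {
  stopifnot(genome_length >= 1, coverage > 0, mean_read_length >= 1,
            length_sd >= 0, min_truth_overlap >= 1)
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 1)
  if (mean_read_length > genome_length)
    stop("mean_read_length must not exceed genome_length")
  structure(list(genome_length = as.integer(genome_length),
                 coverage = coverage,
                 mean_read_length = mean_read_length,
                 length_sd = length_sd, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 min_truth_overlap = as.integer(min_truth_overlap),
                 seed = seed),
            class = "simulation_config")
}

#' Generate a uniform random genome
#'
#' @param length Genome length (>= 1).
#' @param seed Optional RNG seed.
#' @return A single uppercase ACGT string.
#' @export
generate_genome <- function(length, seed = NULL) {
  if (length < 1) stop("genome length must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

# Single-pass error process on a base vector. At each position: geometric
# number of insertions (uniform bases, no advance), then substitution
# (uniform over the three alternatives), deletion (no emission) or copy.
.apply_errors <- function(bases, sub_rate, ins_rate, del_rate) {
  L <- length(bases)
  n_ins <- if (ins_rate > 0) stats::rgeom(L, 1 - ins_rate) else integer(L)
  p_adv <- 1 - ins_rate
  u <- stats::runif(L)
  a_sub <- u < sub_rate / p_adv
  a_del <- !a_sub & u < (sub_rate + del_rate) / p_adv
  out_base <- bases
  n_sub <- sum(a_sub)
  if (n_sub > 0) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T",
                    "A", "C", "T", "A", "C", "G"), nrow = 3)
    ix <- match(bases[a_sub], c("A", "C", "G", "T"))
    out_base[a_sub] <- alt[cbind(sample.int(3, n_sub, replace = TRUE), ix)]
  }
  cnt <- n_ins + as.integer(!a_del)
  total <- sum(cnt)
  out <- character(total)
  ends <- cumsum(cnt)
  out[ends[!a_del]] <- out_base[!a_del]
  ins_slots <- which(out == "")
  if (length(ins_slots) > 0)
    out[ins_slots] <- sample(c("A", "C", "G", "T"), length(ins_slots),
                             replace = TRUE)
  paste(out, collapse = "")
}

#' Sample error-prone reads from a genome
#'
#' Read start positions are uniform, strands are assigned uniformly, and
#' sequencing errors are applied in a single pass over the sampled
#' substring (insertions emit without advancing, deletions advance
#' without emitting, substitutions replace with one of the three other
#' bases). The total sampled bases approximate
#' `coverage * genome_length`. Minus-strand reads are stored
#' reverse-complemented, as a sequencer would report them.
#'
#' @param genome A genome string (e.g. from [generate_genome()]).
#' @param config A [simulation_config()]. Its `seed`, when set, makes the
#'   result reproducible.
#' @return A list with `reads` (a [read_set()]) and `placements` (data
#'   frame: `id`, `start`, `end` half-open genomic interval, `strand`,
#'   `read_length`).
#' @export
sample_reads <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  g_len <- nchar(genome)
  if (config$mean_read_length > g_len)
    stop("mean read length exceeds genome length")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- max(1L, as.integer(round(config$coverage * g_len /
                                  config$mean_read_length)))
  lens <- as.integer(pmin(pmax(round(stats::rnorm(n, config$mean_read_length,
                                                  config$length_sd)), 200),
                          g_len))
  starts <- as.integer(floor(stats::runif(n, 0, g_len - lens + 1)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("read%05d", seq_len(n))
  gbases <- strsplit(genome, "", fixed = TRUE)[[1]]
  seqs <- character(n)
  for (r in seq_len(n)) {
    sampled <- gbases[(starts[r] + 1):(starts[r] + lens[r])]
    s <- .apply_errors(sampled, config$sub_rate, config$ins_rate,
                       config$del_rate)
    if (strands[r] == "-") s <- reverse_complement(s)
    seqs[r] <- s
  }
  reads <- read_set(ids, seqs)
  placements <- data.frame(id = ids, start = starts, end = starts + lens,
                           strand = strands, read_length = nchar(seqs),
                           stringsAsFactors = FALSE)
  list(reads = reads, placements = placements)
}

#' Ground-truth overlap pairs from read placements
#'
#' A pair of reads truly overlaps when their genomic sampling intervals
#' intersect by at least `min_truth_overlap` bases. Pairs are listed once
#' under canonical identifier order. Adjacency marks irreducible edges:
#' consecutive reads in genomic start order whose intersection qualifies.
#'
#' @param placements Placement table from [sample_reads()].
#' @param min_truth_overlap Minimum genomic intersection (default 100).
#' @return A data frame with `id_a`, `id_b`, `overlap_length`,
#'   `is_adjacent`, class `ground_truth`.
#' @export
true_overlaps <- function(placements, min_truth_overlap = 100) {
  n <- nrow(placements)
  if (n < 2) {
    out <- data.frame(id_a = character(), id_b = character(),
                      overlap_length = integer(), is_adjacent = logical())
    class(out) <- c("ground_truth", "data.frame")
    return(out)
  }
  ix <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- ix[, 1]; b <- ix[, 2]
  olap <- pmin(placements$end[a], placements$end[b]) -
    pmax(placements$start[a], placements$start[b])
  keep <- olap >= min_truth_overlap
  a <- a[keep]; b <- b[keep]; olap <- olap[keep]
  id_a <- placements$id[a]; id_b <- placements$id[b]
  swap <- id_a > id_b
  tmp <- id_a[swap]; id_a[swap] <- id_b[swap]; id_b[swap] <- tmp
  # irreducible edges: consecutive reads by genomic start
  ord <- order(placements$start, placements$end, placements$id)
  adj_a <- placements$id[ord][-n]
  adj_b <- placements$id[ord][-1]
  adj_key <- paste(pmin(adj_a, adj_b), pmax(adj_a, adj_b), sep = "\r")
  key <- paste(id_a, id_b, sep = "\r")
  out <- data.frame(id_a = id_a, id_b = id_b,
                    overlap_length = as.integer(olap),
                    is_adjacent = key %in% adj_key,
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Run the full simulator
#'
#' Generates a random genome, samples error-prone reads and derives the
#' ground truth in one call.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome`, `reads`, `placements`, `truth`.
#' @export
simulate_reads <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- generate_genome(config$genome_length, seed = config$seed)
  sampled <- sample_reads(genome, config)
  truth <- true_overlaps(sampled$placements, config$min_truth_overlap)
  list(genome = genome, reads = sampled$reads,
       placements = sampled$placements, truth = truth)
}

#' Fraction of irreducible overlaps shorter than a fraction of read length
#'
#' Summarizes the adjacent-read (irreducible-edge) overlaps: the share
#' whose overlap size is below `ratio * mean(read length of the pair)`.
#' At fixed read length this fraction decreases with coverage, since
#' denser sampling places adjacent reads closer together.
#'
#' @param truth A [true_overlaps()] table.
#' @param placements The matching placement table (for read lengths).
#' @param ratio Length-ratio cutoff (default 0.5).
#' @return A single fraction (NaN when there are no adjacent pairs).
#' @export
irreducible_overlap_fraction <- function(truth, placements, ratio = 0.5) {
  adj <- truth[truth$is_adjacent, , drop = FALSE]
  if (nrow(adj) == 0) return(NaN)
  len <- stats::setNames(placements$read_length, placements$id)
  pair_mean <- (len[adj$id_a] + len[adj$id_b]) / 2
  mean(adj$overlap_length < ratio * pair_mean)
}

#' Write ground truth as TSV
#'
#' Columns: `id_a`, `id_b`, `overlap_length`, `is_adjacent`.
#'
#' @param truth A [true_overlaps()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth TSV written by [write_truth()]
#'
#' @param path Input path.
#' @return A `ground_truth` data frame.
#' @export
read_truth <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "logical"))
  class(out) <- c("ground_truth", "data.frame")
  out
}
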