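#' Detect overlaps in a read set
#'
#' Runs the full three-stage pipeline: (1) filtration of read pairs by
#' positional shared `filter_k`-mer counts from the generalized suffix
#' index; (2) per-pair group seeding with `group_k`-mers under the
#' calibrated `rho`/`delta` constraints; (3) chaining, collinearity
#' trimming, overlap-region estimation, and the matched-bases acceptance
#' rule plus span similarity. The output is deterministic and invariant
#' to the input order of the reads: pairs are processed and reported in
#' canonical identifier order.
#'
#' For minus-strand calls the reported target coordinates are on the
#' forward strand of read b, following the PAF convention.
#'
#' @param reads A [read_set()] (or path handled by [read_sequences()]).
#' @param config A [pipeline_config()].
#' @param keep_rejected Also return rejected candidates with reason codes
#'   in `attr(, "rejected")` (default `FALSE`).
#' @param verbose Print per-stage counts (default `FALSE`).
#' @return An `overlap_calls` data frame: `id_a`, `a_len`, `a_start`,
#'   `a_end`, `strand`, `id_b`, `b_len`, `b_start`, `b_end`,
#'   `n_matched`, `l_o`.
#' @examples
#' reads <- read_set(c("r1", "r2"),
#'                   c(strrep("ACGTTGCA", 40), strrep("ACGTTGCA", 40)))
#' run_pipeline(reads, pipeline_config())
#' @export
run_pipeline <- function(reads, config = pipeline_config(),
                         keep_rejected = FALSE, verbose = FALSE) {
  if (is.character(reads) && length(reads) == 1) reads <- read_sequences(reads)
  stopifnot(inherits(reads, "read_set"), inherits(config, "pipeline_config"))
  if (config$min_read_length > 0) {
    keep <- reads$lengths >= config$min_read_length
    if (!any(keep)) stop("no reads pass min_read_length")
    reads <- read_set(reads$ids[keep], reads$sequences[keep])
  }
  index <- build_suffix_index(reads, include_reverse_complement = TRUE)
  counts <- count_shared_kmers(index, config$filter_k)
  candidates <- filter_pairs(counts, config$filter_threshold)
  if (verbose)
    message("filtration: ", nrow(counts), " counted pairs -> ",
            nrow(candidates), " candidates")
  seqs <- stats::setNames(reads$sequences, reads$ids)
  lens <- stats::setNames(reads$lengths, reads$ids)
  calls <- vector("list", nrow(candidates))
  rejected <- vector("list", nrow(candidates))
  for (t in seq_len(nrow(candidates))) {
    id_a <- candidates$id_a[t]
    id_b <- candidates$id_b[t]
    strand <- candidates$strand[t]
    seq_a <- seqs[[id_a]]
    seq_b <- if (strand == "+") seqs[[id_b]] else
      reverse_complement(seqs[[id_b]])
    res <- .call_pair(seq_a, seq_b, config)
    if (is.null(res)) next
    len_b <- lens[[id_b]]
    if (strand == "-") {
      b0 <- len_b - res$b_end
      b1 <- len_b - res$b_start
      res$b_start <- b0; res$b_end <- b1
    }
    row <- data.frame(id_a = id_a, a_len = lens[[id_a]],
                      a_start = res$a_start, a_end = res$a_end,
                      strand = strand, id_b = id_b, b_len = len_b,
                      b_start = res$b_start, b_end = res$b_end,
                      n_matched = res$n_matched, l_o = res$l_o,
                      stringsAsFactors = FALSE)
    if (res$accepted) calls[[t]] <- row
    else if (keep_rejected) rejected[[t]] <- cbind(row, reason = res$reason)
  }
  out <- do.call(rbind, calls[!vapply(calls, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(id_a = character(), a_len = integer(),
                      a_start = integer(), a_end = integer(),
                      strand = character(), id_b = character(),
                      b_len = integer(), b_start = integer(),
                      b_end = integer(), n_matched = integer(),
                      l_o = integer())
  # one call per pair: keep the best-supported strand
  out <- out[order(out$id_a, out$id_b, -out$n_matched, out$strand), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("id_a", "id_b")]), , drop = FALSE]
  rownames(out) <- NULL
  if (verbose) message("chaining: ", nrow(out), " accepted calls")
  class(out) <- c("overlap_calls", "data.frame")
  if (keep_rejected)
    attr(out, "rejected") <-
      do.call(rbind, rejected[!vapply(rejected, is.null, TRUE)])
  out
}

# Seed, group, chain and judge one oriented pair. Returns NULL when no
# seed survives, else the call geometry with the acceptance verdict.
.call_pair <- function(seq_a, seq_b, config) {
  hits <- enumerate_hits(seq_a, seq_b, config$group_k)
  if (nrow(hits) == 0) return(NULL)
  groups <- group_hits(hits, rho = config$rho, delta = config$delta)
  summ <- group_summary(groups)
  chain <- chain_groups(summ)
  chain <- trim_collinear(chain, delta = config$delta, q = config$q)
  region <- estimate_overlap_region(chain, nchar(seq_a), nchar(seq_b))
  verdict <- decide_overlap(chain, region$l_o, c = config$c,
                            rho = config$rho, k_group = config$group_k,
                            size_similarity_tau = config$size_similarity_tau)
  list(accepted = verdict$accepted, reason = verdict$reason,
       a_start = region$a_start, a_end = region$a_end,
       b_start = region$b_start, b_end = region$b_end,
       n_matched = verdict$n_matched, l_o = region$l_o)
}
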