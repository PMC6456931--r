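#' Construct a read set
#'
#' A light container pairing unique read identifiers with uppercase
#' nucleotide sequences. Sequences may contain `N` (or other IUPAC
#' letters); such positions never participate in a k-mer match.
#'
#' @param ids Character vector of unique read identifiers.
#' @param sequences Character vector of non-empty nucleotide sequences.
#' @return An object of class `read_set`: a list with `ids`, `sequences`
#'   and `lengths`.
#' @export
read_set <- function(ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("ids and sequences must have the same length")
  if (length(ids) == 0) stop("read set must not be empty")
  if (anyDuplicated(ids))
    stop("duplicate read ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(sequences) == 0)) stop("empty sequences are not allowed")
  if (any(grepl("[^A-Z]", sequences)))
    stop("sequences must contain letters only")
  structure(list(ids = ids, sequences = sequences,
                 lengths = nchar(sequences)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set:", length(x$ids), "reads, total",
      sum(x$lengths), "bases (mean length",
      round(mean(x$lengths), 1), ")\n")
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$ids)

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build a generalized suffix index over a read set
#'
#' Concatenates all reads (and, by default, their reverse complements),
#' each followed by a unique terminator, and computes the suffix array,
#' the LCP array (Kasai's algorithm) and aligned read-id/orientation/
#' position arrays. Terminators and ambiguous bases are encoded as unique
#' symbols so they can never extend a common prefix.
#'
#' @param reads A [read_set()].
#' @param include_reverse_complement Index both orientations of every read
#'   (default `TRUE`), required for strand-aware overlap detection.
#' @return An object of class `suffix_index` with fields `sa`, `lcp`,
#'   `read`, `orient`, `pos` (all aligned to suffix rank, 0-based), plus
#'   `ids`, `lengths` and `include_rc`. Positions on the `-` orientation
#'   are in reverse-complement coordinates.
#' @export
build_suffix_index <- function(reads, include_reverse_complement = TRUE) {
  stopifnot(inherits(reads, "read_set"))
  idx <- build_suffix_index_cpp(reads$sequences, include_reverse_complement)
  structure(c(idx, list(ids = reads$ids, lengths = reads$lengths,
                        include_rc = include_reverse_complement)),
            class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat("Suffix index:", length(x$ids), "reads, text length", x$text_length,
      if (x$include_rc) "(both orientations)" else "(forward only)", "\n")
  invisible(x)
}

#' Count positional shared k-mers per oriented read pair
#'
#' Enumerates maximal suffix-array runs with LCP at least `k_filter` and
#' accumulates cross-read position-pair counts within each run; the result
#' equals brute-force hash-join counting of k-mer start-position pairs.
#' Self pairs (a read against itself or its own reverse complement) are
#' excluded. Pairs are reported under canonical identifier order
#' (`id_a < id_b` lexicographically); counts are symmetric by
#' construction. Strand `-` means read b is taken reverse-complemented.
#'
#' @param index A [build_suffix_index()] result.
#' @param k_filter Filtration k-mer length (default 15).
#' @param max_run Optional cap on suffix-run size as a guard against
#'   pathological repeats; `Inf` (default) disables it.
#' @return A data frame with columns `id_a`, `id_b`, `strand`
#'   (`"+"`/`"-"`), `shared_kmers`; pairs with zero count are absent.
#' @export
count_shared_kmers <- function(index, k_filter = 15, max_run = Inf) {
  stopifnot(inherits(index, "suffix_index"), k_filter >= 1)
  cap <- if (is.finite(max_run)) as.integer(max_run) else -1L
  raw <- count_shared_kmers_cpp(index$lcp, index$read, index$orient,
                                as.integer(k_filter), length(index$ids), cap)
  id_a <- index$ids[raw$a + 1L]
  id_b <- index$ids[raw$b + 1L]
  swap <- id_a > id_b
  tmp <- id_a[swap]; id_a[swap] <- id_b[swap]; id_b[swap] <- tmp
  out <- data.frame(id_a = id_a, id_b = id_b,
                    strand = c("+", "-")[raw$strand + 1L],
                    shared_kmers = raw$count,
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidate read pairs by shared k-mer count
#'
#' Each orientation of a pair is tested against the threshold
#' independently (a true overlap exists in one relative orientation, so
#' counts are not summed across strands).
#'
#' @param pair_counts Output of [count_shared_kmers()].
#' @param threshold Minimum shared k-mer count (default 2).
#' @return The retained rows, class `candidate_pairs`.
#' @export
filter_pairs <- function(pair_counts, threshold = 2) {
  stopifnot(threshold >= 1)
  out <- pair_counts[pair_counts$shared_kmers >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", "data.frame")
  out
}

#' Write candidate pairs as TSV
#'
#' @param pairs Candidate pair data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
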