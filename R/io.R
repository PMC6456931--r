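#' Read sequences from FASTA or FASTQ
#'
#' The format is auto-detected from the first record character (`>` or
#' `@`), transparently through gzip. Identifiers are the first
#' whitespace-delimited header token; sequences are uppercased; FASTQ
#' qualities are ignored. Duplicate identifiers are an error.
#'
#' @param path Path to a FASTA or FASTQ file (optionally gzipped).
#' @return A [read_set()].
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "r")
  first <- ""
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) break
    if (nzchar(trimws(line))) { first <- substr(trimws(line), 1, 1); break }
  }
  close(con)
  format <- if (first == ">") "fasta" else if (first == "@") "fastq" else
    stop("cannot detect FASTA/FASTQ format in ", path,
         " (first record starts with '", first, "')")
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate read ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  read_set(ids, as.character(seqs))
}

#' Write a read set as FASTA
#'
#' When `placements` are given, each header carries the sampling
#' metadata as comment fields: `id start end strand`.
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @param placements Optional placement table from [sample_reads()].
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path, placements = NULL) {
  stopifnot(inherits(reads, "read_set"))
  headers <- reads$ids
  if (!is.null(placements)) {
    m <- match(reads$ids, placements$id)
    headers <- paste(reads$ids, placements$start[m], placements$end[m],
                     placements$strand[m])
  }
  x <- Biostrings::DNAStringSet(reads$sequences)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write overlap calls in PAF format
#'
#' Standard headerless 12-column PAF: query name/length/start/end,
#' strand, target name/length/start/end, residue matches (the chain's
#' matched bases), alignment block length (the estimated overlap length)
#' and mapping quality 255. Coordinates are 0-based half-open; minus-
#' strand target coordinates are already given on the target's forward
#' strand.
#'
#' @param calls An `overlap_calls` data frame from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(calls, path) {
  with(calls, {
    bad <- a_start < 0 | a_end > a_len | b_start < 0 | b_end > b_len |
      a_start >= a_end | b_start >= b_end
    if (any(bad)) stop("call coordinates out of read bounds")
  })
  paf <- data.frame(calls$id_a, calls$a_len, calls$a_start, calls$a_end,
                    calls$strand, calls$id_b, calls$b_len, calls$b_start,
                    calls$b_end, calls$n_matched, calls$l_o,
                    rep(255L, nrow(calls)))
  utils::write.table(paf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PAF file written by [write_paf()]
#'
#' @param path Input path.
#' @return An `overlap_calls` data frame.
#' @export
read_paf <- function(path) {
  if (file.size(path) == 0) {
    out <- data.frame(id_a = character(), a_len = integer(),
                      a_start = integer(), a_end = integer(),
                      strand = character(), id_b = character(),
                      b_len = integer(), b_start = integer(),
                      b_end = integer(), n_matched = integer(),
                      l_o = integer(), mapq = integer())
  } else {
    out <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    names(out) <- c("id_a", "a_len", "a_start", "a_end", "strand", "id_b",
                    "b_len", "b_start", "b_end", "n_matched", "l_o",
                    "mapq")
  }
  class(out) <- c("overlap_calls", "data.frame")
  out
}

#' Pipeline configuration
#'
#' Bundles every tunable of the overlap pipeline. Defaults: filtration
#' with two shared 15-mers; group seeding with 9-mers under thresholds
#' calibrated at `p = 0.85`, `q = 0.06`, `alpha = 0.05` (rho = 54,
#' delta = 5); chaining acceptance with coefficient `c = 2` and span
#' similarity tolerance 0.3.
#'
#' @param filter_k Filtration k-mer length (default 15).
#' @param filter_threshold Minimum shared filtration k-mers (default 2).
#' @param group_k Group-seed k-mer length (default 9).
#' @param p Per-base match probability for calibration (default 0.85).
#' @param q Per-base indel probability (default 0.06).
#' @param alpha Significance level (default 0.05).
#' @param c Chain acceptance coefficient (default 2).
#' @param size_similarity_tau Span similarity tolerance (default 0.3).
#' @param min_read_length Reads shorter than this are dropped up front
#'   (default 0: keep all).
#' @param seed Unused by the deterministic pipeline; recorded for
#'   provenance.
#' @return An object of class `pipeline_config` with calibrated `rho` and
#'   `delta` attached.
#' @export
pipeline_config <- function(filter_k = 15, filter_threshold = 2,
                            group_k = 9, p = 0.85, q = 0.06, alpha = 0.05,
                            c = 2, size_similarity_tau = 0.3,
                            min_read_length = 0, seed = NULL) {
  stopifnot(filter_k >= 1, filter_threshold >= 1, group_k >= 1, c > 0,
            size_similarity_tau >= 0, min_read_length >= 0)
  gc <- group_criteria(p = p, q = q, alpha = alpha, k = group_k)
  structure(list(filter_k = as.integer(filter_k),
                 filter_threshold = as.integer(filter_threshold),
                 group_k = as.integer(group_k), p = p, q = q,
                 alpha = alpha, c = c,
                 size_similarity_tau = size_similarity_tau,
                 min_read_length = as.integer(min_read_length),
                 seed = seed, rho = gc$rho, delta = gc$delta),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  v <- unclass(x)
  v$seed <- NULL
  cat("Pipeline config:\n")
  for (f in names(v)) cat(" ", f, "=", v[[f]], "\n")
  invisible(x)
}

#' Write a pipeline configuration as key=value text
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- unclass(config)
  v$rho <- NULL; v$delta <- NULL   # derived, recomputed on load
  v <- v[!vapply(v, is.null, TRUE)]
  writeLines(paste0(names(v), "=",
                    vapply(v, format, "", scientific = FALSE)), path)
  invisible(path)
}

#' Read a pipeline configuration from key=value text
#'
#' Keys absent from the file keep their defaults.
#'
#' @param path Input path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- stats::setNames(lapply(kv, function(x) as.numeric(x[2])),
                          vapply(kv, `[`, "", 1))
  do.call(pipeline_config, args)
}
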