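#' Harmonic mean of sensitivity and precision
#'
#' @param sensitivity,precision Fractions in `[0, 1]`.
#' @return The F1 score; 0 when both inputs are 0.
#' @export
f1_score <- function(sensitivity, precision) {
  ifelse(sensitivity + precision > 0,
         2 * sensitivity * precision / (sensitivity + precision), 0)
}

.canonical_keys <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "\r")
}

#' Score overlap calls against ground truth
#'
#' Pairs are matched by identity only: a reported pair is correct when it
#' appears in the ground truth, regardless of the reported coordinates or
#' strand (truth derived from genomic placements is strand-agnostic).
#' Duplicate calls and duplicate truth rows are collapsed. With zero
#' calls, precision is 0 by convention.
#'
#' @param calls Data frame with `id_a`, `id_b` (overlap calls).
#' @param truth Ground-truth data frame with `id_a`, `id_b` and
#'   optionally `overlap_length`.
#' @param min_overlap Restrict the evaluation to truth pairs with
#'   `overlap_length >= min_overlap` (default 0: use all); calls matching
#'   an excluded truth pair then count as false positives.
#' @return An object of class `evaluation_report`: list with `tp`, `fp`,
#'   `fn`, `sensitivity`, `precision`, `f1`, `n_calls`, `n_truth`.
#' @export
score_calls <- function(calls, truth, min_overlap = 0) {
  if (min_overlap > 0)
    truth <- truth[truth$overlap_length >= min_overlap, , drop = FALSE]
  truth_keys <- unique(.canonical_keys(truth$id_a, truth$id_b))
  call_keys <- unique(.canonical_keys(calls$id_a, calls$id_b))
  tp <- sum(call_keys %in% truth_keys)
  fp <- length(call_keys) - tp
  fn <- length(truth_keys) - tp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 precision = prec, f1 = f1_score(sens, prec),
                 n_calls = length(call_keys),
                 n_truth = length(truth_keys)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Overlap evaluation: ", x$n_calls, " calls vs ", x$n_truth,
      " truth pairs\n", sep = "")
  cat(sprintf("  tp = %d  fp = %d  fn = %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  sensitivity = %.4f  precision = %.4f  F1 = %.4f\n",
              x$sensitivity, x$precision, round(x$f1, 4)))
  invisible(x)
}

#' Write an evaluation report as key=value text
#'
#' @param x An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "evaluation_report"))
  vals <- unclass(x)
  vals$f1 <- round(vals$f1, 4)
  writeLines(paste0(names(vals), "=", vapply(vals, format, "")), path)
  invisible(path)
}

#' Sensitivity binned by true overlap size
#'
#' Truth pairs are partitioned into bins of fixed width by overlap
#' length (`bin = floor(length / bin_width)`: 0..499 in the first bin for
#' width 500, 500..999 in the second, and so on); per-bin sensitivity is
#' the detected fraction.
#'
#' @param calls Data frame with `id_a`, `id_b`.
#' @param truth Ground truth with `id_a`, `id_b`, `overlap_length`.
#' @param bin_width Bin width in bases (default 500).
#' @return A data frame: `bin`, `lower`, `upper`, `truth_count`,
#'   `detected`, `sensitivity`.
#' @export
binned_sensitivity <- function(calls, truth, bin_width = 500) {
  stopifnot(bin_width >= 1)
  bin_width <- as.integer(bin_width)
  truth <- truth[!duplicated(.canonical_keys(truth$id_a, truth$id_b)), ,
                 drop = FALSE]
  call_keys <- unique(.canonical_keys(calls$id_a, calls$id_b))
  bin <- as.integer(truth$overlap_length) %/% bin_width
  hit <- .canonical_keys(truth$id_a, truth$id_b) %in% call_keys
  bins <- sort(unique(bin))
  out <- data.frame(bin = bins,
                    lower = bins * bin_width,
                    upper = (bins + 1L) * bin_width - 1L,
                    truth_count = as.integer(table(factor(bin, bins))),
                    detected = vapply(bins, function(b)
                      sum(hit[bin == b]), 0L))
  out$sensitivity <- out$detected / out$truth_count
  out
}
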