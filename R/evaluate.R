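#' Prune a benchmark complex set to the proteins of a network
#'
#' To avoid selection bias, each gold-standard complex is intersected with
#' the proteins actually present in the analysed PPI network, and complexes
#' left with fewer than `min_size` members are dropped.
#'
#' @param benchmark A complex tibble (see [read_complexes()]) or list of
#'   protein-ID vectors.
#' @param network_proteins Character vector of network protein IDs.
#' @param min_size Minimum surviving complex size (default 3).
#' @return A complex tibble.
#' @export
prune_benchmark <- function(benchmark, network_proteins, min_size = 3) {
  sets <- if (is.data.frame(benchmark)) benchmark$proteins else benchmark
  pruned <- lapply(sets, function(p) sort(intersect(p, network_proteins)))
  pruned <- pruned[lengths(pruned) >= min_size]
  tibble(complex_id = seq_along(pruned), proteins = pruned,
         size = lengths(pruned), source = "benchmark")
}

#' Score predicted complexes against a benchmark set
#'
#' A predicted complex counts as matched when some benchmark complex
#' overlaps it with Jaccard index at least `delta`, and vice versa
#' (existence matching, not one-to-one assignment). Precision is the
#' matched fraction of predictions, recall the matched fraction of the
#' benchmark, and F1 their harmonic mean. Threshold comparisons are
#' computed as `|A n B| >= delta * |A u B|` on integer counts, so ties at
#' dyadic `delta` values (0.25, 0.5, ...) are exact.
#'
#' @param detected A complex tibble or list of protein-ID vectors.
#' @param benchmark A nonempty complex tibble or list of protein-ID vectors.
#' @param delta Jaccard match threshold in (0, 1] (default 0.25).
#' @return A one-row tibble of class `"complex_evaluation"` with columns
#'   `precision`, `recall`, `f1`, `delta`, `matched_detected`,
#'   `matched_benchmark`, `n_detected`, `n_benchmark`.
#' @examples
#' evaluate_complexes(list(c("a", "b", "c")), list(c("a", "b", "c", "d")))
#' @export
evaluate_complexes <- function(detected, benchmark, delta = 0.25) {
  stopifnot(delta > 0, delta <= 1)
  dsets <- lapply(if (is.data.frame(detected)) detected$proteins else detected,
                  function(p) unique(as.character(p)))
  bsets <- lapply(if (is.data.frame(benchmark)) benchmark$proteins else benchmark,
                  function(p) unique(as.character(p)))
  if (length(bsets) == 0) abort("benchmark complex set is empty")
  nd <- length(dsets)
  nb <- length(bsets)
  d_matched <- logical(nd)
  b_matched <- logical(nb)
  for (i in seq_len(nd)) {
    for (j in seq_len(nb)) {
      if (d_matched[i] && b_matched[j]) next
      inter <- length(intersect(dsets[[i]], bsets[[j]]))
      uni <- length(dsets[[i]]) + length(bsets[[j]]) - inter
      if (inter >= delta * uni) {
        d_matched[i] <- TRUE
        b_matched[j] <- TRUE
      }
    }
  }
  precision <- if (nd == 0) 0 else sum(d_matched) / nd
  recall <- sum(b_matched) / nb
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(tibble(precision = precision, recall = recall, f1 = f1,
                   delta = delta,
                   matched_detected = sum(d_matched),
                   matched_benchmark = sum(b_matched),
                   n_detected = nd, n_benchmark = nb),
            class = c("complex_evaluation", class(tibble())))
}

#' @export
print.complex_evaluation <- function(x, ...) {
  cat(sprintf(
    "Complex detection evaluation (delta = %g):\n  precision %.3f (%d/%d)  recall %.3f (%d/%d)  f1 %.3f\n",
    x$delta, x$precision, x$matched_detected, x$n_detected,
    x$recall, x$matched_benchmark, x$n_benchmark, x$f1))
  invisible(x)
}

#' Write an evaluation result as TSV
#'
#' @param result A `"complex_evaluation"`.
#' @param path Output file path.
#' @param comments Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(result, path, comments = NULL) {
  df <- as.data.frame(result)
  out <- c(if (length(comments)) paste0("# ", comments),
           paste(names(df), collapse = "\t"),
           paste(vapply(df, function(v) format(v, digits = 10), character(1)),
                 collapse = "\t"))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
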