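#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GA biclustering fit
#'
#' @param x A `"ga_biclusters"` object from [run_ga()].
#' @param ... Unused.
#' @return The bicluster tibble (one row per harvested bicluster, with
#'   list-columns `genes` and `conditions` and fitness `dcm`).
#' @export
tidy.ga_biclusters <- function(x, ...) x$biclusters

#' One-row summary of a GA biclustering fit
#'
#' @param x A `"ga_biclusters"` object.
#' @param ... Unused.
#' @return A one-row tibble: number of harvested biclusters, best and mean
#'   fitness, restarts and total generations executed.
#' @export
glance.ga_biclusters <- function(x, ...) {
  tibble(n_biclusters = nrow(x$biclusters),
         best_dcm = if (nrow(x$biclusters)) max(x$biclusters$dcm) else NA_real_,
         mean_dcm = if (nrow(x$biclusters)) mean(x$biclusters$dcm) else NA_real_,
         n_restarts = x$config$n_restarts,
         total_generations = sum(x$history$generation > 0))
}

#' Tidy an evaluation result into metric/value pairs
#'
#' @param x A `"complex_evaluation"` from [evaluate_complexes()].
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value`.
#' @export
tidy.complex_evaluation <- function(x, ...) {
  tibble(metric = c("precision", "recall", "f1"),
         value = c(x$precision, x$recall, x$f1))
}

#' One-row summary of an evaluation result
#'
#' @param x A `"complex_evaluation"`.
#' @param ... Unused.
#' @return The underlying one-row tibble, without the class decoration.
#' @export
glance.complex_evaluation <- function(x, ...) {
  as_tibble(unclass(x))
}
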