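# Registry of protein-complex detectors. A detector is a function
# (sub: ppi_subnetwork, params: named list) -> list of character vectors
# (one protein set per predicted complex). Registration is the seam where
# external detection tools plug in, either as R functions or via
# read_complexes() on their output files.
.detectors <- new.env(parent = emptyenv())

#' Register a protein-complex detector
#'
#' @param name Detector name used in [detect_on_all()] and the pipeline
#'   config.
#' @param fun A `function(sub, params)` returning a list of protein-ID
#'   character vectors.
#' @return `name`, invisibly.
#' @export
register_detector <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .detectors)
  invisible(name)
}

#' List registered detector names
#' @return A character vector.
#' @export
list_detectors <- function() sort(ls(.detectors))

get_detector <- function(name) {
  if (!exists(name, envir = .detectors, inherits = FALSE)) {
    abort(sprintf("unknown detector '%s'; registered: %s", name,
                  paste(list_detectors(), collapse = ", ")))
  }
  get(name, envir = .detectors, inherits = FALSE)
}

#' Greedy density-based complex detector (baseline)
#'
#' A deliberately simple built-in detector used as the package's baseline:
#' it is *not* a reimplementation of any published detection method.
#' Starting from each unvisited node in order of decreasing degree (ties
#' broken lexicographically), it greedily adds the neighbour that maximises
#' the cluster's edge density while the density stays at or above
#' `min_density`, then emits clusters with at least `min_size` members.
#' Fully deterministic.
#'
#' @param sub A `"ppi_subnetwork"`.
#' @param min_density Minimum edge density (edges over possible pairs) in
#'   (0, 1]; default 0.6.
#' @param min_size Minimum complex size; default 3.
#' @return A list of character vectors (predicted complexes).
#' @export
greedy_density_detect <- function(sub, min_density = 0.6, min_size = 3) {
  stopifnot(inherits(sub, "ppi_subnetwork"),
            min_density > 0, min_density <= 1, min_size >= 1)
  if (nrow(sub$edges) == 0) return(list())
  g <- as_igraph(sub)
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  # adjacency as named list of neighbour name vectors
  adj <- lapply(igraph::adjacent_vertices(g, nodes), function(v) v$name)
  names(adj) <- nodes
  order_nodes <- nodes[order(-deg, nodes)]
  visited <- character(0)
  out <- list()
  for (seed in order_nodes) {
    if (seed %in% visited || deg[[seed]] == 0) next
    cluster <- seed
    n_edges <- 0L
    repeat {
      cand <- setdiff(unique(unlist(adj[cluster], use.names = FALSE)),
                      c(cluster, visited))
      if (length(cand) == 0) break
      gains <- vapply(cand, function(v) sum(adj[[v]] %in% cluster), integer(1))
      k <- length(cluster) + 1L
      dens <- (n_edges + gains) / (k * (k - 1) / 2)
      best <- order(-dens, cand)[1]
      if (dens[best] < min_density) break
      n_edges <- n_edges + gains[best]
      cluster <- c(cluster, cand[best])
    }
    if (length(cluster) >= min_size) out[[length(out) + 1L]] <- sort(cluster)
    visited <- c(visited, cluster)
  }
  out
}

#' Run a detector on every dynamic subnetwork
#'
#' Applies the named detector to each subnetwork and concatenates the
#' predictions, tagging each complex with the bicluster that produced its
#' subnetwork.
#'
#' @param subs List of `"ppi_subnetwork"` objects.
#' @param detector Registered detector name (default `"greedy_density"`).
#' @param params Named list of detector parameters.
#' @return A complex tibble: `complex_id`, list-column `proteins`, `size`,
#'   `source` (bicluster ID as character).
#' @export
detect_on_all <- function(subs, detector = "greedy_density", params = list()) {
  fun <- get_detector(detector)
  rows <- list()
  for (s in subs) {
    sets <- fun(s, params)
    for (p in sets) {
      rows[[length(rows) + 1L]] <-
        list(proteins = sort(unique(as.character(p))),
             source = as.character(s$bicluster_id))
    }
  }
  tibble(complex_id = seq_along(rows),
         proteins = lapply(rows, `[[`, "proteins"),
         size = vapply(rows, function(r) length(r$proteins), integer(1)),
         source = vapply(rows, `[[`, character(1), "source"))
}

#' Aggregate predicted complexes, removing exact duplicates
#'
#' Complexes predicted from several subnetworks are pooled; predictions with
#' exactly equal protein sets are collapsed to one (the first occurrence,
#' relabelled `"aggregate"` when it absorbed duplicates). Near-duplicates
#' are deliberately *not* merged. Output is ordered by descending size, then
#' lexicographically.
#'
#' @param complexes A complex tibble (see [detect_on_all()]).
#' @return The deduplicated complex tibble.
#' @export
aggregate_complexes <- function(complexes) {
  if (nrow(complexes) == 0) return(complexes)
  key <- vapply(complexes$proteins, set_key, character(1))
  dup_keys <- unique(key[duplicated(key)])
  keep <- !duplicated(key)
  out <- complexes[keep, , drop = FALSE]
  out$source[key[keep] %in% dup_keys] <- "aggregate"
  first_protein <- vapply(out$proteins, function(p) sort(p)[1], character(1))
  out <- out[order(-out$size, first_protein,
                   vapply(out$proteins, set_key, character(1))), , drop = FALSE]
  out$complex_id <- seq_len(nrow(out))
  out
}

#' Drop complexes below a minimum size
#'
#' Gold-standard complex sets conventionally require at least 3 proteins;
#' the same filter is applied to predictions for symmetric treatment.
#'
#' @param complexes A complex tibble.
#' @param k Minimum number of proteins (default 3).
#' @return The filtered complex tibble.
#' @export
filter_min_size <- function(complexes, k = 3) {
  stopifnot(k >= 1)
  if (nrow(complexes) == 0) return(complexes)
  complexes[vapply(complexes$proteins, length, integer(1)) >= k, , drop = FALSE]
}

#' Read a complex set (one complex per line, tab-separated proteins)
#'
#' The de-facto format of curated gold standards and of most detection
#' tools' outputs, so external detectors can be plugged into the pipeline
#' through their files.
#'
#' @param path Input file path; `#` comments and blank lines skipped.
#' @return A complex tibble with `source = "file"`.
#' @export
read_complexes <- function(path) {
  cl <- read_content_lines(path)
  sets <- lapply(strsplit(cl$lines, "\t", fixed = TRUE), function(p) {
    sort(unique(p[nzchar(p)]))
  })
  empty <- lengths(sets) == 0
  if (any(empty)) {
    abort(sprintf("'%s' line %d: empty complex", path, cl$lineno[which(empty)[1]]))
  }
  tibble(complex_id = seq_along(sets), proteins = sets,
         size = lengths(sets), source = "file")
}

#' Write a complex set (one complex per line, tab-separated proteins)
#'
#' @param complexes A complex tibble or a list of protein-ID vectors.
#' @param path Output file path.
#' @param comments Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path, comments = NULL) {
  sets <- if (is.data.frame(complexes)) complexes$proteins else complexes
  out <- c(if (length(comments)) paste0("# ", comments),
           vapply(sets, function(p) paste(sort(unique(p)), collapse = "\t"),
                  character(1)))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
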