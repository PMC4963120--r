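#' Construct a PPI network from an edge table
#'
#' Stores an undirected protein-protein interaction network as a canonical
#' edge table: each edge is an unordered pair kept with its endpoints in
#' lexicographic order, so `{a, b}` and `{b, a}` are one edge. Self-loops
#' are dropped with a warning and duplicate edges collapsed.
#'
#' @param a,b Character vectors of interacting protein IDs (same length).
#' @param proteins Optional additional isolated proteins to include.
#' @return An object of class `"ppi_network"`: a list with sorted `proteins`
#'   and an `edges` tibble (columns `a < b`).
#' @export
ppi_network <- function(a = character(0), b = character(0),
                        proteins = character(0)) {
  stopifnot(length(a) == length(b))
  a <- as.character(a)
  b <- as.character(b)
  loops <- a == b
  if (any(loops)) {
    warn(sprintf("dropped %d self-loop(s)", sum(loops)))
    a <- a[!loops]
    b <- b[!loops]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  edges <- distinct(tibble(a = lo, b = hi))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  structure(list(proteins = sort(unique(c(edges$a, edges$b, as.character(proteins)))),
                 edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d proteins, %d interactions\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI network from an edge-list or SIF file
#'
#' Accepts whitespace- or tab-separated two-column edge lists (`a b`) or
#' three-column SIF lines (`a relation b`). Direction is ignored, duplicate
#' and reversed edges are collapsed, and self-loops dropped with a warning.
#'
#' @param path Input file path; `#` comments and blank lines are skipped.
#' @param format `"auto"` (default, by column count), `"edgelist"` or
#'   `"sif"`.
#' @return A `"ppi_network"`.
#' @export
read_ppi <- function(path, format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  cl <- read_content_lines(path)
  if (length(cl$lines) == 0) return(ppi_network())
  fields <- strsplit(trimws(cl$lines), "[ \t]+")
  nf <- lengths(fields)
  if (format == "auto") {
    format <- if (stats::median(nf) >= 3) "sif" else "edgelist"
  }
  want <- if (format == "sif") 3L else 2L
  bad <- which(nf != want)
  if (length(bad)) {
    abort(sprintf("'%s' line %d: expected %d fields (%s format), found %d",
                  path, cl$lineno[bad[1]], want, format, nf[bad[1]]))
  }
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), want)
  ppi_network(a, b)
}

#' Write a PPI network or subnetwork as a tab-separated edge list
#'
#' @param net A `"ppi_network"` or `"ppi_subnetwork"`.
#' @param path Output file path.
#' @param comments Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(net, path, comments = NULL) {
  edges <- net$edges
  out <- c(if (length(comments)) paste0("# ", comments),
           sprintf("%s\t%s", edges$a, edges$b))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict a network to a set of genes
#'
#' Keeps only the proteins in `keep` and the interactions with both
#' endpoints kept — the standard pruning of a static network to the genes
#' present in an expression data set.
#'
#' @param net A `"ppi_network"`.
#' @param keep Character vector of gene/protein IDs (exact, case-sensitive
#'   match).
#' @return The pruned `"ppi_network"`.
#' @export
prune_to_genes <- function(net, keep) {
  stopifnot(inherits(net, "ppi_network"))
  keep <- unique(as.character(keep))
  edges <- net$edges[net$edges$a %in% keep & net$edges$b %in% keep, , drop = FALSE]
  dropped_p <- length(net$proteins) - length(intersect(net$proteins, keep))
  dropped_e <- nrow(net$edges) - nrow(edges)
  if (dropped_p > 0 || dropped_e > 0) {
    inform(sprintf("pruned %d protein(s) and %d interaction(s)",
                   dropped_p, dropped_e))
  }
  structure(list(proteins = sort(intersect(net$proteins, keep)), edges = edges),
            class = "ppi_network")
}

#' Extract the dynamic subnetwork induced by one bicluster
#'
#' The subnetwork of a bicluster is the induced subgraph of the static PPI
#' network on the bicluster's gene set: its nodes are the bicluster genes
#' present in the network (isolated nodes retained) and its edges are
#' exactly the network edges with both endpoints in that set.
#'
#' @param net A `"ppi_network"`.
#' @param genes Character vector of the bicluster's gene IDs.
#' @param bicluster_id Identifier recorded as the subnetwork's provenance.
#' @return An object of class `"ppi_subnetwork"`: list with `bicluster_id`,
#'   `proteins` and canonical `edges`.
#' @export
extract_subnetwork <- function(net, genes, bicluster_id = NA_integer_) {
  stopifnot(inherits(net, "ppi_network"))
  genes <- unique(as.character(genes))
  proteins <- sort(intersect(net$proteins, genes))
  edges <- net$edges[net$edges$a %in% proteins & net$edges$b %in% proteins, ,
                     drop = FALSE]
  structure(list(bicluster_id = bicluster_id, proteins = proteins,
                 edges = edges),
            class = "ppi_subnetwork")
}

#' @export
print.ppi_subnetwork <- function(x, ...) {
  cat(sprintf("Dynamic PPI subnetwork (bicluster %s): %d proteins, %d edges\n",
              format(x$bicluster_id), length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Extract one dynamic subnetwork per bicluster
#'
#' @param net A `"ppi_network"`.
#' @param x A `"ga_biclusters"` fit or bicluster tibble.
#' @return A list of `"ppi_subnetwork"` objects, one per bicluster, named by
#'   bicluster ID.
#' @export
extract_subnetworks <- function(net, x) {
  bics <- as_bicluster_tbl(x)
  subs <- lapply(seq_len(nrow(bics)), function(i) {
    extract_subnetwork(net, bics$genes[[i]], bics$bicluster_id[i])
  })
  names(subs) <- as.character(bics$bicluster_id)
  subs
}

#' Classify interactions as stable or transient across subnetworks
#'
#' An interaction appearing in every extracted dynamic subnetwork is
#' *stable* (part of the network's backbone); one appearing in some but not
#' all is *transient*, active only in particular expression states.
#'
#' @param subs Nonempty list of `"ppi_subnetwork"` objects.
#' @return A tibble with columns `protein_a`, `protein_b`, `support`
#'   (number of subnetworks containing the edge) and `label`
#'   (`"stable"`/`"transient"`), sorted by descending support.
#' @export
classify_interactions <- function(subs) {
  if (length(subs) == 0) abort("no subnetworks to classify")
  all_edges <- dplyr::bind_rows(lapply(subs, function(s) distinct(s$edges)))
  if (nrow(all_edges) == 0) {
    return(tibble(protein_a = character(0), protein_b = character(0),
                  support = integer(0), label = character(0)))
  }
  counts <- dplyr::count(all_edges, .data$a, .data$b, name = "support")
  out <- tibble(protein_a = counts$a, protein_b = counts$b,
                support = as.integer(counts$support),
                label = ifelse(counts$support == length(subs),
                               "stable", "transient"))
  out[order(-out$support, out$protein_a, out$protein_b), , drop = FALSE]
}

#' Convert a network or subnetwork to an igraph object
#'
#' @param x A `"ppi_network"` or `"ppi_subnetwork"`.
#' @return An undirected [igraph::graph] with protein IDs as vertex names.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, c("ppi_network", "ppi_subnetwork")))
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = data.frame(name = x$proteins))
}
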