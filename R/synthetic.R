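#' Generate a synthetic expression matrix with planted biclusters
#'
#' Emulates a time-series microarray matrix (genes by time-points) in which
#' subsets of genes are co-regulated over subsets of time-points. Background
#' cells are standard normal. Each planted block gets shared per-column
#' offsets `c_j` of a single per-block magnitude in `[4, 5]` with balanced,
#' randomly ordered signs, so all block genes move together and every block
#' column clears the per-gene discretization band while each block carries
#' its own temporal signature; the
#' `shifting` pattern additionally adds a per-gene offset
#' `b_i ~ Uniform(-2, 2)` and the `scaling` pattern multiplies by
#' `a_i ~ Uniform(0.5, 2)` — the two coherence families a column-based
#' discretized fitness is expected to capture. Gaussian noise of standard
#' deviation `noise_sd` is finally added everywhere. Planted blocks occupy
#' disjoint gene ranges (so no cell belongs to two blocks) and, by default,
#' contiguous time-point ranges at evenly spaced phase offsets — distinct
#' expression phases of a cycle, disjoint whenever they fit side by side.
#'
#' Defaults reproduce the package's reference study conditions: a 100 x 12
#' matrix with two planted 20 x 6 constant-column blocks and noise 0.25.
#'
#' @param m,n Matrix dimensions (genes, time-points).
#' @param truth_spec List of planted-block specs, each a list
#'   `(size_genes, size_conds, pattern)` with pattern one of
#'   `"constant_column"`, `"shifting"`, `"scaling"`.
#' @param noise_sd Standard deviation of the added Gaussian noise (>= 0).
#' @param seed Integer seed; the same seed reproduces the matrix exactly.
#' @param scattered_conditions If `TRUE`, planted condition sets are random
#'   subsets instead of contiguous ranges.
#' @return A list with `expression` (numeric matrix, genes `g001`... by
#'   time-points `t01`...) and `truth` (class `"planted_truth"`: tibble of
#'   planted biclusters, complexes added by [gen_ppi()]).
#' @export
gen_expression <- function(m = 100, n = 12,
                           truth_spec = list(list(20, 6, "constant_column"),
                                             list(20, 6, "constant_column")),
                           noise_sd = 0.25, seed = 1,
                           scattered_conditions = FALSE) {
  stopifnot(m >= 1, n >= 1, noise_sd >= 0)
  sizes_g <- vapply(truth_spec, function(s) as.integer(s[[1]]), integer(1))
  sizes_c <- vapply(truth_spec, function(s) as.integer(s[[2]]), integer(1))
  patterns <- vapply(truth_spec, function(s) as.character(s[[3]]), character(1))
  if (length(truth_spec)) {
    stopifnot(all(patterns %in% c("constant_column", "shifting", "scaling")))
    if (sum(sizes_g) > m || any(sizes_c > n)) {
      abort("planted blocks do not fit in the requested matrix dimensions")
    }
  }
  gene_ids <- sprintf("g%03d", seq_len(m))
  cond_ids <- sprintf("t%02d", seq_len(n))
  set.seed(derive_seed(seed, 0))
  M <- matrix(stats::rnorm(m * n), m, n, dimnames = list(gene_ids, cond_ids))
  gene_cursor <- 0L
  bic_rows <- vector("list", length(truth_spec))
  for (k in seq_along(truth_spec)) {
    gi <- gene_cursor + seq_len(sizes_g[k])
    gene_cursor <- gene_cursor + sizes_g[k]
    ci <- if (scattered_conditions) {
      sort(sample(n, sizes_c[k]))
    } else {
      # evenly spaced phase starts: distinct expression phases of a cycle,
      # disjoint whenever the blocks fit side by side
      K <- length(truth_spec)
      start <- round((k - 1) * (n - sizes_c[k]) / max(K - 1, 1)) + 1L
      start + seq_len(sizes_c[k]) - 1L
    }
    # shared per-column offsets: one magnitude per block drawn from [4, 5],
    # balanced signs in random order. Sign balance keeps the row mean near
    # zero and a single magnitude keeps every block column equally far
    # outside the mean +/- sd band (a weak column next to strong ones would
    # inherit their inflated row sd); the random sign order gives each block
    # its own temporal signature even where condition ranges of different
    # blocks overlap.
    signs <- sample(rep_len(c(1, -1), sizes_c[k]))
    cj <- signs * stats::runif(1, 4, 5)
    block <- matrix(rep(cj, each = sizes_g[k]), sizes_g[k], sizes_c[k])
    if (patterns[k] == "shifting") {
      block <- block + stats::runif(sizes_g[k], -2, 2)
    } else if (patterns[k] == "scaling") {
      block <- block * stats::runif(sizes_g[k], 0.5, 2)
    }
    M[gi, ci] <- block
    bic_rows[[k]] <- tibble(bicluster = k,
                            genes = list(gene_ids[gi]),
                            conditions = list(cond_ids[ci]),
                            pattern = patterns[k])
  }
  if (noise_sd > 0) {
    M <- M + matrix(stats::rnorm(m * n, sd = noise_sd), m, n)
  }
  truth <- structure(list(biclusters = dplyr::bind_rows(bic_rows),
                          complexes = NULL),
                     class = "planted_truth")
  list(expression = M, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  nb <- if (is.null(x$biclusters)) 0 else nrow(x$biclusters)
  nc <- if (is.null(x$complexes)) 0 else nrow(x$complexes)
  cat(sprintf("Planted truth: %d bicluster(s), %d complex(es)\n", nb, nc))
  invisible(x)
}

#' Generate a synthetic PPI network with planted complexes
#'
#' Builds an undirected network whose nodes are all planted-bicluster genes
#' plus `extra_proteins` background proteins. Within each planted complex —
#' a random subset of one planted bicluster's genes — every protein pair is
#' an edge with probability `intra_density`; every other node pair is an
#' edge with probability `background_density`. The planted complexes (and
#' which bicluster each inhabits) are recorded in the returned truth.
#'
#' @param truth A `"planted_truth"` from [gen_expression()] with at least
#'   one planted bicluster.
#' @param extra_proteins Number of background proteins (default 60).
#' @param intra_density Within-complex edge probability (default 0.9).
#' @param background_density All-other-pairs edge probability
#'   (default 0.01); must be below `intra_density`.
#' @param complex_sizes Candidate complex sizes sampled per bicluster
#'   (default `5:10`), capped at the bicluster's gene count.
#' @param n_complexes_per_bicluster Planted complexes per bicluster
#'   (default 1; multiple complexes get disjoint member sets when possible).
#' @param seed Integer seed.
#' @return A list with `network` (a [ppi_network()]) and the augmented
#'   `truth`.
#' @export
gen_ppi <- function(truth, extra_proteins = 60, intra_density = 0.9,
                    background_density = 0.01, complex_sizes = 5:10,
                    n_complexes_per_bicluster = 1, seed = 1) {
  stopifnot(inherits(truth, "planted_truth"),
            background_density >= 0, background_density < intra_density,
            intra_density <= 1)
  if (is.null(truth$biclusters) || nrow(truth$biclusters) == 0) {
    abort("truth has no planted biclusters to host complexes")
  }
  set.seed(derive_seed(seed, 1))
  bic_genes <- truth$biclusters$genes
  nodes <- sort(unique(c(unlist(bic_genes),
                         sprintf("x%03d", seq_len(extra_proteins)))))
  cx_rows <- list()
  for (k in seq_len(nrow(truth$biclusters))) {
    pool <- sort(bic_genes[[k]])
    for (r in seq_len(n_complexes_per_bicluster)) {
      size <- min(length(pool), sample(rep(complex_sizes, 2), 1))
      if (size < 1) break
      members <- sort(sample(pool, size))
      pool <- setdiff(pool, members) # prefer disjoint complexes
      if (length(pool) < min(complex_sizes)) pool <- sort(bic_genes[[k]])
      cx_rows[[length(cx_rows) + 1L]] <-
        tibble(complex = length(cx_rows) + 1L, proteins = list(members),
               bicluster = k)
    }
  }
  complexes <- dplyr::bind_rows(cx_rows)
  # Bernoulli edges over all node pairs; complex-internal pairs are dense.
  pairs <- utils::combn(nodes, 2)
  pair_key <- paste(pairs[1, ], pairs[2, ])
  intra_keys <- unique(unlist(lapply(complexes$proteins, function(p) {
    if (length(p) < 2) return(character(0))
    pr <- utils::combn(sort(p), 2)
    paste(pr[1, ], pr[2, ])
  })))
  p_edge <- ifelse(pair_key %in% intra_keys, intra_density, background_density)
  on <- stats::runif(length(p_edge)) < p_edge
  net <- ppi_network(pairs[1, on], pairs[2, on], proteins = nodes)
  truth$complexes <- complexes
  list(network = net, truth = truth)
}

#' Relevance and recovery of found biclusters against planted truth
#'
#' Gene-set analogues of precision and recall for planted-bicluster
#' experiments: *relevance* is the mean over found biclusters of the best
#' Jaccard index against any planted gene set (are the findings real?);
#' *recovery* is the mean over planted gene sets of the best Jaccard
#' against any found bicluster (were the plants found?). An empty found set
#' scores 0 on both.
#'
#' @param found A `"ga_biclusters"` fit or bicluster tibble.
#' @param truth A `"planted_truth"` with at least one planted bicluster.
#' @return A one-row tibble with `relevance` and `recovery` in `[0, 1]`.
#' @export
recovery_scores <- function(found, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  if (is.null(truth$biclusters) || nrow(truth$biclusters) == 0) {
    abort("truth has no planted biclusters")
  }
  fsets <- as_bicluster_tbl(found)$genes
  tsets <- truth$biclusters$genes
  if (length(fsets) == 0) {
    return(tibble(relevance = 0, recovery = 0))
  }
  best_vs <- function(x, sets) max(vapply(sets, jaccard, numeric(1), b = x))
  tibble(relevance = mean(vapply(fsets, best_vs, numeric(1), sets = tsets)),
         recovery = mean(vapply(tsets, best_vs, numeric(1), sets = fsets)))
}
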