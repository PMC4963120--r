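# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity from first principles (explicit loops, no shared
# code with the package internals) so agreement is meaningful.

# Plain symbol matrix of a discretized_matrix: drops class and metadata
# attributes (and dimnames unless kept) for value-only comparisons.
sym <- function(D, dimnames = FALSE) {
  x <- unclass(D)
  attributes(x) <- if (dimnames) {
    list(dim = dim(x), dimnames = base::dimnames(x))
  } else {
    list(dim = dim(x))
  }
  x
}

# Build a discretized_matrix by hand from a character matrix.
make_disc <- function(symbols, alphabet = if (any(symbols == "N")) 3L else 2L,
                      technique = "manual") {
  if (is.null(rownames(symbols))) {
    rownames(symbols) <- sprintf("g%02d", seq_len(nrow(symbols)))
  }
  if (is.null(colnames(symbols))) {
    colnames(symbols) <- sprintf("c%02d", seq_len(ncol(symbols)))
  }
  structure(symbols, class = c("discretized_matrix", class(symbols)),
            technique = technique, alphabet = as.integer(alphabet),
            params = list())
}

random_disc <- function(m, n, alphabet = 3L) {
  syms <- if (alphabet == 3L) c("D", "N", "U") else c("D", "U")
  make_disc(matrix(sample(syms, m * n, replace = TRUE), m, n), alphabet)
}

# Brute-force DCM: per-column frequency count with explicit loops.
oracle_dcm <- function(symbols, alphabet, alpha) {
  nI <- nrow(symbols)
  total <- 0
  for (j in seq_len(ncol(symbols))) {
    col <- symbols[, j]
    best_sym <- NA_character_
    best_cnt <- 0L
    for (s in unique(col)) {
      cnt <- 0L
      for (x in col) if (x == s) cnt <- cnt + 1L
      if (cnt > best_cnt) {
        best_cnt <- cnt
        best_sym <- s
      }
    }
    fj <- if (best_cnt > nI / 2) {
      if (alphabet == 3L && best_sym == "N") nI / 2 else nI - best_cnt
    } else {
      nI
    }
    total <- total + (1 - (1 + alpha) * fj / nI)
  }
  total
}

# Brute-force existence matcher for complex evaluation.
oracle_evaluate <- function(dsets, bsets, delta) {
  jac <- function(a, b) {
    length(intersect(a, b)) / length(union(a, b))
  }
  dm <- 0L
  for (d in dsets) {
    hit <- FALSE
    for (b in bsets) if (jac(d, b) >= delta) hit <- TRUE
    if (hit) dm <- dm + 1L
  }
  bm <- 0L
  for (b in bsets) {
    hit <- FALSE
    for (d in dsets) if (jac(d, b) >= delta) hit <- TRUE
    if (hit) bm <- bm + 1L
  }
  p <- if (length(dsets) == 0) 0 else dm / length(dsets)
  r <- bm / length(bsets)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f, dm = dm, bm = bm)
}

random_protein_sets <- function(n_sets, pool, min_size = 3, max_size = 8) {
  lapply(seq_len(n_sets), function(i) {
    sample(pool, sample(min_size:max_size, 1))
  })
}

# Small random matrix with dimnames for expression tests.
random_expr <- function(m, n) {
  matrix(stats::rnorm(m * n), m, n,
         dimnames = list(sprintf("g%03d", seq_len(m)),
                         sprintf("t%02d", seq_len(n))))
}

# Random undirected graph as a ppi_network, via independent edge sampling.
random_net <- function(n_nodes, p) {
  nodes <- sprintf("p%02d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  on <- stats::runif(ncol(pairs)) < p
  ppi_network(pairs[1, on], pairs[2, on], proteins = nodes)
}
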