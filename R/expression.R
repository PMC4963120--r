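#' Read a genes-by-time-points expression matrix from TSV
#'
#' Parses a tab-separated expression file whose first row holds the
#' time-point (condition) headers and whose subsequent rows hold one gene
#' identifier followed by one numeric expression value per time-point.
#' Lines starting with `#` and blank lines are skipped. Numbers must use a
#' dot decimal separator regardless of locale.
#'
#' @param path Path to a TSV file. The header line is
#'   `gene<TAB>cond1<TAB>...<TAB>condN`; the leading corner label is
#'   arbitrary and ignored.
#' @return A numeric matrix (genes in rows, time-points in columns) with
#'   gene identifiers as `rownames` and condition identifiers as `colnames`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tt1\tt2", "g1\t0.5\t1.5", "g2\t-1\t2"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path) {
  cl <- read_content_lines(path)
  if (length(cl$lines) < 2) {
    abort(sprintf("'%s': need a header line and at least one gene row", path))
  }
  fields <- strsplit(cl$lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) {
    abort(sprintf("'%s' line %d: header must name at least one condition",
                  path, cl$lineno[1]))
  }
  cond_ids <- header[-1]
  if (anyDuplicated(cond_ids)) {
    abort(sprintf("'%s' line %d: duplicate condition IDs: %s", path,
                  cl$lineno[1],
                  paste(unique(cond_ids[duplicated(cond_ids)]), collapse = ", ")))
  }
  n <- length(cond_ids)
  body <- fields[-1]
  lineno <- cl$lineno[-1]
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = n)
  seen <- new.env(parent = emptyenv())
  for (k in seq_along(body)) {
    row <- body[[k]]
    if (length(row) != n + 1L) {
      abort(sprintf("'%s' line %d: expected %d fields, found %d",
                    path, lineno[k], n + 1L, length(row)))
    }
    gid <- row[1]
    if (!is.null(seen[[gid]])) {
      abort(sprintf("'%s' line %d: duplicate gene ID '%s'", path, lineno[k], gid))
    }
    assign(gid, TRUE, envir = seen)
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals) || any(!is.finite(vals))) {
      bad <- which(is.na(vals) | !is.finite(vals))[1]
      abort(sprintf("'%s' line %d: non-numeric value '%s' in column %d",
                    path, lineno[k], row[bad + 1L], bad))
    }
    gene_ids[k] <- gid
    values[k, ] <- vals
  }
  dimnames(values) <- list(gene_ids, cond_ids)
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: writes the header line followed by
#' one row per gene. An optional comment block (prefixed `#`) can carry
#' provenance; readers skip it.
#'
#' @param M Numeric matrix with gene rownames and condition colnames.
#' @param path Output file path.
#' @param comments Optional character vector written as `#`-prefixed lines
#'   before the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(M, path, comments = NULL) {
  stopifnot(is.matrix(M), !is.null(rownames(M)), !is.null(colnames(M)))
  hdr <- paste(c("gene", colnames(M)), collapse = "\t")
  body <- vapply(seq_len(nrow(M)), function(i) {
    paste(c(rownames(M)[i], format(M[i, ], trim = TRUE, digits = 15,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  out <- c(if (length(comments)) paste0("# ", comments), hdr, body)
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Row-normalize an expression matrix to z-scores
#'
#' Centres and scales every gene's profile to mean 0 and standard deviation 1
#' using the population standard deviation (divisor n). Constant rows cannot
#' be scaled; they map to all-zeros and are reported with a warning, since
#' flat probes are common in real microarray matrices.
#'
#' @param M Numeric genes-by-conditions matrix with dimnames.
#' @return A numeric matrix of class `"normalized_matrix"` with the same
#'   dimnames; attribute `constant_rows` lists the gene IDs of any flat rows.
#' @examples
#' M <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
#' rowMeans(normalize_rows(M))
#' @export
normalize_rows <- function(M) {
  stopifnot(is.matrix(M), is.numeric(M), nrow(M) >= 1, ncol(M) >= 1)
  if (any(!is.finite(M))) abort("expression matrix contains non-finite values")
  mu <- rowMeans(M)
  sdv <- sqrt(rowMeans((M - mu)^2))
  const <- sdv == 0
  sdv[const] <- 1 # rows centred to zero already; avoids 0/0
  Z <- (M - mu) / sdv
  if (any(const)) {
    warn(sprintf("%d constant row(s) normalized to all-zeros: %s",
                 sum(const),
                 paste(utils::head(rownames(M)[const], 5), collapse = ", ")))
  }
  structure(Z, class = c("normalized_matrix", class(Z)),
            constant_rows = rownames(M)[const])
}

is_normalized <- function(x) inherits(x, "normalized_matrix")

new_discretized <- function(symbols, technique, alphabet, params) {
  structure(symbols, class = c("discretized_matrix", class(symbols)),
            technique = technique, alphabet = as.integer(alphabet),
            params = params)
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat(sprintf("Discretized expression matrix: %d genes x %d time-points\n",
              nrow(x), ncol(x)))
  cat(sprintf("  technique: %s, alphabet: {%s}\n", attr(x, "technique"),
              paste(sort(unique(as.vector(unclass(x)))), collapse = ", ")))
  invisible(x)
}

#' Discretize with a single global threshold
#'
#' Binary up/down coding: a cell becomes `U` (up-regulated) when its raw
#' expression value is strictly higher than the threshold `t`, otherwise `D`
#' (down-regulated). Ties at the threshold are `D`.
#'
#' @param M Numeric expression matrix with dimnames.
#' @param t Finite threshold on the raw expression scale.
#' @return A character matrix of class `"discretized_matrix"` over `{D, U}`.
#' @export
discretize_simple_threshold <- function(M, t) {
  stopifnot(is.matrix(M), is.numeric(M), is.finite(t))
  S <- ifelse(M > t, "U", "D")
  dimnames(S) <- dimnames(M)
  new_discretized(S, "simple_threshold", 2L, list(t = t))
}

#' Discretize by per-gene mean and standard deviation bands
#'
#' Three-letter coding per gene: with row mean `mu_i` and population standard
#' deviation `sigma_i`, a cell is `D` below `mu_i - alpha_disc * sigma_i`,
#' `U` above `mu_i + alpha_disc * sigma_i`, and `N` (no regulation) inside
#' the band. Strict inequalities: band-edge ties are `N`. A constant gene
#' (zero sd) is entirely `N`.
#'
#' This is the pipeline's default technique: the fitness function's special
#' rule for a majority of `N` symbols presumes a three-letter alphabet.
#'
#' @param M Numeric expression matrix with dimnames.
#' @param alpha_disc Positive band half-width in units of the row sd
#'   (default 1). Distinct from the fitness penalty `alpha_penalty`.
#' @return A `"discretized_matrix"` over `{D, N, U}`.
#' @export
discretize_mean_sd <- function(M, alpha_disc = 1) {
  stopifnot(is.matrix(M), is.numeric(M), alpha_disc > 0)
  mu <- rowMeans(M)
  sdv <- sqrt(rowMeans((M - mu)^2))
  lo <- mu - alpha_disc * sdv
  hi <- mu + alpha_disc * sdv
  S <- matrix("N", nrow(M), ncol(M), dimnames = dimnames(M))
  S[M < lo] <- "D"
  S[M > hi] <- "U"
  new_discretized(S, "mean_sd", 3L, list(alpha_disc = alpha_disc))
}

#' Discretize by transitional state (sign of the z-score)
#'
#' Binary coding on the row-normalized matrix: `U` where the z-score is
#' strictly positive, `D` otherwise (zero included).
#'
#' @param Mn A matrix produced by [normalize_rows()].
#' @return A `"discretized_matrix"` over `{D, U}`.
#' @export
discretize_transitional_state <- function(Mn) {
  if (!is_normalized(Mn)) abort("`Mn` must come from normalize_rows()")
  S <- ifelse(unclass(Mn) > 0, "U", "D")
  dimnames(S) <- dimnames(Mn)
  new_discretized(S, "transitional_state", 2L, list())
}

#' Discretize by variation between consecutive time-points
#'
#' Codes each cell by the change from the previous time-point of the
#' row-normalized matrix. In the binary case the threshold `beta` is
#' computed as `alpha_disc` times the population standard deviation of the
#' first time-point's normalized values over all genes, and a cell is `U`
#' when its difference from the previous time-point strictly exceeds `beta`,
#' else `D`. In the three-letter case `beta` is supplied directly and the
#' coding is `U` above `beta`, `D` below `-beta`, `N` otherwise. The first
#' time-point has no predecessor and is assigned `D` (binary) or `N`
#' (three-letter) so the matrix stays rectangular.
#'
#' @param Mn A matrix produced by [normalize_rows()] with at least two
#'   time-points.
#' @param alphabet 2 or 3.
#' @param alpha_disc Multiplier for the first-column sd (binary case).
#' @param beta Direct threshold (three-letter case).
#' @return A `"discretized_matrix"` over `{D, U}` or `{D, N, U}`.
#' @export
discretize_variation <- function(Mn, alphabet = c(3, 2), alpha_disc = 1,
                                 beta = NULL) {
  if (!is_normalized(Mn)) abort("`Mn` must come from normalize_rows()")
  alphabet <- as.integer(alphabet[1])
  stopifnot(alphabet %in% c(2L, 3L))
  if (ncol(Mn) < 2) abort("variation discretization needs at least 2 time-points")
  Z <- unclass(Mn)
  diffs <- Z[, -1, drop = FALSE] - Z[, -ncol(Z), drop = FALSE]
  if (alphabet == 2L) {
    stopifnot(is.numeric(alpha_disc), alpha_disc >= 0)
    beta <- alpha_disc * sd_pop(Z[, 1])
    Sd <- ifelse(diffs > beta, "U", "D")
    S <- cbind(matrix("D", nrow(Z), 1), Sd)
    params <- list(alpha_disc = alpha_disc, beta = beta)
  } else {
    if (is.null(beta)) abort("three-letter variation coding needs `beta`")
    Sd <- matrix("N", nrow(diffs), ncol(diffs))
    Sd[diffs > beta] <- "U"
    Sd[diffs < -beta] <- "D"
    S <- cbind(matrix("N", nrow(Z), 1), Sd)
    params <- list(beta = beta)
  }
  dimnames(S) <- dimnames(Mn)
  new_discretized(S, "variation", alphabet, params)
}

#' Discretize an expression matrix with a named technique
#'
#' Convenience dispatcher used by the pipeline. `simple_threshold` and
#' `mean_sd` operate on the raw matrix; `transitional_state` and `variation`
#' first row-normalize it.
#'
#' @param M Numeric expression matrix with dimnames.
#' @param technique One of `"mean_sd"` (default), `"simple_threshold"`,
#'   `"transitional_state"`, `"variation"`.
#' @param ... Passed to the technique function (`t`, `alpha_disc`,
#'   `alphabet`, `beta`).
#' @return A `"discretized_matrix"`.
#' @export
discretize <- function(M, technique = c("mean_sd", "simple_threshold",
                                        "transitional_state", "variation"),
                       ...) {
  technique <- match.arg(technique)
  switch(technique,
    simple_threshold   = discretize_simple_threshold(M, ...),
    mean_sd            = discretize_mean_sd(M, ...),
    transitional_state = discretize_transitional_state(suppressWarnings(normalize_rows(M)), ...),
    variation          = discretize_variation(suppressWarnings(normalize_rows(M)), ...)
  )
}

#' Write a discretized matrix as TSV
#'
#' Same layout as the expression TSV, with single-character `D`/`N`/`U`
#' cells; technique and parameters are recorded in `#` comment lines.
#'
#' @param D A `"discretized_matrix"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_discretized <- function(D, path) {
  stopifnot(inherits(D, "discretized_matrix"))
  params <- attr(D, "params")
  meta <- sprintf("technique=%s alphabet=%d %s", attr(D, "technique"),
                  attr(D, "alphabet"),
                  paste(names(params), unlist(params), sep = "=", collapse = " "))
  hdr <- paste(c("gene", colnames(D)), collapse = "\t")
  body <- vapply(seq_len(nrow(D)), function(i) {
    paste(c(rownames(D)[i], D[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(paste0("# ", meta), hdr, body), path, useBytes = TRUE)
  invisible(path)
}
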