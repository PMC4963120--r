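#' Configuration for the genetic biclustering algorithm
#'
#' Collects the hyperparameters of the binary-encoded GA that searches for
#' high-fitness biclusters of a discretized expression matrix. Defaults are
#' standard GA practice for this problem size; see the methods vignette for
#' the rationale behind each.
#'
#' @param population_size Chromosomes per generation (default 200).
#' @param generations Maximum generations per restart (default 100).
#' @param crossover_prob Probability a selected parent pair is recombined
#'   (default 0.85).
#' @param mutation_prob Per-bit flip probability; `NULL` (default) resolves
#'   to `1 / (m + n)` at run time.
#' @param alpha_penalty Fitness penalty factor in (0, 1) (default 0.1).
#' @param elitism_count Top chromosomes copied unchanged into the next
#'   generation (default 2).
#' @param stall_generations Stop a restart after this many generations
#'   without best-fitness improvement (default 20).
#' @param init_gene_prob,init_cond_prob Per-bit set probability at
#'   initialization (defaults 0.05 and 0.5: planted co-regulation involves
#'   few genes but often many time-points).
#' @param n_restarts Independent GA runs whose harvests are pooled
#'   (default 10).
#' @param min_genes,min_conditions Minimum bicluster dimensions enforced by
#'   repair (defaults 3 and 2).
#' @param harvest_fraction Keep final-population chromosomes whose fitness
#'   is at least this fraction of the run best (default 0.9).
#' @param consolidate_harvest If `TRUE` (default), each harvested
#'   chromosome's gene set is completed to the maximal set of genes matching
#'   its columns' majority pattern before deduplication (see Details).
#' @param seed Integer seed; restart `r` uses `seed + r - 1`.
#'
#' @details
#' The fitness is invariant to adding genes that agree with every selected
#' column's majority, so a population can drift among partial versions of
#' the same underlying bicluster. Harvest consolidation resolves this: for
#' each harvested chromosome the strict majority symbol of every selected
#' column is computed over its genes, and the gene set is redefined as all
#' matrix genes agreeing with that signature at more than half of the
#' columns with a non-`N` majority — the same majority logic the fitness
#' applies within columns, which keeps the completion robust to sporadic
#' noise-induced symbol flips (columns whose majority is `N`, or that have
#' none, carry no signature and are ignored; if no column has a non-`N`
#' majority, or fewer than `min_genes` genes match, the chromosome is kept
#' as-is). Partial
#' discoveries of one coherent bicluster thereby complete to the same
#' maximal gene set and collapse in deduplication.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 200, generations = 100,
                      crossover_prob = 0.85, mutation_prob = NULL,
                      alpha_penalty = 0.1, elitism_count = 2,
                      stall_generations = 20, init_gene_prob = 0.05,
                      init_cond_prob = 0.5, n_restarts = 10,
                      min_genes = 3, min_conditions = 2,
                      harvest_fraction = 0.9, consolidate_harvest = TRUE,
                      seed = 1) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              crossover_prob = crossover_prob, mutation_prob = mutation_prob,
              alpha_penalty = alpha_penalty, tournament_size = 2L,
              elitism_count = as.integer(elitism_count),
              stall_generations = as.integer(stall_generations),
              init_gene_prob = init_gene_prob, init_cond_prob = init_cond_prob,
              n_restarts = as.integer(n_restarts),
              min_genes = as.integer(min_genes),
              min_conditions = as.integer(min_conditions),
              harvest_fraction = harvest_fraction,
              consolidate_harvest = isTRUE(consolidate_harvest),
              seed = as.integer(seed))
  stopifnot(cfg$population_size >= 2, cfg$generations >= 1,
            cfg$crossover_prob >= 0, cfg$crossover_prob <= 1,
            is.null(cfg$mutation_prob) ||
              (cfg$mutation_prob >= 0 && cfg$mutation_prob <= 1),
            cfg$alpha_penalty > 0, cfg$alpha_penalty < 1,
            cfg$elitism_count >= 0, cfg$stall_generations >= 1,
            cfg$init_gene_prob > 0, cfg$init_gene_prob <= 1,
            cfg$init_cond_prob > 0, cfg$init_cond_prob <= 1,
            cfg$n_restarts >= 1, cfg$harvest_fraction > 0,
            cfg$harvest_fraction <= 1)
  structure(cfg, class = "ga_config")
}

# --- chromosome primitives --------------------------------------------------
# A chromosome is a pair of logical masks (genes, conditions) plus a cached
# fitness. The exported operators work on single chromosomes; the GA loop
# applies the same part-level primitives row-wise.

new_chromosome <- function(genes, conditions, fitness = NA_real_) {
  structure(list(genes = as.logical(genes), conditions = as.logical(conditions),
                 fitness = fitness), class = "chromosome")
}

repair_part <- function(bits, minimum) {
  if (minimum > length(bits)) {
    abort(sprintf("minimum size %d exceeds mask length %d", minimum, length(bits)))
  }
  deficit <- minimum - sum(bits)
  if (deficit > 0) {
    zeros <- which(!bits)
    add <- if (length(zeros) == 1) zeros else sample(zeros, deficit)
    bits[add] <- TRUE
  }
  bits
}

cross_part <- function(x1, x2) {
  L <- length(x1)
  cuts <- sort(sample(0:L, 2))
  if (cuts[1] < cuts[2]) {
    seg <- (cuts[1] + 1):cuts[2]
    tmp <- x1[seg]
    x1[seg] <- x2[seg]
    x2[seg] <- tmp
  }
  list(x1, x2)
}

mutate_part <- function(bits, prob) {
  xor(bits, stats::runif(length(bits)) < prob)
}

#' Repair a chromosome to the minimum bicluster dimensions
#'
#' If either mask has fewer set bits than its minimum, uniformly chosen
#' additional bits are set until the minimum holds. Feasible chromosomes are
#' returned unchanged.
#'
#' @param chrom A chromosome (see [init_population()]).
#' @param min_genes,min_conditions Minimum set bits per part.
#' @return The repaired chromosome (fitness cleared if it changed).
#' @export
repair_chromosome <- function(chrom, min_genes = 3, min_conditions = 2) {
  g <- repair_part(chrom$genes, min_genes)
  co <- repair_part(chrom$conditions, min_conditions)
  changed <- !identical(g, chrom$genes) || !identical(co, chrom$conditions)
  new_chromosome(g, co, if (changed) NA_real_ else chrom$fitness)
}

#' Initialize a random GA population
#'
#' Draws `population_size` chromosomes with each gene bit set independently
#' with probability `init_gene_prob` and each condition bit with
#' `init_cond_prob`, then repairs each to the minimum dimensions. Uses R's
#' global RNG: call `set.seed()` for reproducibility.
#'
#' @param cfg A [ga_config()].
#' @param m,n Numbers of genes and conditions in the discretized matrix.
#' @return A list of chromosomes.
#' @export
init_population <- function(cfg, m, n) {
  stopifnot(inherits(cfg, "ga_config"), m >= 1, n >= 1)
  lapply(seq_len(cfg$population_size), function(i) {
    repair_chromosome(
      new_chromosome(stats::runif(m) < cfg$init_gene_prob,
                     stats::runif(n) < cfg$init_cond_prob),
      cfg$min_genes, cfg$min_conditions)
  })
}

#' Binary tournament selection
#'
#' Draws two chromosomes uniformly with replacement and returns the one with
#' the higher fitness (ties go to the first drawn).
#'
#' @param population List of chromosomes with evaluated fitness.
#' @return The selected chromosome.
#' @export
binary_tournament_select <- function(population) {
  if (length(population) == 0) abort("empty population")
  idx <- sample(length(population), 2, replace = TRUE)
  f1 <- population[[idx[1]]]$fitness
  f2 <- population[[idx[2]]]$fitness
  if (is.na(f1) || is.na(f2)) abort("tournament requires evaluated fitness")
  if (f2 > f1) population[[idx[2]]] else population[[idx[1]]]
}

#' Dual two-point crossover
#'
#' Recombines two parents by exchanging a randomly chosen segment, picked
#' independently for the gene part and the condition part. Children are
#' returned unrepaired; repair happens after mutation in the GA loop.
#'
#' @param p1,p2 Parent chromosomes with equal mask lengths.
#' @return A list of two children.
#' @export
two_point_crossover <- function(p1, p2) {
  stopifnot(length(p1$genes) == length(p2$genes),
            length(p1$conditions) == length(p2$conditions))
  g <- cross_part(p1$genes, p2$genes)
  co <- cross_part(p1$conditions, p2$conditions)
  list(new_chromosome(g[[1]], co[[1]]), new_chromosome(g[[2]], co[[2]]))
}

#' Bit-flip mutation
#'
#' Flips every bit of both parts independently with probability
#' `mutation_prob`, then repairs to the minimum dimensions.
#'
#' @param chrom A chromosome.
#' @param mutation_prob Per-bit flip probability in `[0, 1]`.
#' @param min_genes,min_conditions Repair minima (default 1 each).
#' @return The mutated, repaired chromosome.
#' @export
mutate_chromosome <- function(chrom, mutation_prob, min_genes = 1,
                              min_conditions = 1) {
  stopifnot(mutation_prob >= 0, mutation_prob <= 1)
  repair_chromosome(
    new_chromosome(mutate_part(chrom$genes, mutation_prob),
                   mutate_part(chrom$conditions, mutation_prob)),
    min_genes, min_conditions)
}

#' Complete a bicluster's gene set to its majority signature
#'
#' Computes the strict majority symbol of every selected column over the
#' current gene set and redefines the gene set as all genes of the matrix
#' that match the majority at every column with a non-`N` majority — the
#' maximal gene set carrying the same regulation signature. Columns with an
#' `N` majority or no majority carry no signature and do not constrain the
#' completion. If no column has a non-`N` majority, or fewer than
#' `min_genes` genes match, the input gene set is returned unchanged.
#'
#' @param Md A `"discretized_matrix"`.
#' @param genes,conditions The bicluster's members.
#' @param min_genes Minimum completed size (default 3).
#' @details A gene is kept when it agrees with the signature at strictly
#'   more than half of the signature columns — the fitness's own majority
#'   logic, applied across columns — so sporadic noise-induced flips do not
#'   exclude genuine members.
#' @return A character vector of gene IDs (matrix row order).
#' @export
consolidate_bicluster <- function(Md, genes, conditions, min_genes = 3) {
  S <- unclass(Md)
  sub <- S[genes, conditions, drop = FALSE]
  nI <- length(genes)
  maj <- apply(sub, 2, function(col) {
    counts <- table(col)
    if (max(counts) * 2 > nI) names(counts)[which.max(counts)] else NA_character_
  })
  sig_cols <- conditions[!is.na(maj) & maj != "N"]
  if (length(sig_cols) == 0) return(genes)
  sig <- maj[match(sig_cols, conditions)]
  hits <- rowSums(S[, sig_cols, drop = FALSE] ==
                    matrix(sig, nrow(S), length(sig), byrow = TRUE))
  completed <- rownames(S)[hits * 2 > length(sig_cols)]
  if (length(completed) < min_genes) genes else completed
}

# --- GA main loop -----------------------------------------------------------

# One restart on 0/1 mask matrices; returns harvested masks + history rows.
run_ga_once <- function(ind, m, n, cfg, pm) {
  P <- cfg$population_size
  pop_g <- matrix(stats::runif(P * m) < cfg$init_gene_prob, P, m) * 1
  pop_c <- matrix(stats::runif(P * n) < cfg$init_cond_prob, P, n) * 1
  for (i in seq_len(P)) {
    pop_g[i, ] <- repair_part(pop_g[i, ] > 0, cfg$min_genes) * 1
    pop_c[i, ] <- repair_part(pop_c[i, ] > 0, cfg$min_conditions) * 1
  }
  fit <- dcm_fitness_population(pop_g, pop_c, ind, cfg$alpha_penalty)
  best <- max(fit)
  stall <- 0L
  history <- list(c(generation = 0, best = best, mean = mean(fit)))
  for (gen in seq_len(cfg$generations)) {
    ord <- order(fit, decreasing = TRUE)
    new_g <- matrix(0, P, m)
    new_c <- matrix(0, P, n)
    n_elite <- min(cfg$elitism_count, P)
    if (n_elite > 0) {
      new_g[seq_len(n_elite), ] <- pop_g[ord[seq_len(n_elite)], , drop = FALSE]
      new_c[seq_len(n_elite), ] <- pop_c[ord[seq_len(n_elite)], , drop = FALSE]
    }
    k <- n_elite
    while (k < P) {
      pick <- function() {
        ij <- sample(P, 2, replace = TRUE)
        if (fit[ij[2]] > fit[ij[1]]) ij[2] else ij[1]
      }
      i1 <- pick(); i2 <- pick()
      g1 <- pop_g[i1, ] > 0; c1 <- pop_c[i1, ] > 0
      g2 <- pop_g[i2, ] > 0; c2 <- pop_c[i2, ] > 0
      if (stats::runif(1) < cfg$crossover_prob) {
        gs <- cross_part(g1, g2); cs <- cross_part(c1, c2)
        g1 <- gs[[1]]; g2 <- gs[[2]]; c1 <- cs[[1]]; c2 <- cs[[2]]
      }
      for (child in list(list(g1, c1), list(g2, c2))) {
        if (k >= P) break
        k <- k + 1L
        cg <- repair_part(mutate_part(child[[1]], pm), cfg$min_genes)
        cc <- repair_part(mutate_part(child[[2]], pm), cfg$min_conditions)
        new_g[k, ] <- cg * 1
        new_c[k, ] <- cc * 1
      }
    }
    pop_g <- new_g
    pop_c <- new_c
    fit <- dcm_fitness_population(pop_g, pop_c, ind, cfg$alpha_penalty)
    gen_best <- max(fit)
    if (gen_best > best + 1e-12) {
      best <- gen_best
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    history[[length(history) + 1L]] <- c(generation = gen, best = max(best, gen_best),
                                         mean = mean(fit))
    if (stall >= cfg$stall_generations) break
  }
  threshold <- if (best > 0) cfg$harvest_fraction * best else best
  keep <- which(fit >= threshold - 1e-12)
  key <- paste(apply(pop_g[keep, , drop = FALSE], 1, paste, collapse = ""),
               apply(pop_c[keep, , drop = FALSE], 1, paste, collapse = ""))
  keep <- keep[!duplicated(key)]
  list(gene_masks = pop_g[keep, , drop = FALSE],
       cond_masks = pop_c[keep, , drop = FALSE],
       fitness = fit[keep],
       history = do.call(rbind, history))
}

#' Evolve biclusters of a discretized expression matrix
#'
#' Runs `n_restarts` independent genetic-algorithm searches over binary
#' bicluster encodings of `Md`, each with tournament selection, dual
#' two-point crossover, bit-flip mutation, elitism-preserving generational
#' replacement and an early stop after `stall_generations` without
#' improvement. From each restart's final population every distinct
#' chromosome scoring at least `harvest_fraction` of the run best is
#' harvested; the pooled harvest, deduplicated and sorted by descending
#' fitness, is returned.
#'
#' @param Md A `"discretized_matrix"`.
#' @param config A [ga_config()].
#' @return An object of class `"ga_biclusters"`: a list with
#'   `biclusters` (tibble with list-columns `genes`, `conditions` and the
#'   fitness `dcm`), `history` (per-restart, per-generation best/mean
#'   fitness) and the resolved `config`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' sim <- gen_expression(m = 40, n = 8,
#'                       truth_spec = list(list(10, 4, "constant_column")),
#'                       noise_sd = 0, seed = 7)
#' fit <- run_ga(discretize_mean_sd(sim$expression),
#'               ga_config(population_size = 40, generations = 20,
#'                         n_restarts = 2, seed = 7))
#' tidy(fit)
#' @export
run_ga <- function(Md, config = ga_config()) {
  stopifnot(inherits(Md, "discretized_matrix"), inherits(config, "ga_config"))
  m <- nrow(Md)
  n <- ncol(Md)
  if (config$min_genes > m || config$min_conditions > n) {
    abort("minimum bicluster dimensions exceed the matrix dimensions")
  }
  pm <- config$mutation_prob %||% (1 / (m + n))
  ind <- dcm_indicators(Md)
  harvests <- vector("list", config$n_restarts)
  hist_rows <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    set.seed(derive_seed(config$seed, r - 1))
    res <- run_ga_once(ind, m, n, config, pm)
    harvests[[r]] <- res
    hist_rows[[r]] <- tibble(restart = r,
                             generation = res$history[, "generation"],
                             best = res$history[, "best"],
                             mean = res$history[, "mean"])
  }
  gene_masks <- do.call(rbind, lapply(harvests, `[[`, "gene_masks"))
  cond_masks <- do.call(rbind, lapply(harvests, `[[`, "cond_masks"))
  fitness <- unlist(lapply(harvests, `[[`, "fitness"))
  restart <- rep(seq_len(config$n_restarts),
                 vapply(harvests, function(h) length(h$fitness), integer(1)))
  gene_sets <- lapply(seq_len(nrow(gene_masks)),
                      function(i) rownames(Md)[gene_masks[i, ] > 0])
  cond_sets <- lapply(seq_len(nrow(cond_masks)),
                      function(i) colnames(Md)[cond_masks[i, ] > 0])
  if (config$consolidate_harvest) {
    gene_sets <- purrr::map2(gene_sets, cond_sets, function(g, co) {
      consolidate_bicluster(Md, g, co, config$min_genes)
    })
    fitness <- purrr::map2_dbl(gene_sets, cond_sets, function(g, co) {
      dcm_fitness(Md, g, co, config$alpha_penalty)
    })
  }
  key <- paste(vapply(gene_sets, set_key, character(1)),
               vapply(cond_sets, set_key, character(1)))
  keep <- !duplicated(key)
  ord <- order(-fitness[keep])
  idx <- which(keep)[ord]
  bics <- tibble(
    bicluster_id = seq_along(idx),
    genes = gene_sets[idx],
    conditions = cond_sets[idx],
    dcm = fitness[idx],
    restart = restart[idx]
  )
  bics$n_genes <- lengths(bics$genes)
  bics$n_conditions <- lengths(bics$conditions)
  cfg_resolved <- config
  cfg_resolved$mutation_prob <- pm
  structure(list(biclusters = bics,
                 history = dplyr::bind_rows(hist_rows),
                 config = cfg_resolved),
            class = "ga_biclusters")
}

#' @export
print.ga_biclusters <- function(x, ...) {
  cat(sprintf("GA biclustering fit: %d harvested bicluster(s), %d restart(s)\n",
              nrow(x$biclusters), x$config$n_restarts))
  if (nrow(x$biclusters)) {
    cat(sprintf("  best DCM %.3f (%d genes x %d conditions)\n",
                x$biclusters$dcm[1], x$biclusters$n_genes[1],
                x$biclusters$n_conditions[1]))
  }
  invisible(x)
}

as_bicluster_tbl <- function(x) {
  if (inherits(x, "ga_biclusters")) x$biclusters
  else if (is.data.frame(x)) x
  else abort("expected a ga_biclusters fit or a bicluster tibble")
}

#' Filter small or weakly coherent biclusters
#'
#' Keeps biclusters with at least `min_genes` genes, `min_conditions`
#' conditions, and fitness at least `min_dcm_fraction` of its maximum
#' attainable value `|J|` — a coherence proxy for biological significance.
#'
#' @param x A `"ga_biclusters"` fit or a bicluster tibble.
#' @param min_genes,min_conditions Minimum dimensions (defaults 3 and 2).
#' @param min_dcm_fraction Minimum `dcm / |J|` (default 0.5).
#' @return The filtered bicluster tibble.
#' @export
filter_biclusters <- function(x, min_genes = 3, min_conditions = 2,
                              min_dcm_fraction = 0.5) {
  bics <- as_bicluster_tbl(x)
  if (nrow(bics) == 0) return(bics)
  keep <- lengths(bics$genes) >= min_genes &
    lengths(bics$conditions) >= min_conditions &
    bics$dcm >= min_dcm_fraction * lengths(bics$conditions)
  bics[keep, , drop = FALSE]
}

#' Jaccard index of two sets
#'
#' `|A n B| / |A u B|` on unique elements.
#'
#' @param a,b Character vectors; at least one must be nonempty.
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) abort("jaccard of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Remove gene-set-redundant biclusters
#'
#' Greedy deduplication by descending fitness: a bicluster is dropped when
#' its gene-set Jaccard index with an already-kept bicluster reaches
#' `overlap_threshold`. Redundancy is measured on gene sets only because the
#' downstream subnetworks are induced by genes alone.
#'
#' @param x A `"ga_biclusters"` fit or a bicluster tibble.
#' @param overlap_threshold Jaccard threshold in (0, 1] (default 0.75).
#' @return The retained bicluster tibble (descending `dcm`).
#' @export
remove_redundant <- function(x, overlap_threshold = 0.75) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  bics <- as_bicluster_tbl(x)
  if (nrow(bics) == 0) return(bics)
  bics <- bics[order(-bics$dcm), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(bics))) {
    redundant <- any(vapply(kept, function(k) {
      jaccard(bics$genes[[i]], bics$genes[[k]]) >= overlap_threshold
    }, logical(1)))
    if (!redundant) kept <- c(kept, i)
  }
  bics[kept, , drop = FALSE]
}

#' Write a bicluster set to a text file
#'
#' One record per bicluster: `>bicluster_<k> dcm=<value>`, then a line of
#' tab-separated gene IDs, then a line of tab-separated condition IDs.
#' `#`-prefixed header lines can carry provenance.
#'
#' @param x A `"ga_biclusters"` fit or bicluster tibble.
#' @param path Output file path.
#' @param comments Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(x, path, comments = NULL) {
  bics <- as_bicluster_tbl(x)
  out <- if (length(comments)) paste0("# ", comments) else character(0)
  for (i in seq_len(nrow(bics))) {
    out <- c(out,
             sprintf(">bicluster_%d dcm=%.10g", bics$bicluster_id[i], bics$dcm[i]),
             paste(bics$genes[[i]], collapse = "\t"),
             paste(bics$conditions[[i]], collapse = "\t"))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a bicluster set written by [write_biclusters()]
#'
#' @param path Input file path.
#' @return A bicluster tibble.
#' @export
read_biclusters <- function(path) {
  cl <- read_content_lines(path)
  lines <- cl$lines
  starts <- grep("^>", lines)
  if (length(lines) && length(starts) == 0) {
    abort(sprintf("'%s': no '>bicluster' records found", path))
  }
  recs <- lapply(seq_along(starts), function(k) {
    s <- starts[k]
    if (s + 2 > length(lines)) {
      abort(sprintf("'%s' line %d: truncated bicluster record", path, cl$lineno[s]))
    }
    dcm <- as.numeric(sub("^>\\S+\\s+dcm=", "", lines[s]))
    list(genes = strsplit(lines[s + 1], "\t", fixed = TRUE)[[1]],
         conditions = strsplit(lines[s + 2], "\t", fixed = TRUE)[[1]],
         dcm = dcm)
  })
  tibble(
    bicluster_id = seq_along(recs),
    genes = lapply(recs, `[[`, "genes"),
    conditions = lapply(recs, `[[`, "conditions"),
    dcm = vapply(recs, `[[`, numeric(1), "dcm"),
    n_genes = vapply(recs, function(r) length(r$genes), integer(1)),
    n_conditions = vapply(recs, function(r) length(r$conditions), integer(1))
  )
}
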