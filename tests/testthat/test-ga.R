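chrom <- function(g, co, fit = NA_real_) {
  dynbic:::new_chromosome(g, co, fit)
}

test_that("ga_config validates its bounds", {
  expect_s3_class(ga_config(), "ga_config")
  expect_error(ga_config(population_size = 1))
  expect_error(ga_config(alpha_penalty = 1))
  expect_error(ga_config(crossover_prob = 1.5))
  expect_error(ga_config(harvest_fraction = 0))
})

test_that("population initialization respects sizes, minima and the seed", {
  cfg <- ga_config(population_size = 10, min_genes = 2, min_conditions = 2)
  set.seed(5)
  pop <- init_population(cfg, m = 30, n = 8)
  expect_length(pop, 10)
  for (p in pop) {
    expect_gte(sum(p$genes), 2)
    expect_gte(sum(p$conditions), 2)
  }
  set.seed(5)
  pop2 <- init_population(cfg, m = 30, n = 8)
  expect_identical(pop, pop2)

  cfg1 <- ga_config(population_size = 5, init_gene_prob = 1)
  set.seed(6)
  pop3 <- init_population(cfg1, m = 12, n = 4)
  expect_true(all(vapply(pop3, function(p) all(p$genes), logical(1))))
})

test_that("repair adds exactly the missing bits and leaves feasible masks alone", {
  set.seed(9)
  zero <- chrom(rep(FALSE, 10), rep(FALSE, 6))
  r <- repair_chromosome(zero, 2, 2)
  expect_equal(sum(r$genes), 2)
  expect_equal(sum(r$conditions), 2)

  ok <- chrom(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, TRUE), fit = 1.5)
  expect_identical(repair_chromosome(ok, 2, 1), ok)

  full <- repair_chromosome(chrom(rep(FALSE, 4), rep(TRUE, 3)), 4, 1)
  expect_true(all(full$genes))
  expect_error(repair_chromosome(zero, 11, 1), "exceeds mask length")
})

test_that("binary tournament prefers the fitter of two uniform draws", {
  a <- chrom(c(TRUE, FALSE), c(TRUE), fit = 5)
  b <- chrom(c(FALSE, TRUE), c(TRUE), fit = 1)
  expect_identical(binary_tournament_select(list(a)), a)
  expect_error(binary_tournament_select(list(chrom(TRUE, TRUE))),
               "evaluated fitness")

  # P(fitter wins) = 1 - P(draw loser twice) = 3/4
  set.seed(10)
  wins <- 0L
  n_draw <- 10000L
  for (i in seq_len(n_draw)) {
    if (binary_tournament_select(list(a, b))$fitness == 5) wins <- wins + 1L
  }
  se <- sqrt(0.75 * 0.25 / n_draw)
  expect_lt(abs(wins / n_draw - 0.75), 3 * se)

  # equal fitness everywhere: uniform selection within sampling error
  pop <- lapply(1:4, function(i) {
    g <- rep(FALSE, 4); g[i] <- TRUE
    chrom(g, c(TRUE), fit = 2)
  })
  set.seed(11)
  picks <- table(vapply(seq_len(n_draw), function(i) {
    which(binary_tournament_select(pop)$genes)
  }, integer(1)))
  expect_gt(stats::chisq.test(picks)$p.value, 1e-4)
})

test_that("two-point crossover exchanges segments and conserves locus multisets", {
  set.seed(12)
  p <- chrom(stats::runif(20) < 0.5, stats::runif(8) < 0.5)
  kids_same <- two_point_crossover(p, p)
  expect_identical(kids_same[[1]]$genes, p$genes)
  expect_identical(kids_same[[2]]$conditions, p$conditions)

  for (rep in 1:25) {
    p1 <- chrom(stats::runif(20) < 0.5, stats::runif(8) < 0.5)
    p2 <- chrom(stats::runif(20) < 0.5, stats::runif(8) < 0.5)
    kids <- two_point_crossover(p1, p2)
    for (part in c("genes", "conditions")) {
      parents <- rbind(p1[[part]], p2[[part]])
      children <- rbind(kids[[1]][[part]], kids[[2]][[part]])
      for (locus in seq_len(ncol(parents))) {
        expect_identical(sort(children[, locus]), sort(parents[, locus]))
      }
    }
  }
})

test_that("mutation flips bits at the configured rate", {
  p <- chrom(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, FALSE))
  expect_identical(mutate_chromosome(p, 0)$genes, p$genes)
  flipped <- mutate_chromosome(p, 1)
  expect_identical(flipped$genes, !p$genes)
  expect_identical(flipped$conditions, !p$conditions)

  set.seed(13)
  big <- chrom(rep(FALSE, 500), rep(FALSE, 500))
  flips <- vapply(1:1000, function(i) {
    m <- mutate_chromosome(big, 0.01)
    sum(m$genes) + sum(m$conditions)
  }, numeric(1))
  # each trial ~ Binomial(1000, 0.01), so the mean of 1000 trials has
  # sd sqrt(1000 * 0.01 * 0.99 / 1000)
  expect_lt(abs(mean(flips) - 10), 3 * sqrt(9.9 / 1000) * 10)
})

test_that("consolidation completes a partial block to its signature set", {
  sim <- gen_expression(m = 50, n = 10,
                        truth_spec = list(list(12, 5, "constant_column")),
                        noise_sd = 0, seed = 21)
  Md <- discretize_mean_sd(sim$expression)
  tb <- sim$truth$biclusters
  partial <- tb$genes[[1]][1:4]
  completed <- consolidate_bicluster(Md, partial, tb$conditions[[1]])
  expect_setequal(completed, tb$genes[[1]])

  # all-N submatrix carries no signature: gene set unchanged
  allN <- make_disc(matrix("N", 6, 4), 3L)
  expect_identical(consolidate_bicluster(allN, rownames(allN)[1:3],
                                         colnames(allN)),
                   rownames(allN)[1:3])
})

test_that("the GA is reproducible and improves monotonically under elitism", {
  sim <- gen_expression(m = 40, n = 8,
                        truth_spec = list(list(10, 4, "constant_column")),
                        noise_sd = 0.25, seed = 31)
  Md <- discretize_mean_sd(sim$expression)
  cfg <- ga_config(population_size = 40, generations = 25, n_restarts = 2,
                   seed = 31)
  fit1 <- run_ga(Md, cfg)
  fit2 <- run_ga(Md, cfg)
  expect_identical(fit1$biclusters, fit2$biclusters)

  for (r in unique(fit1$history$restart)) {
    best <- fit1$history$best[fit1$history$restart == r]
    expect_true(all(diff(best) >= 0))
  }
})

test_that("the GA recovers a planted block and is invariant to gene relabeling", {
  sim <- gen_expression(m = 40, n = 8,
                        truth_spec = list(list(10, 4, "constant_column")),
                        noise_sd = 0, seed = 32)
  Md <- discretize_mean_sd(sim$expression)
  cfg <- ga_config(population_size = 60, generations = 30, n_restarts = 3,
                   seed = 32)
  fit <- run_ga(Md, cfg)
  top <- fit$biclusters$genes[[1]]
  expect_gte(jaccard(top, sim$truth$biclusters$genes[[1]]), 0.8)

  relabel <- setNames(sprintf("protein_%02d", seq_len(nrow(Md))), rownames(Md))
  Md2 <- Md
  rownames(Md2) <- unname(relabel[rownames(Md)])
  fit2 <- run_ga(Md2, cfg)
  expect_identical(lapply(fit2$biclusters$genes, unname),
                   lapply(fit$biclusters$genes,
                          function(g) unname(relabel[g])))
  expect_equal(fit2$biclusters$dcm, fit$biclusters$dcm)
})

test_that("bicluster filtering enforces sizes and DCM fraction", {
  bics <- tibble::tibble(
    bicluster_id = 1:3,
    genes = list(c("a", "b"), c("a", "b", "c"), c("d", "e", "f")),
    conditions = list(c("t1", "t2"), c("t1", "t2"), c("t1", "t2", "t3")),
    dcm = c(2, 2, 0.5))
  out <- filter_biclusters(bics, min_genes = 3, min_conditions = 2,
                           min_dcm_fraction = 0.5)
  # first is too small, third has dcm 0.5 < 0.5 * 3
  expect_identical(out$bicluster_id, 2L)
  expect_identical(nrow(filter_biclusters(bics[0, ], 3, 2, 0.5)), 0L)
})

test_that("redundancy removal is greedy by DCM on gene-set Jaccard", {
  # chain: A~B and B~C overlap >= 0.75 but A~C < 0.75, DCM A > B > C
  A <- as.character(1:8)
  B <- as.character(2:9)   # J(A,B) = 7/9 ~ 0.78
  C <- as.character(3:10)  # J(B,C) = 7/9, J(A,C) = 6/10
  bics <- tibble::tibble(bicluster_id = 1:3, genes = list(A, B, C),
                         conditions = rep(list(c("t1", "t2")), 3),
                         dcm = c(3, 2, 1))
  kept <- remove_redundant(bics, 0.75)
  expect_setequal(kept$bicluster_id, c(1L, 3L))

  dup <- tibble::tibble(bicluster_id = 1:2, genes = list(A, A),
                        conditions = rep(list("t1"), 2), dcm = c(1, 1))
  expect_identical(nrow(remove_redundant(dup, 0.75)), 1L)
  disj <- tibble::tibble(bicluster_id = 1:2,
                         genes = list(A, as.character(20:27)),
                         conditions = rep(list("t1"), 2), dcm = c(1, 1))
  expect_identical(nrow(remove_redundant(disj, 0.75)), 2L)
})

test_that("bicluster files round-trip", {
  bics <- tibble::tibble(
    bicluster_id = 1:2,
    genes = list(c("g1", "g2", "g3"), c("g4", "g5")),
    conditions = list(c("t1", "t3"), c("t2", "t4", "t5")),
    dcm = c(1.875, 2.5))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_biclusters(bics, tf, comments = "test provenance")
  back <- read_biclusters(tf)
  expect_identical(back$genes, bics$genes)
  expect_identical(back$conditions, bics$conditions)
  expect_equal(back$dcm, bics$dcm)
})
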