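test_that("expression generation is seeded, sized and truth-consistent", {
  sim1 <- gen_expression(m = 30, n = 8,
                         truth_spec = list(list(8, 4, "constant_column")),
                         noise_sd = 0.2, seed = 50)
  sim2 <- gen_expression(m = 30, n = 8,
                         truth_spec = list(list(8, 4, "constant_column")),
                         noise_sd = 0.2, seed = 50)
  expect_identical(sim1$expression, sim2$expression)
  expect_identical(dim(sim1$expression), c(30L, 8L))
  tb <- sim1$truth$biclusters
  expect_length(tb$genes[[1]], 8)
  expect_true(all(tb$genes[[1]] %in% rownames(sim1$expression)))

  pure <- gen_expression(m = 10, n = 5, truth_spec = list(), noise_sd = 0,
                         seed = 51)
  expect_identical(nrow(pure$truth$biclusters), 0L)

  expect_error(gen_expression(m = 10, n = 5,
                              truth_spec = list(list(11, 3, "shifting"))),
               "do not fit")
})

test_that("zero-noise constant-column blocks are unanimous after mean/sd coding", {
  for (s in c(52, 53, 54)) {
    sim <- gen_expression(m = 60, n = 12,
                          truth_spec = list(list(15, 6, "constant_column")),
                          noise_sd = 0, seed = s)
    tb <- sim$truth$biclusters
    Md <- discretize_mean_sd(sim$expression, alpha_disc = 1)
    expect_equal(dcm_fitness(Md, tb$genes[[1]], tb$conditions[[1]]),
                 length(tb$conditions[[1]]))
  }
})

test_that("PPI generation plants dense complexes inside bicluster genes", {
  sim <- gen_expression(m = 40, n = 10,
                        truth_spec = list(list(12, 5, "constant_column"),
                                          list(10, 5, "shifting")),
                        noise_sd = 0.1, seed = 55)
  ppi <- gen_ppi(sim$truth, extra_proteins = 20, intra_density = 1,
                 background_density = 0, seed = 55)
  # degenerate probabilities: exactly a union of cliques over complexes
  expected <- unique(unlist(lapply(ppi$truth$complexes$proteins, function(p) {
    pr <- utils::combn(sort(p), 2)
    paste(pr[1, ], pr[2, ])
  })))
  expect_setequal(paste(ppi$network$edges$a, ppi$network$edges$b), expected)
  # complexes live inside their bicluster's gene set
  for (i in seq_len(nrow(ppi$truth$complexes))) {
    b <- ppi$truth$complexes$bicluster[i]
    expect_true(all(ppi$truth$complexes$proteins[[i]] %in%
                      sim$truth$biclusters$genes[[b]]))
  }
  # determinism
  ppi2 <- gen_ppi(sim$truth, extra_proteins = 20, intra_density = 1,
                  background_density = 0, seed = 55)
  expect_identical(ppi$network$edges, ppi2$network$edges)
})

test_that("generated edge counts match binomial expectations", {
  sim <- gen_expression(m = 12, n = 6,
                        truth_spec = list(list(6, 3, "constant_column")),
                        noise_sd = 0, seed = 56)
  counts <- vapply(1:200, function(s) {
    ppi <- gen_ppi(sim$truth, extra_proteins = 0, intra_density = 0.9,
                   background_density = 0, complex_sizes = 6, seed = s)
    nrow(ppi$network$edges)
  }, numeric(1))
  # each draw ~ Binomial(15, 0.9); mean of 200 draws within 3 sigma
  expect_lt(abs(mean(counts) - 13.5), 3 * sqrt(15 * 0.9 * 0.1 / 200))
})

test_that("relevance and recovery average best gene-set Jaccard overlaps", {
  truth <- structure(list(biclusters = tibble::tibble(
    bicluster = 1:2,
    genes = list(sprintf("g%02d", 1:10), sprintf("g%02d", 11:20)),
    conditions = list("t1", "t2"), pattern = "constant_column"),
    complexes = NULL), class = "planted_truth")
  found_exact <- tibble::tibble(bicluster_id = 1:2,
                                genes = truth$biclusters$genes,
                                conditions = list("t1", "t2"),
                                dcm = c(1, 1))
  expect_equal(recovery_scores(found_exact, truth),
               tibble::tibble(relevance = 1, recovery = 1))

  found_disjoint <- tibble::tibble(bicluster_id = 1L,
                                   genes = list(sprintf("h%02d", 1:5)),
                                   conditions = list("t1"), dcm = 1)
  expect_equal(recovery_scores(found_disjoint, truth),
               tibble::tibble(relevance = 0, recovery = 0))

  found_half <- tibble::tibble(bicluster_id = 1L,
                               genes = truth$biclusters$genes[1],
                               conditions = list("t1"), dcm = 1)
  sc <- recovery_scores(found_half, truth)
  expect_equal(sc$relevance, 1)
  expect_equal(sc$recovery, 0.5)

  empty_truth <- structure(list(biclusters = tibble::tibble(),
                                complexes = NULL), class = "planted_truth")
  expect_error(recovery_scores(found_exact, empty_truth), "no planted")
})
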