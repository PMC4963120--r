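test_that("expression TSV reader parses well-formed files and round-trips", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "gene\tc1\tc2", "g1\t0.5\t1.5",
               "g2\t-1\t2", "g3\t0\t3.25"), tf)
  M <- read_expression_matrix(tf)
  expect_identical(dim(M), c(3L, 2L))
  expect_identical(rownames(M), c("g1", "g2", "g3"))
  expect_identical(colnames(M), c("c1", "c2"))
  expect_equal(M["g2", "c2"], 2)

  set.seed(42)
  M0 <- random_expr(10, 5)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(M0, tf2, comments = "round trip")
  M1 <- read_expression_matrix(tf2)
  expect_identical(dimnames(M1), dimnames(M0))
  expect_equal(M1, M0, tolerance = 1e-12)
})

test_that("expression TSV reader reports parse errors with line numbers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "g1\t1\t2", "g2\t3\t4", "g1\t5\t6"), tf)
  expect_error(read_expression_matrix(tf), "line 4.*duplicate gene ID")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "g1\t1\t2\t3"), tf2)
  expect_error(read_expression_matrix(tf2), "line 2.*expected 3 fields")

  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tc1\tc2", "g1\t1\tabc"), tf3)
  expect_error(read_expression_matrix(tf3), "line 2.*non-numeric")
})

test_that("row normalization gives population z-scores and flags flat rows", {
  M <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  Z <- normalize_rows(M)
  expect_equal(mean(Z), 0)
  expect_equal(sqrt(mean((Z - mean(Z))^2)), 1)

  Mc <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
               dimnames = list(c("flat", "g2"), c("a", "b", "c")))
  expect_warning(Zc <- normalize_rows(Mc), "constant row")
  expect_equal(unname(unclass(Zc)["flat", ]), c(0, 0, 0))
  expect_identical(attr(Zc, "constant_rows"), "flat")

  set.seed(1)
  Z2 <- normalize_rows(random_expr(20, 12))
  expect_true(all(abs(rowMeans(Z2)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans((Z2 - rowMeans(Z2))^2)) - 1) < 1e-9))
  # idempotence on non-constant rows
  Z3 <- normalize_rows(unclass(Z2))
  expect_equal(unclass(Z3), unclass(Z2), tolerance = 1e-9)
})

test_that("simple-threshold discretization applies a strict greater-than rule", {
  M <- matrix(c(0.1, 0.9), 1, 2, dimnames = list("g", c("a", "b")))
  D <- discretize_simple_threshold(M, 0.5)
  expect_identical(unname(unclass(D)[1, ]), c("D", "U"))
  expect_identical(attr(D, "alphabet"), 2L)

  Mt <- matrix(c(0.5, 0.5000001), 1, 2, dimnames = list("g", c("a", "b")))
  Dt <- discretize_simple_threshold(Mt, 0.5)
  expect_identical(unname(unclass(Dt)[1, ]), c("D", "U")) # tie goes to D

  set.seed(7)
  M2 <- random_expr(50, 10)
  D2 <- unclass(discretize_simple_threshold(M2, 0))
  for (i in seq_len(nrow(M2))) {
    for (j in seq_len(ncol(M2))) {
      expect_identical(D2[i, j], if (M2[i, j] > 0) "U" else "D")
    }
  }
})

test_that("mean/sd-band discretization matches a hand oracle", {
  M <- matrix(c(0, 0, 0, 10), 1, 4,
              dimnames = list("g", sprintf("c%d", 1:4)))
  D <- discretize_mean_sd(M, alpha_disc = 1)
  mu <- 2.5
  sdv <- sqrt(mean((c(0, 0, 0, 10) - mu)^2)) # population sd
  expect_identical(unname(unclass(D)[1, 4]), "U") # 10 > 2.5 + 4.33
  expect_true(all(unclass(D)[1, 1:3] %in% c("D", "N")))
  expect_identical(unname(unclass(D)[1, 1]), if (0 < mu - sdv) "D" else "N")

  Mc <- matrix(7, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_true(all(unclass(discretize_mean_sd(Mc)) == "N"))

  set.seed(8)
  Mr <- random_expr(10, 6)
  expect_true(all(unclass(discretize_mean_sd(Mr, alpha_disc = 1e6)) == "N"))
})

test_that("transitional-state discretization is the sign of the z-score", {
  Z <- suppressWarnings(normalize_rows(random_expr(5, 8)))
  D <- discretize_transitional_state(Z)
  expect_identical(sym(D), unname(ifelse(unclass(Z) > 0, "U", "D")))

  Mz <- matrix(c(0, 0, 3), 1, 3, dimnames = list("g", c("a", "b", "c")))
  Dz <- discretize_transitional_state(normalize_rows(Mz))
  expect_identical(unname(unclass(Dz)[1, 1]), "D") # z < 0
  Mz2 <- matrix(c(-1, 0, 1), 1, 3, dimnames = list("g", c("a", "b", "c")))
  Dz2 <- discretize_transitional_state(normalize_rows(Mz2))
  expect_identical(unname(unclass(Dz2)[1, 2]), "D") # exact zero is D
  expect_error(discretize_transitional_state(random_expr(3, 3)),
               "normalize_rows")
})

test_that("variation discretization codes consecutive differences", {
  # three-letter: diffs +2 then -2 around beta = 0.5
  Z <- structure(matrix(c(0, 2, 0), 1, 3,
                        dimnames = list("g", c("a", "b", "c"))),
                 class = c("normalized_matrix", "matrix", "array"))
  D <- discretize_variation(Z, alphabet = 3, beta = 0.5)
  expect_identical(unname(unclass(D)[1, ]), c("N", "U", "D"))

  Dbig <- discretize_variation(Z, alphabet = 3, beta = 10)
  expect_identical(unname(unclass(Dbig)[1, ]), c("N", "N", "N"))

  # binary with alpha_disc = 0: beta = 0, strictly positive diffs are U
  Zr <- suppressWarnings(normalize_rows(random_expr(6, 5)))
  Db <- discretize_variation(Zr, alphabet = 2, alpha_disc = 0)
  diffs <- unclass(Zr)[, -1] - unclass(Zr)[, -5]
  expect_identical(unname(sym(Db)[, -1]), unname(ifelse(diffs > 0, "U", "D")))
  expect_true(all(unclass(Db)[, 1] == "D")) # first column convention

  Z1 <- structure(matrix(0, 2, 1, dimnames = list(c("a", "b"), "t1")),
                  class = c("normalized_matrix", "matrix", "array"))
  expect_error(discretize_variation(Z1, alphabet = 2), "at least 2")
})

test_that("discretization is total and row-permutation equivariant", {
  set.seed(11)
  M <- random_expr(15, 7)
  perm <- sample(nrow(M))
  for (tech in c("simple_threshold", "mean_sd", "transitional_state",
                 "variation")) {
    args <- switch(tech, simple_threshold = list(t = 0),
                   mean_sd = list(alpha_disc = 1),
                   variation = list(alphabet = 3, beta = 0.4), list())
    D <- do.call(discretize, c(list(M, technique = tech), args))
    alphabet <- if (attr(D, "alphabet") == 3L) c("D", "N", "U") else c("D", "U")
    expect_true(all(unclass(D) %in% alphabet))
    Dp <- do.call(discretize, c(list(M[perm, ], technique = tech), args))
    expect_identical(sym(Dp, dimnames = TRUE), sym(D, dimnames = TRUE)[perm, ])
  }
})

test_that("discretized matrices write to readable TSV", {
  set.seed(3)
  D <- discretize_mean_sd(random_expr(4, 3))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_discretized(D, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "technique=mean_sd")
  expect_identical(length(lines), 2L + 4L)
  body <- do.call(rbind, strsplit(lines[-(1:2)], "\t"))
  expect_identical(body[, 1], rownames(D))
  expect_identical(body[1, -1], unname(unclass(D)[1, ]))
})
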