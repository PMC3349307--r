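test_that("the pair alphabet is the frozen 16-pair ordering", {
  om <- dinucleotides()
  expect_length(om, 16L)
  expect_false(anyDuplicated(om) > 0)
  expect_identical(om[1L], "AT")
  expect_identical(om[16L], "CG")
  expect_setequal(om, as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                                      paste0)))
})

test_that("adjacent and gapped pair counts match the worked example", {
  c1 <- count_pairs("ATCGATC", d = 1)
  expect_identical(c1[c("AT", "TC", "CG", "GA")],
                   c(AT = 2L, TC = 2L, CG = 1L, GA = 1L))
  expect_identical(sum(c1), 6L)
  expect_identical(sum(c1[!names(c1) %in% c("AT", "TC", "CG", "GA")]), 0L)

  c2 <- count_pairs("ATCGATC", d = 2)
  expect_identical(c2[c("AC", "TG", "CA", "GT")],
                   c(AC = 2L, TG = 1L, CA = 1L, GT = 1L))
  expect_identical(sum(c2), 5L)

  hom <- count_pairs("AAAA", d = 1)
  expect_identical(hom[["AA"]], 3L)
  expect_identical(sum(hom), 3L)
})

test_that("count_pairs validates its separation distance", {
  expect_error(count_pairs("ATCGATC", d = 0), "positive")
  expect_error(count_pairs("ATCGATC", d = 7), "must be <")
  expect_error(count_pairs("ATNGA", d = 1), "position 3")
})

test_that("counting agrees with a brute-force sliding-window oracle", {
  withr::local_seed(421)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    s <- random_dna(n)
    for (d in unique(c(1L, sample(seq_len(n - 1L), 3)))) {
      got <- count_pairs(s, d)
      expect_identical(unclass(got)[seq_len(16)], oracle_pair_counts(s, d),
                       info = sprintf("n=%d d=%d", n, d))
    }
  }
})

test_that("frequencies are counts over n - d and lie on the simplex", {
  f1 <- frequency_vector("ATCGATC", d = 1)
  expect_identical(f1[c("AT", "TC", "CG", "GA")],
                   c(AT = 2 / 6, TC = 2 / 6, CG = 1 / 6, GA = 1 / 6))
  f2 <- frequency_vector("ATCGATC", d = 2)
  expect_identical(f2[c("AC", "TG", "CA", "GT")],
                   c(AC = 2 / 5, TG = 1 / 5, CA = 1 / 5, GT = 1 / 5))
  expect_identical(frequency_vector("AAAA", d = 1)[["AA"]], 1)

  withr::local_seed(99)
  for (rep in 1:20) {
    s <- random_dna(sample(12:80, 1))
    d <- sample(max_valid_distance(nchar(s)), 1)
    fr <- frequency_vector(s, d)
    expect_equal(sum(fr), 1)
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("the depth bound is floor(n/4)", {
  expect_identical(max_valid_distance(86), 21L)
  expect_identical(max_valid_distance(7), 1L)
  expect_identical(max_valid_distance(105), 26L)
  expect_error(max_valid_distance(3), ">= 4")
})

test_that("frequency_matrix stacks per-distance rows and enforces the bound", {
  bg <- beta_globin()
  fm <- frequency_matrix(bg["Human"], d0 = 21)
  expect_identical(dim(unclass(fm)), c(21L, 16L))
  expect_equal(unname(rowSums(fm)), rep(1, 21))
  expect_identical(attr(fm, "id"), "Human")

  # base case: single row equals the frequency vector
  s <- "ATCGATCGGA"
  expect_equal(as.vector(unclass(frequency_matrix(s, 1))[1, ]),
               as.vector(frequency_vector(s, 1)))

  # row 21 of an 86-mer recomputed by the brute-force scan (denominator 65)
  goat <- unclass(bg)[["Goat"]]
  expect_equal(unname(unclass(frequency_matrix(bg["Goat"], 21))[21, ]),
               unname(oracle_pair_counts(goat, 21)) / 65)

  expect_error(frequency_matrix(bg["Human"], 24), "exceeds floor")
  expect_warning(fm24 <- frequency_matrix(bg["Human"], 24, enforce_bound = FALSE),
                 "50%")
  expect_identical(nrow(fm24), 24L)
  expect_error(frequency_matrix("ACGTACGT", 8, enforce_bound = FALSE), "n - 1")
})

test_that("flatten is the row-major unrolling, first separation first", {
  fm <- frequency_matrix(beta_globin()["Human"], d0 = 21)
  v <- flatten(fm)
  expect_length(v, 336L)
  expect_equal(sum(v), 21)
  expect_equal(unname(v[1:16]), unname(unclass(fm)[1, ]))
  # round-trip back to the matrix
  expect_equal(matrix(v, 21, 16, byrow = TRUE), unclass(fm),
               ignore_attr = TRUE)
  # depth 1: identical to the single row
  f1 <- frequency_matrix("ATCGATC", 1)
  expect_equal(unname(flatten(f1)), unname(unclass(f1)[1, ]))
})

test_that("ambiguity skipping drops affected pairs from numerator and denominator", {
  # N at position 3: at d = 1 pairs (2,3) and (3,4) are dropped
  cn <- count_pairs("ATNGA", d = 1, skip_ambiguous = TRUE)
  expect_identical(sum(cn), 2L)
  expect_identical(cn[["AT"]], 1L)
  expect_identical(cn[["GA"]], 1L)
  fn <- frequency_vector("ATNGA", d = 1, skip_ambiguous = TRUE)
  expect_equal(sum(fn), 1)
  expect_equal(fn[["AT"]], 0.5)
  # frequencies over retained pairs still match the clean subsequence logic
  expect_equal(frequency_vector("ACGTACGT", 2, skip_ambiguous = TRUE),
               frequency_vector("ACGTACGT", 2))
})
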