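test_that("counts_to_proportions follows the pseudocount formula", {
  ct <- count_table(matrix(c(10, 10, 10, 10), 1, 4))
  expect_equal(unname(counts_to_proportions(ct, 0)$values[1, ]),
               rep(0.25, 4))
  ct2 <- count_table(matrix(c(0, 1, 3), 1, 3))
  expect_equal(unname(counts_to_proportions(ct2, 0.5)$values[1, ]),
               c(0.5, 1.5, 3.5) / 5.5)
})

test_that("zero counts without pseudocount name the offender", {
  ct <- count_table(matrix(c(5, 0, 2, 3), 2, 2,
                           dimnames = list(c("sA", "sB"), c("tX", "tY"))))
  expect_error(counts_to_proportions(ct, 0), "sB.*tX|tX.*sB")
  expect_silent(counts_to_proportions(ct, 0.5))
})

test_that("proportion rows always sum to 1 (property)", {
  set.seed(11)
  for (i in 1:20) {
    ct <- random_counts(sample(2:8, 1), sample(2:12, 1))
    comp <- counts_to_proportions(ct, runif(1, 0.1, 2))
    expect_lt(max(abs(rowSums(comp$values) - 1)), 1e-10)
    expect_true(all(comp$values > 0))
  }
})

test_that("log-ratio transform matches direct arithmetic and drops the reference", {
  comp <- composition_table(matrix(c(0.2, 0.3, 0.5), 1, 3,
                                   dimnames = list("s1", c("A", "B", "C"))))
  y <- log_ratio_transform(comp, "C")
  expect_equal(unname(y$values[1, ]), c(log(0.4), log(0.6)))
  expect_identical(y$taxon_ids, c("A", "B"))
  expect_identical(y$reference_taxon, "C")
  # uniform proportions give zero log-ratios for any reference
  u <- composition_table(matrix(1 / 3, 2, 3,
                                dimnames = list(NULL, c("A", "B", "C"))))
  for (ref in c("A", "B", "C"))
    expect_equal(unname(log_ratio_transform(u, ref)$values),
                 matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(log_ratio_transform(comp, "nope"), "unknown reference")
})

test_that("inverse_log_ratio forced cases and stability", {
  y0 <- log_ratio_table(matrix(0, 1, 3), "s1", c("A", "B", "C"), "D")
  expect_equal(unname(inverse_log_ratio(y0)$values[1, ]), rep(0.25, 4))
  y2 <- log_ratio_table(matrix(log(2), 1, 1), "s1", "A", "B")
  expect_equal(unname(inverse_log_ratio(y2)$values[1, ]), c(2 / 3, 1 / 3))
  # overflow-scale entries: stable log-sum-exp, no NaN, unit row sums
  yb <- log_ratio_table(matrix(c(800, -800, 0), 1, 3), "s1",
                        c("A", "B", "C"), "D")
  rho <- inverse_log_ratio(yb)$values
  expect_true(all(is.finite(rho)))
  expect_lt(abs(sum(rho) - 1), 1e-10)
})

test_that("transform and inverse are mutually inverse (property)", {
  set.seed(21)
  for (i in 1:10) {
    S <- sample(3:10, 1); n <- sample(1:6, 1)
    y <- log_ratio_table(matrix(rnorm(n * (S - 1), sd = 3), n, S - 1),
                         taxon_ids = paste0("t", seq_len(S - 1)),
                         reference_taxon = "ref")
    back <- log_ratio_transform(inverse_log_ratio(y), "ref")
    expect_lt(max(abs(back$values - y$values)), 1e-10)

    comp <- counts_to_proportions(random_counts(n, S), 0.5)
    ref <- comp$taxon_ids[S]
    again <- inverse_log_ratio(log_ratio_transform(comp, ref))
    expect_lt(max(abs(again$values[, comp$taxon_ids] - comp$values)), 1e-10)
  }
})

test_that("changing the reference shifts y by the old coordinate of the new reference", {
  set.seed(31)
  comp <- counts_to_proportions(random_counts(4, 6), 0.5)
  taxa <- comp$taxon_ids
  y_last <- log_ratio_transform(comp, taxa[6])
  y_new <- log_ratio_transform(comp, taxa[3])
  shift <- y_last$values[, taxa[3]]
  for (t in setdiff(taxa, c(taxa[3], taxa[6])))
    expect_equal(y_new$values[, t], y_last$values[, t] - shift)
  expect_equal(y_new$values[, taxa[6]], -shift)
})

test_that("count and log-ratio tables round-trip through disk", {
  dir <- withr::local_tempdir()
  ct <- random_counts(3, 4)
  p1 <- file.path(dir, "counts.tsv")
  write_count_table(ct, p1)
  expect_equal(read_count_table(p1)$values, ct$values)

  y <- log_ratio_transform(counts_to_proportions(ct, 0.5))
  p2 <- file.path(dir, "y.tsv")
  write_log_ratio_table(y, p2)
  y2 <- read_log_ratio_table(p2)
  expect_equal(y2$values, y$values, tolerance = 1e-12)
  expect_identical(y2$reference_taxon, y$reference_taxon)
})

test_that("constructor invariants reject bad input", {
  expect_error(count_table(matrix(-1, 2, 2)), "nonnegative")
  expect_error(count_table(matrix(1, 2, 1)), "two taxa")
  expect_error(count_table(matrix(1, 2, 2,
                                  dimnames = list(c("a", "a"), NULL))),
               "duplicate")
  expect_error(composition_table(matrix(c(0.5, 0.6), 1, 2)), "sum to 1")
  expect_error(log_ratio_table(matrix(0, 1, 2), "s", c("A", "B"), "A"),
               "reference")
})
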