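test_that("count matrix TSV round trip is the identity", {
  x <- toy_counts()
  dir <- withr::local_tempdir()
  write_count_matrix(x, file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  y <- read_count_matrix(file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  expect_identical(y$counts, x$counts)
  expect_identical(y$meta, x$meta)
})

test_that("malformed inputs are rejected with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("mirna\tS1\tS1", "mir-a\t1\t2"), file.path(dir, "dup.tsv"))
  writeLines(c("sample_id\tgroup\tdataset\tbatch", "S1\ttumor\td\tb"),
             file.path(dir, "m.tsv"))
  expect_error(read_count_matrix(file.path(dir, "dup.tsv"),
                                 file.path(dir, "m.tsv")), "S1")
  writeLines(c("mirna\tS1\tS2", "mir-a\t1\t2"), file.path(dir, "c.tsv"))
  expect_error(read_count_matrix(file.path(dir, "c.tsv"),
                                 file.path(dir, "m.tsv")), "S2")
  cnt <- matrix(-1, 1, 1, dimnames = list("mir-a", "S1"))
  meta <- data.frame(sample_id = "S1", group = "tumor", dataset = "d",
                     batch = "b")
  expect_error(count_matrix(cnt, meta), "non-negative")
  expect_error(count_matrix(matrix(1.5, 1, 1,
                                   dimnames = list("mir-a", "S1")), meta),
               "integer")
})

test_that("arm collapsing sums -5p/-3p reads under the precursor name", {
  x <- toy_counts(counts = rbind(c(100, 50, 10), c(20, 5, 1), c(7, 7, 7)),
                  features = c("mir-9-5p", "mir-9-3p", "mir-7-5p"))
  cc <- collapse_to_precursor(x)
  expect_equal(rownames(cc$counts), c("mir-9", "mir-7"))
  expect_equal(unname(cc$counts["mir-9", ]), c(120, 55, 11))
  expect_equal(unname(cc$counts["mir-7", ]), c(7, 7, 7))   # lone arm
})

test_that("collapsing conserves the grand total on random matrices", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 30
    feats <- paste0("mir-", rep(sample(100, n / 2), each = 2),
                    c("-5p", "-3p"))
    x <- toy_counts(counts = matrix(rpois(n * 3, 50), n, 3),
                    features = feats)
    expect_equal(sum(collapse_to_precursor(x)$counts), sum(x$counts))
  }
})

test_that("low-count filter discards features below 10 mean reads", {
  # smallest group n = 1 here; force n = 3 via group_sizes
  x <- toy_counts(counts = rbind(c(10, 10, 9), c(10, 10, 10), c(0, 0, 1)))
  f <- filter_low_counts(x, group_sizes = c(3, 3))
  # row total 29 -> mean 9.67 < 10 dropped; boundary total 30 -> mean 10 kept
  expect_equal(rownames(f$counts), "mir-02")
  expect_warning(filter_low_counts(toy_counts(counts = matrix(0, 2, 3)),
                                   group_sizes = c(2, 1)), "no features")
})

test_that("kept set equals a brute-force per-row scan", {
  set.seed(11)
  cnt <- matrix(rpois(200, 8), 40, 5)
  x <- toy_counts(counts = cnt, groups = c(rep("tumor", 3), rep("normal", 2)))
  f <- filter_low_counts(x)
  n <- 2
  manual <- rownames(x$counts)[vapply(seq_len(40), function(i)
    sum(cnt[i, ]) / n >= 10, logical(1))]
  expect_equal(rownames(f$counts), manual)
})

test_that("median-of-ratios size factors match hand-computed references", {
  a <- c(4, 50, 300)
  x <- toy_counts(counts = cbind(a, a), groups = c("tumor", "normal"))
  expect_equal(unname(estimate_size_factors(x)), c(1, 1))
  x2 <- toy_counts(counts = cbind(a, 2 * a), groups = c("tumor", "normal"))
  expect_equal(unname(estimate_size_factors(x2)), c(1 / sqrt(2), sqrt(2)))
  x3 <- toy_counts(counts = matrix(c(4, 9), 1, 2,
                                   dimnames = list("mir-a", NULL)),
                   groups = c("tumor", "normal"))
  expect_equal(unname(estimate_size_factors(x3)), c(2 / 3, 3 / 2))
})

test_that("all-zero-overlap matrices fall back to total-count factors", {
  cnt <- rbind(c(10, 0), c(0, 40))
  x <- toy_counts(counts = cnt, groups = c("tumor", "normal"))
  expect_warning(sf <- estimate_size_factors(x), "falling back")
  expect_equal(unname(sf), c(10, 40) / sqrt(400))
})

test_that("log2 normalization is exact and strictly monotone", {
  x <- toy_counts(counts = rbind(c(0, 7), c(7, 0)),
                  groups = c("tumor", "normal"))
  nm <- normalize_log2(x, size_factors = c(1, 1), pseudocount = 1)
  expect_equal(unname(nm$values[1, ]), c(0, 3))   # log2(0+1), log2(7+1)
  set.seed(3)
  cnt <- matrix(sample(0:100, 40), 20, 2)
  nm2 <- normalize_log2(toy_counts(counts = cnt,
                                   groups = c("tumor", "normal")))
  o <- order(cnt[, 1])
  expect_true(all(diff(nm2$values[o, 1]) >= 0))
})

test_that("rescaling one sample shifts normalized values by c^(1/n) exactly", {
  # median-of-ratios re-estimation moves the geometric reference by c^(1/n),
  # so the normalized profile of a rescaled sample shifts by that factor
  a <- c(4, 9)
  x <- toy_counts(counts = rbind(a), groups = c("tumor", "normal"))
  x2 <- toy_counts(counts = rbind(c(a[1], 2 * a[2])),
                   groups = c("tumor", "normal"))
  norm_b <- function(x) {
    sf <- estimate_size_factors(x)
    (x$counts / rep(sf, each = nrow(x$counts)))[1, 2]
  }
  expect_equal(norm_b(x2), norm_b(x) * 2^(1 / 2))
})

test_that("z-transform matches population-sd arithmetic and centers exactly", {
  m <- toy_normalized(rbind(c(1, 3), c(5, 5)), groups = c("tumor", "normal"))
  zp <- fit_z(m)
  z <- apply_z(m, zp)
  expect_equal(unname(z[1, ]), c(-1, 1))     # population sd of (1,3) is 1
  expect_equal(unname(z[2, ]), c(0, 0))      # constant feature maps to 0
  set.seed(5)
  big <- toy_normalized(matrix(rnorm(60), 6, 10),
                        groups = rep(c("tumor", "normal"), 5))
  zb <- apply_z(big, fit_z(big))
  expect_lt(max(abs(rowMeans(zb))), 1e-12)
  expect_equal(unname(apply(zb, 1, function(v) sqrt(mean((v - mean(v))^2)))),
               rep(1, 6))
})
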