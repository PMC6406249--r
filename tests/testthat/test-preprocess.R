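rand_matrix <- function(nr, nc, seed = 1, min = 1, max = 10) {
  set.seed(seed)
  matrix(runif(nr * nc, min, max), nr, nc,
         dimnames = list(sprintf("g%02d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

test_that("quantile normalization maps columns to rank-wise means", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2, 3))
  expect_equal(unname(out[, 2]), c(2, 3))
  expect_identical(dimnames(out), dimnames(m))

  # a matrix with identical columns is a fixed point
  same <- cbind(s1 = c(5, 1, 3), s2 = c(5, 1, 3))
  rownames(same) <- c("a", "b", "c")
  expect_equal(quantile_normalize(same), same)
})

test_that("quantile normalization is idempotent and equalizes multisets", {
  m <- rand_matrix(20, 5, seed = 11)
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1)
  sorted <- apply(q1, 2, sort)
  for (j in 2:ncol(sorted)) expect_identical(sorted[, j], sorted[, 1])
})

test_that("quantile normalization rejects degenerate input", {
  m1 <- matrix(1:3, 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_error(quantile_normalize(m1), "at least 2 samples")
  m2 <- rand_matrix(3, 3)
  m2[1, 1] <- NA
  expect_error(quantile_normalize(m2), "non-finite")
})

test_that("probe collapse keeps the largest-CV probe per gene", {
  m <- rbind(p1 = c(10, 10, 10), p2 = c(5, 10, 15), p3 = c(2, 2, 4))
  colnames(m) <- c("s1", "s2", "s3")
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_symbol = c("G", "G", "H"))
  out <- collapse_probes(m, ann)
  # p2 has CV 0.5 vs p1's 0; G takes p2's row
  expect_equal(out["G", ], m["p2", ])
  expect_setequal(rownames(out), c("G", "H"))
})

test_that("probe collapse is an identity relabelling for 1:1 maps", {
  m <- rand_matrix(4, 3, seed = 3)
  ann <- data.frame(probe_id = rownames(m),
                    gene_symbol = paste0("GENE_", rownames(m)))
  out <- collapse_probes(m, ann)
  expect_equal(unname(out), unname(m))
  expect_identical(rownames(out), paste0("GENE_", rownames(m)))
})

test_that("non-uniquely mapped probes are excluded", {
  m <- rand_matrix(3, 3, seed = 4)
  ann <- data.frame(probe_id = c("g01", "g01", "g02", "g03"),
                    gene_symbol = c("A", "B", "C", ""))
  out <- collapse_probes(m, ann) # g01 multi-mapped, g03 unmapped
  expect_identical(rownames(out), "C")
})

test_that("probe collapse errors on undefined CV and unknown probes", {
  m <- rbind(p1 = c(-1, 0, 1)) # mean 0
  colnames(m) <- c("s1", "s2", "s3")
  ann <- data.frame(probe_id = "p1", gene_symbol = "A")
  expect_error(collapse_probes(m, ann), "mean <= 0")
  m2 <- rand_matrix(2, 3)
  expect_error(collapse_probes(m2, ann), "absent from annotation")
})

test_that("probe collapse agrees with a brute-force oracle", {
  set.seed(42)
  n_probes <- 50
  m <- rand_matrix(n_probes, 8, seed = 42, min = 2, max = 20)
  rownames(m) <- sprintf("p%02d", seq_len(n_probes))
  ann <- data.frame(probe_id = rownames(m),
                    gene_symbol = sample(sprintf("GN%02d", 1:18),
                                         n_probes, replace = TRUE))
  out <- collapse_probes(m, ann)
  oracle <- collapse_oracle(m, ann)
  expect_setequal(rownames(out), names(oracle))
  for (g in names(oracle)) {
    expect_equal(out[g, ], m[oracle[g], ], ignore_attr = TRUE)
  }
})

test_that("z-scoring standardizes rows with the n-1 denominator", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g", c("a", "b", "c")))
  expect_equal(unname(zscore_genes(m)[1, ]), c(-1, 0, 1))

  big <- rand_matrix(30, 7, seed = 9)
  z <- zscore_genes(big)
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  sds <- apply(z, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-10))

  # an already-standardized row passes through unchanged
  expect_equal(zscore_genes(z), z)
})

test_that("constant genes error by name unless dropped on request", {
  m <- rbind(ok = c(1, 2, 3), flat = c(5, 5, 5))
  colnames(m) <- c("a", "b", "c")
  expect_error(zscore_genes(m), "flat")
  expect_message(out <- zscore_genes(m, drop_constant = TRUE), "flat")
  expect_identical(rownames(out), "ok")
})
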