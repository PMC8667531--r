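test_that("MTX reading transposes 10x-style input and validates shapes", {
  dir <- withr::local_tempdir()
  # 3 genes x 2 cells with entries (1,1)=5 and (3,2)=2
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
                            dims = c(3, 2))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "cells.tsv"))
  cm <- read_counts(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                    file.path(dir, "cells.tsv"), orientation = "genes_x_cells")
  expect_equal(dim(cm), c(2L, 3L))
  expect_equal(unname(cm$counts["c1", "gA"]), 5)
  expect_equal(unname(cm$counts["c2", "gC"]), 2)

  # mismatched sidecars name the offending file
  writeLines(c("gA", "gB"), file.path(dir, "genes.tsv"))
  expect_error(read_counts(file.path(dir, "matrix.mtx"),
                           file.path(dir, "genes.tsv"),
                           file.path(dir, "cells.tsv")),
               class = "cider_error")

  # empty matrix file errors rather than returning an empty object
  writeLines(character(0), file.path(dir, "empty.tsv"))
  expect_error(read_counts(file.path(dir, "empty.tsv")),
               class = "cider_error")
})

test_that("write -> read round trip reproduces a random matrix exactly", {
  withr::with_seed(42, {
    m <- matrix(rpois(50 * 100, 0.8), 50, 100,
                dimnames = list(sprintf("c%02d", 1:50),
                                sprintf("g%03d", 1:100)))
  })
  cm <- count_matrix(m)
  dir <- withr::local_tempdir()
  write_counts(cm, dir)
  back <- read_counts(file.path(dir, "matrix.mtx"),
                      file.path(dir, "genes.tsv"),
                      file.path(dir, "cells.tsv"))
  expect_identical(back$cell_ids, cm$cell_ids)
  expect_identical(back$gene_ids, cm$gene_ids)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
})

test_that("count_matrix rejects duplicates, negatives and non-integers", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("g1", "g2")))
  expect_error(count_matrix(m), class = "cider_error")
  m2 <- matrix(c(1, -1, 0, 2), 2, 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(count_matrix(m2), class = "cider_error")
  m3 <- matrix(c(1, 0.5, 0, 2), 2, 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(count_matrix(m3), class = "cider_error")
})

test_that("filter_cells matches the per-cell nonzero-count oracle", {
  withr::with_seed(7, {
    m <- matrix(rbinom(60 * 30, 1, 0.4), 60, 30,
                dimnames = list(sprintf("c%02d", 1:60),
                                sprintf("g%02d", 1:30)))
  })
  cm <- count_matrix(m)
  thr <- 12L
  res <- filter_cells(cm, min_genes = thr)
  oracle <- rownames(m)[apply(m, 1, function(r) sum(r != 0)) >= thr]
  expect_identical(res$cm$cell_ids, oracle)

  # a cell one gene short of the threshold is removed
  m499 <- matrix(0L, 2, 600,
                 dimnames = list(c("short", "ok"), sprintf("g%03d", 1:600)))
  m499["short", 1:499] <- 1L
  m499["ok", 1:500] <- 1L
  kept <- filter_cells(count_matrix(m499), min_genes = 500)
  expect_identical(kept$cm$cell_ids, "ok")

  # min_genes = 0 is the identity; all filtered errors
  expect_identical(filter_cells(cm, min_genes = 0)$cm$cell_ids, cm$cell_ids)
  expect_error(filter_cells(cm, min_genes = 31), class = "cider_error")
})

test_that("lognormalize follows the formula and preserves sparsity", {
  withr::with_seed(3, {
    m <- matrix(rpois(20 * 40, 1.5), 20, 40,
                dimnames = list(sprintf("c%02d", 1:20),
                                sprintf("g%02d", 1:40)))
  })
  m[1, ] <- 0L; m[1, 1] <- 3L  # keep one nearly empty but nonzero cell
  cm <- count_matrix(m)
  em <- lognormalize(cm, scale = 1e4)
  lib <- rowSums(m)
  direct <- log2(1 + 1e4 * sweep(m, 1, lib, "/"))
  expect_lt(max(abs(as.matrix(em$values) - direct)), 1e-12)
  expect_identical(as.matrix(em$values) == 0, m == 0)

  # count 1 with libsize 1e4 and scale 1e4 -> log2(2) = 1
  big <- matrix(c(1L, 9999L), 1, 2, dimnames = list("c", c("g1", "g2")))
  expect_equal(unname(as.matrix(lognormalize(count_matrix(big))$values)[1, 1]), 1)

  zero <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("z", "c"), "g"))
  expect_error(lognormalize(count_matrix(zero)), class = "cider_error")
})

test_that("CDR is a z-score over the requested cells, gene-order invariant", {
  withr::with_seed(5, {
    m <- matrix(rbinom(30 * 50, 2, 0.3), 30, 50,
                dimnames = list(sprintf("c%02d", 1:30),
                                sprintf("g%02d", 1:50)))
  })
  cm <- count_matrix(m)
  cdr <- compute_cdr(cm)
  expect_equal(cdr$raw, unname(apply(m, 1, function(r) sum(r != 0))))
  expect_lt(abs(mean(cdr$scaled)), 1e-10)
  expect_lt(abs(sd(cdr$scaled) - 1), 1e-10)

  perm <- sample(ncol(m))
  cdr_perm <- compute_cdr(count_matrix(m[, perm]))
  expect_equal(cdr_perm$scaled, cdr$scaled)

  # zero-variance case: identical raw values give scaled zeros
  mm <- matrix(c(1L, 2L, 0L, 0L), 2, 2,
               dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_equal(compute_cdr(count_matrix(mm))$scaled, c(0, 0))

  within <- 5:20
  sub <- compute_cdr(cm, within = within)
  expect_equal(sub$raw, cdr$raw[within])
  expect_lt(abs(mean(sub$scaled)), 1e-10)
})

test_that("HVG ranking matches a brute-force dispersion sort", {
  withr::with_seed(9, {
    m <- matrix(rpois(100 * 20, 3), 100, 20,
                dimnames = list(sprintf("c%03d", 1:100),
                                sprintf("g%02d", 1:20)))
  })
  em <- lognormalize(count_matrix(m))
  got <- select_hvgs(em, n = 20, n_bins = 4)
  # oracle: z-score variances within 4 equal-occupancy mean bins
  x <- as.matrix(em$values)
  mu <- colMeans(x); v <- apply(x, 2, var)
  bins <- cut(rank(mu, ties.method = "first"), 4, labels = FALSE)
  z <- ave(v, bins, FUN = function(u) (u - mean(u)) / sd(u))
  oracle <- colnames(x)[order(-z, colnames(x))]
  expect_identical(got, oracle)

  # n = total is the identity set; n too large warns and returns all
  expect_setequal(select_hvgs(em, n = 20), em$gene_ids)
  expect_warning(all_g <- select_hvgs(em, n = 50), class = "cider_warning")
  expect_length(all_g, 20)
})

test_that("PCA is centered, ordered, orthogonal and matches SVD truncation", {
  withr::with_seed(13, {
    x <- matrix(rnorm(40 * 25), 40, 25,
                dimnames = list(sprintf("c%02d", 1:40),
                                sprintf("g%02d", 1:25)))
  })
  em <- expression_matrix(abs(x))
  pcs <- compute_pca(em, n_pcs = 5)
  expect_equal(dim(pcs), c(40L, 5L))
  expect_lt(max(abs(crossprod(pcs) - diag(diag(crossprod(pcs))))), 1e-8)
  sdev <- attr(pcs, "sdev")
  expect_true(all(diff(sdev) <= 1e-12))

  # reconstruction error equals the SVD truncation error
  xc <- sweep(abs(x), 2, colMeans(abs(x)))
  sv <- svd(xc)
  recon <- pcs %*% t(attr(pcs, "rotation"))
  err <- sum((xc - recon)^2)
  oracle_err <- sum(sv$d[6:length(sv$d)]^2)
  expect_equal(err, oracle_err, tolerance = 1e-8)

  # rank-1 input: PC1 carries essentially all variance
  r1 <- outer(seq_len(30), runif(10)) +
    matrix(rnorm(300, 0, 1e-8), 30, 10)
  dimnames(r1) <- list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:10))
  p1 <- compute_pca(expression_matrix(abs(r1)), n_pcs = 2)
  sd1 <- attr(p1, "sdev")
  expect_gt(sd1[1]^2 / sum(sd1^2), 0.9999)

  expect_error(compute_pca(em, n_pcs = 26), class = "cider_error")
  # sign convention makes repeated runs identical
  expect_identical(pcs, compute_pca(em, n_pcs = 5))
})

test_that("lognormalize is monotone in counts within a cell", {
  m <- matrix(c(0L, 1L, 5L, 20L), 1, 4,
              dimnames = list("c", paste0("g", 1:4)))
  v <- as.matrix(lognormalize(count_matrix(m))$values)[1, ]
  expect_true(all(diff(v) > 0))
})
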