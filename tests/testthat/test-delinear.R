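test_that("design matrix columns follow the stated layout", {
  group <- c("g_i", "g_i", "g_j", "g_j", "background", "background")
  cdr <- c(0.5, -0.5, 1, -1, 0.3, -0.3)
  X <- build_design(group, batch = rep("b1", 6), cdr = cdr)
  expect_identical(colnames(X$matrix),
                   c("(Intercept)", "groupg_i", "groupg_j", "cdr"))
  expect_identical(unname(X$term_map),
                   c("intercept", "group-level", "group-level", "cdr"))
  # single-level batch contributes no columns
  expect_false(any(startsWith(colnames(X$matrix), "batch")))

  X2 <- build_design(group, batch = c("b1", "b2", "b1", "b2", "b1", "b2"),
                     cdr = cdr)
  expect_true("batchb2" %in% colnames(X2$matrix))
  expect_equal(qr(X2$matrix)$rank, ncol(X2$matrix))
})

test_that("nested covariates are rank-reduced like the assembled oracle", {
  # donors nested in species: donor dummies span within-species contrasts
  withr::with_seed(21, {
    n <- 40
    species <- rep(c("human", "mouse"), each = 20)
    donor <- paste0(species, "_d", rep(rep(1:2, each = 10), 2))
    group <- sample(c("g_i", "g_j", "background"), n, replace = TRUE)
    cdr <- rnorm(n)
  })
  X <- suppressWarnings(
    build_design(group, batch = species, cdr = cdr,
                 extra = list(donor = donor)))
  # oracle: rank of the naively assembled full dummy matrix
  full <- cbind(1, stats::model.matrix(~ group + species + donor)[, -1],
                cdr)
  expect_equal(ncol(X$matrix), qr(full)$rank)
  expect_equal(qr(X$matrix)$rank, ncol(X$matrix))
})

test_that("confounded lower-priority columns are dropped, group survives", {
  expect_error(build_design(c("g_i", "g_i", "g_i", "g_i")),
               class = "cider_error")  # reference level absent
  # batch perfectly aliased with group: the batch column is dropped with
  # a warning (right-to-left policy) and the group coefficient survives
  group <- c("g_i", "g_i", "g_j", "g_j", "background", "background")
  batch <- c("b1", "b1", "b2", "b2", "b1", "b1")
  expect_warning(X <- build_design(group, batch = batch,
                                   extra = list(dup = batch)),
                 class = "cider_warning")
  expect_true(all(c("groupg_i", "groupg_j") %in% colnames(X$matrix)))
  expect_true("dupb2" %in% X$dropped)
  expect_equal(qr(X$matrix)$rank, ncol(X$matrix))
})

test_that("OLS reproduces closed forms and the normal-equations oracle", {
  withr::with_seed(31, {
    y <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(sprintf("c%02d", 1:30),
                                sprintf("g%02d", 1:10)))
    # intercept-only: coefficient is the per-gene mean
    fit0 <- fit_ols(y, matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)")))
    expect_equal(unname(fit0$coefficients[, 1]), unname(colMeans(y)),
                 tolerance = 1e-12)

    # balanced two-group design: group coefficient = difference of means
    grp <- rep(c("background", "g_i"), each = 15)
    X <- build_design(grp)
    fit1 <- fit_ols(y, X)
    diffs <- colMeans(y[16:30, ]) - colMeans(y[1:15, ])
    expect_equal(unname(fit1$coefficients[, "groupg_i"]), unname(diffs),
                 tolerance = 1e-10)

    # random full design vs (X'X)^-1 X'y
    Xr <- cbind(1, matrix(rnorm(30 * 4), 30, 4))
    colnames(Xr) <- c("(Intercept)", paste0("v", 1:4))
    fit2 <- fit_ols(y, Xr)
    beta <- solve(crossprod(Xr), crossprod(Xr, y))
    expect_lt(max(abs(fit2$coefficients - t(beta))), 1e-8)
    # sigma2 = RSS / df
    rss <- colSums((y - Xr %*% beta)^2)
    expect_equal(unname(fit2$sigma2), unname(rss / (30 - 5)),
                 tolerance = 1e-10)
  })
})

test_that("contrast extraction selects the group column and is linear", {
  withr::with_seed(33, {
    y1 <- matrix(rnorm(24 * 8), 24, 8,
                 dimnames = list(NULL, sprintf("g%02d", 1:8)))
    y2 <- matrix(rnorm(24 * 8), 24, 8,
                 dimnames = list(NULL, sprintf("g%02d", 1:8)))
    grp <- rep(c("background", "g_i", "g_j"), each = 8)
    X <- build_design(grp)
  })
  d1 <- contrast_estimates(fit_ols(y1, X), "g_i")
  d2 <- contrast_estimates(fit_ols(y2, X), "g_i")
  dsum <- contrast_estimates(fit_ols(y1 + y2, X), "g_i")
  expect_equal(dsum$estimates, d1$estimates + d2$estimates,
               tolerance = 1e-10)
  # oracle: c' beta-hat with c selecting the group column
  beta <- solve(crossprod(X$matrix), crossprod(X$matrix, y1))
  expect_equal(unname(d1$estimates),
               unname(beta["groupg_i", ]), tolerance = 1e-10)
  expect_error(contrast_estimates(fit_ols(y1, X), "nope"),
               class = "cider_error")
})

test_that("noise-free additive group effects are recovered exactly", {
  grp <- rep(c("background", "g_i", "g_j"), each = 6)
  delta <- c(2, -1, 0.5, 0)
  y <- matrix(1, 18, 4) + outer(as.numeric(grp == "g_i"), delta)
  colnames(y) <- paste0("g", 1:4)
  d <- contrast_estimates(fit_ols(y, build_design(grp)), "g_i")
  expect_equal(unname(d$estimates), delta, tolerance = 1e-12)
})

test_that("residuals are orthogonal to every design column", {
  withr::with_seed(35, {
    for (rep in 1:5) {
      X <- cbind(1, matrix(rnorm(25 * 3), 25, 3))
      colnames(X) <- c("(Intercept)", paste0("v", 1:3))
      y <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("g", 1:6)))
      fit <- fit_ols(y, X)
      resid <- y - X %*% t(fit$coefficients)
      expect_lt(max(abs(crossprod(X, resid))), 1e-6)
    }
  })
})

test_that("additive batch shifts leave group contrasts unchanged", {
  withr::with_seed(37, {
    n <- 36
    grp <- rep(c("background", "g_i", "g_j"), 12)
    batch <- rep(c("b1", "b2"), each = 18)
    y <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("g", 1:20)))
    shift <- rnorm(20, 3, 1)
  })
  X <- build_design(grp, batch = batch)
  y_shift <- y
  y_shift[batch == "b2", ] <- sweep(y[batch == "b2", ], 2, -shift)
  d0 <- contrast_estimates(fit_ols(y, X), "g_i")
  d1 <- contrast_estimates(fit_ols(y_shift, X), "g_i")
  expect_lt(max(abs(d0$estimates - d1$estimates)), 1e-8)
})

test_that("variance moderation matches limma's closed form without trend", {
  skip_if_not_installed("limma")
  withr::with_seed(41, {
    grp <- rep(c("background", "g_i"), each = 20)
    X <- build_design(grp)
    y <- matrix(rnorm(40 * 200, sd = rep(sqrt(rchisq(200, 5) / 5),
                                         each = 40)), 40, 200)
    colnames(y) <- sprintf("g%03d", 1:200)
  })
  fit <- fit_ols(y, X)
  mod <- eb_moderate_trend(fit, trend = FALSE)
  sq <- limma::squeezeVar(fit$sigma2, df = fit$df_residual)
  expect_equal(attr(mod, "df_prior"), sq$df.prior, tolerance = 1e-6)
  expect_equal(unname(mod$posterior_var), unname(sq$var.post),
               tolerance = 1e-8)
  # BH ordering is preserved and adjusted p >= p
  expect_true(all(mod$adj_p >= mod$p_value - 1e-15))
  expect_true(all(mod$adj_p <= 1 + 1e-15))
})

test_that("trend moderation agrees with limma-trend on moderated t", {
  skip_if_not_installed("limma")
  withr::with_seed(43, {
    grp <- rep(c("background", "g_i"), each = 25)
    X <- build_design(grp)
    mu <- runif(300, 0.5, 6)
    y <- sapply(mu, function(m) rnorm(50, m, sd = 0.2 + 0.3 * sqrt(m)))
    colnames(y) <- sprintf("g%03d", 1:300)
  })
  fit <- fit_ols(y, X)
  mod <- eb_moderate_trend(fit)
  lf <- limma::lmFit(t(y), X$matrix)
  lf <- limma::eBayes(lf, trend = TRUE)
  # same estimator family, different lowess details: demand tight
  # agreement in ranking and close numerical agreement
  expect_gt(cor(mod$t, lf$t[, "groupg_i"]), 0.999)
  expect_lt(median(abs(mod$posterior_var - lf$s2.post) / lf$s2.post), 0.05)
})

test_that("degenerate moderation cases behave as the formula forces", {
  grp <- rep(c("background", "g_i"), each = 10)
  X <- build_design(grp)
  withr::with_seed(45, {
    y <- matrix(rnorm(20 * 50), 20, 50)
  })
  colnames(y) <- sprintf("g%02d", 1:50)
  # all genes identical sigma2: posterior variance equals sigma2
  fit <- fit_ols(y, X)
  fit$sigma2 <- rep(2, 50)  # force the degenerate case
  mod <- eb_moderate_trend(fit, trend = FALSE)
  expect_equal(unname(mod$posterior_var), rep(2, 50), tolerance = 1e-6)

  # fewer than 10 genes: warning, unmoderated
  ysmall <- y[, 1:5]
  fs <- fit_ols(ysmall, X)
  expect_warning(ms <- eb_moderate_trend(fs), class = "cider_warning")
  expect_equal(unname(ms$posterior_var), unname(fs$sigma2))
})

test_that("BH adjustment reproduces the step-up oracle", {
  # frozen from the step-up procedure on p = (.01,.02,.03,.04), m = 4:
  # min over j>=i of p_j * m / j -> all 0.04
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
})
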