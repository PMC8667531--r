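#' Build a design matrix for group-versus-background modelling
#'
#' Assembles treatment-coded dummy columns for the 3-level group factor
#' (reference = background), the batch factor, any extra categorical
#' covariates (e.g. donor nested in species or disease), and one numeric
#' column for the scaled cellular detection rate. Columns are admitted in
#' priority order group > batch > extras > CDR; a column that is constant
#' or linearly dependent on the columns already admitted is dropped with a
#' warning, so when group and batch are partially confounded the group
#' effect of interest survives.
#'
#' @param group factor/character per cell; `reference` must be a level.
#' @param batch factor/character per cell (may be single-level: no columns).
#' @param cdr numeric scaled CDR per cell, or a `CDRVector`, or `NULL`.
#' @param extra named list / data.frame of additional categorical columns.
#' @param reference reference level for `group` (default `"background"`).
#' @return A `DesignMatrix`: list with `matrix` (n x p), `term_map`
#'   (per-column term class) and `dropped` (names of discarded columns).
#' @export
build_design <- function(group, batch = NULL, cdr = NULL, extra = NULL,
                         reference = "background") {
  group <- as.character(group)
  n <- length(group)
  if (!reference %in% group)
    stop_cider("cider_design_error", "reference level '", reference,
               "' absent from group labels")
  if (inherits(cdr, "CDRVector")) cdr <- cdr$scaled

  cols <- list(`(Intercept)` = rep(1, n))
  terms <- c(`(Intercept)` = "intercept")
  add_factor <- function(values, prefix, term, cols, terms) {
    values <- as.character(values)
    if (length(values) != n)
      stop_cider("cider_design_error", prefix, " has length ",
                 length(values), ", expected ", n)
    lev <- sort(unique(values))
    for (l in lev[-1L]) {  # first level is the reference
      nm <- paste0(prefix, l)
      cols[[nm]] <- as.numeric(values == l)
      terms[nm] <- term
    }
    list(cols = cols, terms = terms)
  }

  glev <- c(reference, setdiff(sort(unique(group)), reference))
  for (l in glev[-1L]) {
    nm <- paste0("group", l)
    cols[[nm]] <- as.numeric(group == l)
    terms[nm] <- "group-level"
  }
  if (!is.null(batch)) {
    r <- add_factor(batch, "batch", "batch-level", cols, terms)
    cols <- r$cols; terms <- r$terms
  }
  if (!is.null(extra) && length(extra)) {
    extra <- as.data.frame(extra, stringsAsFactors = FALSE)
    for (nm in colnames(extra)) {
      r <- add_factor(extra[[nm]], nm, "covariate-level", cols, terms)
      cols <- r$cols; terms <- r$terms
    }
  }
  if (!is.null(cdr)) {
    if (length(cdr) != n)
      stop_cider("cider_design_error", "cdr has length ", length(cdr),
                 ", expected ", n)
    cols[["cdr"]] <- as.numeric(cdr)
    terms["cdr"] <- "cdr"
  }

  X <- matrix(0, n, 0)
  kept <- character(0)
  dropped <- character(0)
  tol <- 1e-9
  for (nm in names(cols)) {
    cand <- cbind(X, cols[[nm]])
    if (nm != "(Intercept)" && sd(cols[[nm]]) == 0) {
      dropped <- c(dropped, nm)
      next
    }
    if (qr(cand, tol = tol)$rank > ncol(X)) {
      X <- cand
      kept <- c(kept, nm)
    } else {
      dropped <- c(dropped, nm)
      if (terms[nm] == "group-level")
        stop_cider("cider_design_error", "group coefficient '", nm,
                   "' is aliased with columns already in the design (",
                   paste(kept, collapse = ", "), ")")
    }
  }
  if (length(dropped))
    warn_cider("cider_design_warning", "dropped dependent/constant columns: ",
               paste(dropped, collapse = ", "))
  colnames(X) <- kept
  structure(list(matrix = X, term_map = terms[kept], dropped = dropped,
                 reference = reference),
            class = "DesignMatrix")
}

#' Fit per-gene ordinary least squares for a shared design
#'
#' One QR factorization of the design is reused across all genes, so the
#' fit costs one decomposition plus two triangular solves per gene block.
#'
#' @param em an `ExpressionMatrix`, or a numeric cells x genes matrix,
#'   whose rows align with the rows of `X`.
#' @param X a [build_design()] result (or bare numeric matrix).
#' @return A `FitResult`: `coefficients` (genes x p), `sigma2`,
#'   `df_residual`, `mean_expr`, `cov_unscaled` (diag of `(X'X)^-1`) and
#'   the design.
#' @export
fit_ols <- function(em, X) {
  Y <- if (inherits(em, "ExpressionMatrix")) as.matrix(em$values) else as.matrix(em)
  Xm <- if (inherits(X, "DesignMatrix")) X$matrix else X
  if (nrow(Y) != nrow(Xm))
    stop_cider("cider_design_error", "response has ", nrow(Y),
               " rows but design has ", nrow(Xm))
  p <- ncol(Xm)
  df <- nrow(Xm) - p
  if (df <= 0)
    stop_cider("cider_design_error",
               "non-positive residual degrees of freedom (n = ", nrow(Xm),
               ", p = ", p, ")")
  qrX <- qr(Xm)
  if (qrX$rank < p)
    stop_cider("cider_design_error", "design matrix is rank deficient")
  coef <- qr.coef(qrX, Y)                    # p x G
  resid <- qr.resid(qrX, Y)
  sigma2 <- colSums(resid^2) / df
  R <- qr.R(qrX)
  xtx_inv <- chol2inv(R)
  dimnames(xtx_inv) <- list(colnames(Xm), colnames(Xm))
  structure(list(coefficients = t(coef),     # genes x p
                 sigma2 = sigma2,
                 df_residual = df,
                 mean_expr = colMeans(Y),
                 cov_unscaled = xtx_inv,
                 gene_ids = colnames(Y),
                 design = Xm),
            class = "FitResult")
}

#' Extract a group-versus-background differential expression signature
#'
#' With background as the reference level of the group factor, the
#' contrast of a group against background is exactly that group's
#' coefficient column: one log2 fold-change per gene.
#'
#' @param fit a [fit_ols()] result whose design contains `group<label>`.
#' @param group the group label.
#' @param background description of the background cells (metadata only).
#' @return A `DESignature`: named per-gene `estimates` plus provenance.
#' @export
contrast_estimates <- function(fit, group, background = "background") {
  stopifnot(inherits(fit, "FitResult"))
  col <- paste0("group", group)
  if (!col %in% colnames(fit$coefficients))
    stop_cider("cider_design_error", "no coefficient for group '", group,
               "' in the fit (have: ",
               paste(colnames(fit$coefficients), collapse = ", "), ")")
  est <- fit$coefficients[, col]
  names(est) <- fit$gene_ids
  structure(list(estimates = est, gene_ids = fit$gene_ids,
                 group = group, background = background),
            class = "DESignature")
}

# Newton inversion of the trigamma function (for the method-of-moments
# prior degrees of freedom); monotone decreasing, so the iteration is safe.
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < 1e-8 * x) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of the scaled-F model for residual variances:
# log s^2 is pivoted by digamma/trigamma moments of the chi^2; the excess
# variance of the pivot over trigamma(df/2) estimates trigamma(d0/2).
fit_variance_prior <- function(sigma2, df, mean_expr = NULL, trend = TRUE,
                               span = 0.5) {
  x <- pmax(sigma2, 0)
  m <- stats::median(x)
  if (m == 0) {
    warn_cider("cider_eb_warning",
               "more than half of residual variances are zero")
    m <- 1
  }
  x <- pmax(x, 1e-5 * m)   # keep log finite for all-zero genes
  z <- log(x)
  e <- z - digamma(df / 2) + log(df / 2)
  if (trend && !is.null(mean_expr)) {
    lo <- lowess(mean_expr, e, f = span)
    emean <- stats::approx(lo$x, lo$y, xout = mean_expr, rule = 2,
                           ties = mean)$y
  } else {
    emean <- rep(mean(e), length(x))
  }
  resid_e <- e - emean
  evar <- var(resid_e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s20 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s20 <- if (trend && !is.null(mean_expr)) exp(emean)
           else rep(mean(x), length(x))
  }
  list(df_prior = d0, var_prior = s20)
}

#' Empirical Bayes moderation with a mean-variance trend
#'
#' Shrinks per-gene residual variances toward a smooth function of mean
#' expression (lowess trend), with the prior degrees of freedom estimated
#' by method of moments on the log variances, and forms moderated
#' t-statistics for a chosen coefficient with Benjamini-Hochberg adjusted
#' p values.
#'
#' @param fit a [fit_ols()] result.
#' @param coef name of the coefficient to test (default: first
#'   `group`-prefixed column).
#' @param trend use the mean-expression trend (default `TRUE`); with
#'   `FALSE` the prior is a single constant variance.
#' @return A `ModeratedStats` data.frame: `gene`, `logFC`, `t`, `p_value`,
#'   `adj_p`, `posterior_var`, `mean_expr`, with attributes `df_prior`,
#'   `df_total`, `var_prior`.
#' @export
eb_moderate_trend <- function(fit, coef = NULL, trend = TRUE) {
  stopifnot(inherits(fit, "FitResult"))
  cn <- colnames(fit$coefficients)
  coef <- coef %||% cn[startsWith(cn, "group")][1L]
  if (is.na(coef) || !coef %in% cn)
    stop_cider("cider_design_error", "coefficient '", coef, "' not in fit")
  G <- nrow(fit$coefficients)
  df <- fit$df_residual
  logFC <- fit$coefficients[, coef]
  su <- sqrt(fit$cov_unscaled[coef, coef])
  if (G < 10) {
    warn_cider("cider_eb_warning",
               "fewer than 10 genes; returning unmoderated t statistics")
    post_var <- fit$sigma2
    d0 <- 0
  } else {
    pr <- fit_variance_prior(fit$sigma2, df, fit$mean_expr, trend = trend)
    d0 <- pr$df_prior
    post_var <- if (is.infinite(d0)) pr$var_prior else
      (d0 * pr$var_prior + df * fit$sigma2) / (d0 + df)
  }
  tstat <- logFC / (sqrt(post_var) * su)
  df_total <- df + d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = fit$gene_ids, logFC = logFC, t = tstat,
                    p_value = p, adj_p = p.adjust(p, method = "BH"),
                    posterior_var = post_var, mean_expr = fit$mean_expr,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- d0
  attr(out, "df_total") <- df_total
  attr(out, "var_prior") <- if (G < 10) NA_real_ else pr$var_prior
  class(out) <- c("ModeratedStats", "data.frame")
  out
}
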