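#' Fisher z-transformation of a correlation coefficient
#'
#' `z(r) = ln((1 + r) / (1 - r)) / 2`, mapping correlations onto an
#' approximately Gaussian scale; `|r| >= 1` is clipped just inside the
#' open interval with a warning.
#'
#' @param r numeric vector of correlations.
#' @return Transformed values, same length.
#' @export
fisher_z <- function(r) {
  eps <- 1e-12
  if (any(abs(r) >= 1)) {
    warn_cider("cider_clip_warning", "|r| >= 1 clipped to 1 - 1e-12")
    r <- pmin(pmax(r, -1 + eps), 1 - eps)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Leave-one-gene-out influence on an inter-group similarity
#'
#' For each gene, the correlation of the two signatures with that gene
#' removed (`r_i`) is obtained by downdating the five sufficient sums
#' (O(1) per gene rather than a full re-scan), and the influence is
#' `z(r) - z(r_i)`. Positive influence means the gene pushes the two
#' groups together; negative influence means it drives them apart.
#'
#' @param d_i,d_j `DESignature`s over identical gene sets (>= 4 genes).
#' @return An `InfluenceTable` data.frame sorted by `|influence|`
#'   descending: `gene`, `d_i`, `d_j`, `r_loo`, `influence`, with an
#'   `"overall_r"` attribute.
#' @export
gene_influence <- function(d_i, d_j) {
  stopifnot(inherits(d_i, "DESignature"), inherits(d_j, "DESignature"))
  if (!identical(d_i$gene_ids, d_j$gene_ids))
    stop_cider("cider_input_error", "signatures are not gene-aligned")
  x <- unname(d_i$estimates); y <- unname(d_j$estimates)
  G <- length(x)
  if (G < 4L)
    stop_cider("cider_input_error", "need >= 4 genes for influence")
  r <- ider_similarity(d_i, d_j)

  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  n1 <- G - 1
  num <- (sxy - x * y) - (sx - x) * (sy - y) / n1
  vx <- (sxx - x^2) - (sx - x)^2 / n1
  vy <- (syy - y^2) - (sy - y)^2 / n1
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r_loo <- ifelse(den <= .Machine$double.eps * G, NA_real_, num / den)
  r_loo <- pmin(pmax(r_loo, -1), 1)
  infl <- suppressWarnings(fisher_z(r) - fisher_z(r_loo))

  out <- data.frame(gene = d_i$gene_ids, d_i = x, d_j = y,
                    r_loo = r_loo, influence = infl,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$influence), out$gene), ]
  rownames(out) <- NULL
  attr(out, "overall_r") <- r
  attr(out, "pair") <- c(d_i$group, d_j$group)
  class(out) <- c("InfluenceTable", "data.frame")
  out
}

#' Cross-batch marker genes for final clusters
#'
#' For each final cluster, fits a target-versus-background per-gene model
#' with batch, scaled CDR and any extra covariates regressed out, applies
#' empirical Bayes trend moderation, and filters by adjusted p value and
#' log2 fold-change. Thresholds are free parameters; published analyses
#' have used values as stringent as adjusted p < 1.83e-18 with
#' log2 fold-change > 1.47, but sensible cutoffs are data-dependent.
#'
#' @param em `ExpressionMatrix`; `meta` aligned metadata with `batch`.
#' @param final_assignment per-cell final-cluster labels.
#' @param extra_covariates metadata columns regressed out besides batch.
#' @param lfc_min,adjp_max marker filters (defaults 1 and 0.05).
#' @param gene_set genes to test; default: genes detected in >= 5% of all
#'   cells.
#' @return Named list (one `ModeratedStats`-derived data.frame per
#'   cluster) of markers passing the filters, sorted by adjusted p.
#' @export
find_markers <- function(em, meta, final_assignment,
                         extra_covariates = NULL, lfc_min = 1,
                         adjp_max = 0.05, gene_set = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  labs <- unique(final_assignment[!is.na(final_assignment)])
  if (length(labs) < 2L)
    stop_cider("cider_input_error", "need >= 2 final clusters for markers")
  gene_set <- gene_set %||% working_gene_set(em, seq_len(nrow(em$values)))
  Y <- as.matrix(em$values[, gene_set, drop = FALSE])
  cdr <- compute_cdr(em)
  out <- list()
  for (cl in sort(as.character(labs))) {
    in_cl <- !is.na(final_assignment) & final_assignment == cl
    if (sum(in_cl) < 2L) {
      warn_cider("cider_marker_warning", "cluster '", cl,
                 "' has < 2 cells; skipped")
      next
    }
    group <- ifelse(in_cl, "target", "background")
    extra <- if (length(extra_covariates))
      meta[, extra_covariates, drop = FALSE] else NULL
    X <- suppressWarnings(
      build_design(group, batch = meta$batch, cdr = cdr$scaled,
                   extra = extra))
    fit <- fit_ols(Y, X)
    stats <- eb_moderate_trend(fit, coef = "grouptarget")
    keep <- stats$adj_p <= adjp_max & stats$logFC >= lfc_min
    tab <- stats[keep, , drop = FALSE]
    tab <- tab[order(tab$adj_p, -tab$logFC), ]
    rownames(tab) <- NULL
    out[[cl]] <- tab
  }
  out
}

#' Write marker tables or an influence table as TSV
#' @param x a list of marker data.frames or an `InfluenceTable`.
#' @param path output file (markers get a `cluster` column prepended).
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    tab <- do.call(rbind, lapply(names(x), function(cl)
      if (nrow(x[[cl]])) cbind(cluster = cl, x[[cl]]) else NULL))
    utils::write.table(tab %||% data.frame(), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
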