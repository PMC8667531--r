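#' Construct a batch-specific initial cluster
#'
#' @param label unique cluster label (conventionally batch tag plus
#'   within-batch cluster id or annotation).
#' @param batch batch the member cells belong to.
#' @param cell_indices integer indices of member cells into the expression
#'   matrix rows.
#' @return An `InitialCluster` list.
#' @export
initial_cluster <- function(label, batch, cell_indices) {
  if (length(cell_indices) == 0L)
    stop_cider("cider_input_error", "empty initial cluster '", label, "'")
  structure(list(label = as.character(label), batch = as.character(batch),
                 cell_indices = as.integer(cell_indices),
                 size = length(cell_indices)),
            class = "InitialCluster")
}

#' Downsample initial clusters to a common size
#'
#' Each cluster contributes exactly `target` draws: without replacement
#' when it has at least `target` cells, with replacement otherwise.
#' Clusters smaller than 15 cells trigger a warning — their signatures are
#' noisy and the workflow discourages them.
#'
#' @param clusters list of [initial_cluster()] objects.
#' @param target draws per cluster (default 40, the midpoint of the
#'   recommended 35-50 range).
#' @param seed integer seed; identical seeds give identical subsets.
#' @return Named list of integer index vectors (one per cluster).
#' @export
downsample_groups <- function(clusters, target = 40, seed = 1) {
  stopifnot(length(clusters) >= 1L, target >= 1)
  if (target < 35 || target > 50)
    warn_cider("cider_downsample_warning", "downsample target ", target,
               " is outside the recommended 35-50 range")
  out <- vector("list", length(clusters))
  names(out) <- vapply(clusters, `[[`, character(1), "label")
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    if (cl$size < 15)
      warn_cider("cider_downsample_warning", "cluster '", cl$label,
                 "' has only ", cl$size, " cells (< 15); sampling with ",
                 "replacement from a cluster this small is unreliable")
    out[[k]] <- with_seed(hash_seed(seed, "downsample", cl$label), {
      if (cl$size >= target) sample(cl$cell_indices, target)
      else sample(cl$cell_indices, target, replace = TRUE)
    })
  }
  out
}

# Genes detected (nonzero) in at least `min_frac` of the given cells.
working_gene_set <- function(em, cells, min_frac = 0.05) {
  det <- Matrix::colMeans(em$values[cells, , drop = FALSE] != 0)
  em$gene_ids[det >= min_frac]
}

#' Compute the two differential expression signatures for a cluster pair
#'
#' Builds a working set from downsampled members of `g_i`, `g_j` and a
#' background of equal-size draws from every other initial cluster, fits
#' one per-gene linear model with a 3-level group factor (background as
#' reference), batch, scaled CDR and any extra covariates, and returns the
#' two group-versus-background coefficient vectors.
#'
#' When only the two clusters exist (no background), the fit falls back to
#' the direct each-versus-other contrast with a warning.
#'
#' @param em an `ExpressionMatrix` over all cells.
#' @param meta cell metadata aligned with `em` rows (needs `batch`).
#' @param g_i,g_j [initial_cluster()] objects.
#' @param clusters all initial clusters in the analysis (background pool);
#'   defaults to just the pair.
#' @param extra_covariates character names of metadata columns to regress
#'   out in addition to batch.
#' @param gene_set gene ids to fit; default: genes detected in >= 5% of
#'   the working-set cells.
#' @param target downsampling size per cluster.
#' @param background_cap background is capped at `background_cap * target`
#'   cells by shrinking the per-cluster draw.
#' @param seed integer seed for the downsampling.
#' @return List with `d_i` and `d_j` (`DESignature`s over the same genes)
#'   and the `fit`.
#' @export
compute_des_pair <- function(em, meta, g_i, g_j, clusters = NULL,
                             extra_covariates = NULL, gene_set = NULL,
                             target = 40, background_cap = 10, seed = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  clusters <- clusters %||% list(g_i, g_j)
  labels <- vapply(clusters, `[[`, character(1), "label")
  others <- clusters[!labels %in% c(g_i$label, g_j$label)]

  idx <- downsample_groups(list(g_i, g_j), target = target, seed = seed)
  cells_i <- idx[[g_i$label]]
  cells_j <- idx[[g_j$label]]

  if (length(others)) {
    per <- target
    if (length(others) * target > background_cap * target)
      per <- max(1L, floor(background_cap * target / length(others)))
    bg_idx <- downsample_groups(others, target = per,
                                seed = hash_seed(seed, "background"))
    cells_bg <- unlist(bg_idx, use.names = FALSE)
  } else {
    cells_bg <- integer(0)
  }

  cells <- c(cells_i, cells_j, cells_bg)
  group <- c(rep("g_i", length(cells_i)), rep("g_j", length(cells_j)),
             rep("background", length(cells_bg)))
  batch <- meta$batch[cells]
  cdr <- compute_cdr(em, within = cells)
  extra <- if (length(extra_covariates))
    meta[cells, extra_covariates, drop = FALSE] else NULL
  gene_set <- gene_set %||% working_gene_set(em, cells)
  if (length(gene_set) < 3L)
    stop_cider("cider_input_error",
               "fewer than 3 genes pass detection filtering for pair ",
               g_i$label, " / ", g_j$label)
  Y <- as.matrix(em$values[cells, gene_set, drop = FALSE])

  if (!length(cells_bg)) {
    warn_cider("cider_background_warning",
               "no background clusters for pair ", g_i$label, " / ",
               g_j$label, "; falling back to the direct each-vs-other contrast")
    X <- build_design(ifelse(group == "g_i", "g_i", "g_j"), batch = batch,
                      cdr = cdr, extra = extra, reference = "g_j")
    fit <- fit_ols(Y, X)
    d_i <- contrast_estimates(fit, "g_i", background = g_j$label)
    d_j <- d_i
    d_j$estimates <- -d_i$estimates
    d_j$group <- "g_j"
  } else {
    X <- build_design(group, batch = batch, cdr = cdr, extra = extra,
                      reference = "background")
    fit <- fit_ols(Y, X)
    d_i <- contrast_estimates(fit, "g_i")
    d_j <- contrast_estimates(fit, "g_j")
  }
  d_i$group <- g_i$label
  d_j$group <- g_j$label
  list(d_i = d_i, d_j = d_j, fit = fit)
}

#' IDER similarity between two differential expression signatures
#'
#' The Pearson correlation of the two per-gene contrast vectors; ranges
#' over \[-1, 1\].
#'
#' @param d_i,d_j `DESignature`s over identical gene sets.
#' @return A single numeric similarity.
#' @export
ider_similarity <- function(d_i, d_j) {
  stopifnot(inherits(d_i, "DESignature"), inherits(d_j, "DESignature"))
  if (!identical(d_i$gene_ids, d_j$gene_ids)) {
    common <- intersect(d_i$gene_ids, d_j$gene_ids)
    if (length(common) < 3L)
      stop_cider("cider_input_error", "signatures share fewer than 3 genes")
    x <- d_i$estimates[common]; y <- d_j$estimates[common]
  } else {
    x <- d_i$estimates; y <- d_j$estimates
  }
  if (length(x) < 3L)
    stop_cider("cider_input_error", "need >= 3 genes for a similarity")
  if (sd(x) == 0 || sd(y) == 0)
    stop_cider("cider_degenerate_error",
               "zero-variance signature; similarity undefined")
  cor(x, y)
}

#' Pairwise IDER similarity matrix over initial clusters
#'
#' Each in-scope pair is computed once with its own seed derived from the
#' global seed and the sorted pair labels, so the matrix is independent of
#' pair order and worker count. By default only cross-batch pairs are
#' computed (the clustering scope); within-batch entries are masked (`NA`).
#'
#' @param em `ExpressionMatrix`; `meta` aligned metadata.
#' @param clusters list of [initial_cluster()] objects.
#' @param extra_covariates metadata columns regressed out besides batch.
#' @param scope `"cross_batch"` or `"all_pairs"`, or a 2-column matrix of
#'   label pairs to compute.
#' @param target,background_cap,gene_set passed to [compute_des_pair()].
#' @param n_workers forked workers via `parallel::mclapply` (result is
#'   identical for any count).
#' @param seed global seed.
#' @return A `SimilarityMatrix`: `S` (k x k, diagonal 1, masked pairs
#'   `NA`), `labels`, `batches`, `mask`.
#' @export
pairwise_similarity_matrix <- function(em, meta, clusters,
                                       extra_covariates = NULL,
                                       scope = c("cross_batch", "all_pairs"),
                                       target = 40, background_cap = 10,
                                       gene_set = NULL, n_workers = 1,
                                       seed = 1) {
  k <- length(clusters)
  if (k < 2L)
    stop_cider("cider_input_error", "need >= 2 initial clusters")
  labels <- vapply(clusters, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop_cider("cider_input_error", "duplicate initial cluster labels")
  batches <- vapply(clusters, `[[`, character(1), "batch")

  if (is.matrix(scope)) {
    pairs <- scope
  } else {
    scope <- match.arg(scope)
    pairs <- t(utils::combn(labels, 2L))
    if (scope == "cross_batch") {
      bt <- stats::setNames(batches, labels)
      pairs <- pairs[bt[pairs[, 1L]] != bt[pairs[, 2L]], , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L)
    stop_cider("cider_input_error", "no cluster pairs in scope")

  one_pair <- function(r) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    key <- sort(c(a, b))
    s <- tryCatch({
      des <- compute_des_pair(em, meta,
                              clusters[[match(a, labels)]],
                              clusters[[match(b, labels)]],
                              clusters = clusters,
                              extra_covariates = extra_covariates,
                              gene_set = gene_set, target = target,
                              background_cap = background_cap,
                              seed = hash_seed(seed, key[1L], key[2L]))
      ider_similarity(des$d_i, des$d_j)
    }, cider_error = function(e)
      stop_cider("cider_pair_error", "pair ", a, " / ", b, ": ",
                 conditionMessage(e)))
    s
  }
  vals <- if (n_workers > 1L) {
    unlist(parallel::mclapply(seq_len(nrow(pairs)), one_pair,
                              mc.cores = n_workers, mc.set.seed = FALSE))
  } else {
    vapply(seq_len(nrow(pairs)), one_pair, numeric(1))
  }

  S <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(S) <- 1
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs[r, 1L], labels); j <- match(pairs[r, 2L], labels)
    S[i, j] <- S[j, i] <- vals[r]
  }
  structure(list(S = S, labels = labels, batches = batches,
                 mask = !is.na(S)),
            class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat("SimilarityMatrix over", length(x$labels), "initial clusters;",
      sum(x$mask[upper.tri(x$mask)]), "computed pairs\n")
  print(round(x$S, 3))
  invisible(x)
}

#' Write a similarity matrix as a labelled square TSV
#' @param sm a `SimilarityMatrix`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sm, path) {
  stopifnot(inherits(sm, "SimilarityMatrix"))
  df <- data.frame(cluster = sm$labels, sm$S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Threshold a similarity matrix into a weighted cluster graph
#'
#' @param sm a `SimilarityMatrix`.
#' @param edge_threshold edges are kept where similarity exceeds this.
#' @return An `igraph` undirected graph; vertices carry `batch`, edges
#'   carry `weight` (the similarity).
#' @export
similarity_graph <- function(sm, edge_threshold = 0) {
  stopifnot(inherits(sm, "SimilarityMatrix"))
  ut <- which(upper.tri(sm$S) & sm$mask & sm$S > edge_threshold,
              arr.ind = TRUE)
  edges <- data.frame(from = sm$labels[ut[, 1L]],
                      to = sm$labels[ut[, 2L]],
                      weight = sm$S[ut])
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sm$labels, batch = sm$batches))
  g
}

#' Write a cluster similarity graph as GraphML and an edge-list TSV
#' @param g an `igraph` graph from [similarity_graph()].
#' @param prefix output path prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`.
#' @return The two paths, invisibly.
#' @export
write_graph_outputs <- function(g, prefix) {
  gml <- paste0(prefix, ".graphml")
  tsv <- paste0(prefix, "_edges.tsv")
  igraph::write_graph(g, gml, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(el, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = gml, edges = tsv))
}
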