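# Shared-nearest-neighbor Louvain on an embedding (cells x dims).
# k is reduced for tiny inputs; a batch smaller than 3 cells collapses
# to a single community.
snn_louvain <- function(embedding, k = 20, resolution = 0.4, seed = 1) {
  n <- nrow(embedding)
  if (n < 3L) return(rep(1L, n))
  k_use <- min(k, n - 1L)
  if (k_use < k)
    warn_cider("cider_cluster_warning", "only ", n,
               " cells; SNN neighborhood reduced to k = ", k_use)
  g <- bluster::makeSNNGraph(embedding, k = k_use, type = "jaccard")
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  as.integer(igraph::membership(comm))
}

#' De novo initial clusters: within-batch Louvain plus similarity premerge
#'
#' Within each batch, cells are clustered on an SNN graph (HVG selection,
#' PCA, Jaccard-weighted shared nearest neighbors, Louvain). Pairs of
#' same-batch clusters whose IDER similarity exceeds `premerge_threshold`
#' are then unioned (transitively), yielding the batch-specific initial
#' clusters for the cross-batch stage.
#'
#' @param em `ExpressionMatrix`; `meta` aligned metadata with `batch`.
#' @param n_hvgs,n_pcs,k,resolution within-batch graph-clustering knobs.
#' @param premerge_threshold same-batch clusters with similarity above
#'   this merge; `Inf` disables premerging.
#' @param target downsampling size for the premerge similarity.
#' @param seed integer seed.
#' @return List of [initial_cluster()] objects, labels `batch.cluster`.
#' @export
initial_clusters_dn <- function(em, meta, n_hvgs = 2000, n_pcs = 10,
                                k = 20, resolution = 0.4,
                                premerge_threshold = 0.9, target = 40,
                                seed = 1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  meta_batches <- sort(unique(meta$batch))
  clusters <- list()
  for (b in meta_batches) {
    cells <- which(meta$batch == b)
    sub <- structure(list(values = em$values[cells, , drop = FALSE],
                          cell_ids = em$cell_ids[cells],
                          gene_ids = em$gene_ids,
                          scale_factor = em$scale_factor,
                          pseudocount = em$pseudocount),
                     class = "ExpressionMatrix")
    if (length(cells) <= k) {
      warn_cider("cider_cluster_warning", "batch '", b, "' has ",
                 length(cells), " cells (<= SNN k); kept as one cluster")
      memb <- rep(1L, length(cells))
    } else {
      hvgs <- select_hvgs(sub, n = min(n_hvgs, length(sub$gene_ids)))
      pcs <- compute_pca(sub, genes = hvgs,
                         n_pcs = min(n_pcs, length(cells) - 1L,
                                     length(hvgs) - 1L))
      memb <- snn_louvain(pcs, k = k, resolution = resolution,
                          seed = hash_seed(seed, "louvain", b))
    }
    memb <- premerge_within_batch(em, meta, cells, memb, b,
                                  premerge_threshold, target, seed)
    for (cl in sort(unique(memb))) {
      lab <- paste0(b, ".", cl)
      clusters[[lab]] <- initial_cluster(lab, b, cells[memb == cl])
    }
  }
  unname(clusters)
}

# Merge same-batch Louvain clusters whose IDER similarity exceeds the
# threshold; merging is transitive (connected components of the
# above-threshold graph). Membership ids are renumbered 1..m.
premerge_within_batch <- function(em, meta, cells, memb, batch,
                                  threshold, target, seed) {
  ids <- sort(unique(memb))
  if (length(ids) < 2L || is.infinite(threshold))
    return(match(memb, ids))
  cl <- lapply(ids, function(i)
    initial_cluster(paste0(batch, ".pre", i), batch, cells[memb == i]))
  sm <- suppressWarnings(
    pairwise_similarity_matrix(em, meta, cl, scope = "all_pairs",
                               target = target,
                               seed = hash_seed(seed, "premerge", batch)))
  adj <- !is.na(sm$S) & sm$S > threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  as.integer(comp[match(memb, ids)])
}

#' Annotation-derived initial clusters
#'
#' One initial cluster per observed (batch, annotation) combination; the
#' label concatenates the batch tag and the annotation.
#'
#' @param meta metadata with `batch` and `annotation` columns.
#' @param sep label separator (default `"_"`).
#' @return List of [initial_cluster()] objects.
#' @export
initial_clusters_as <- function(meta, sep = "_") {
  if (!"annotation" %in% colnames(meta))
    stop_cider("cider_input_error", "metadata lacks an 'annotation' column")
  bad <- which(is.na(meta$annotation) | meta$annotation == "")
  if (length(bad))
    stop_cider("cider_input_error", "missing annotation for cells: ",
               paste(head(bad, 10L), collapse = ", "),
               if (length(bad) > 10L) " ..." else "")
  combos <- unique(meta[, c("batch", "annotation")])
  combos <- combos[order(combos$batch, combos$annotation), , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(r) {
    b <- combos$batch[r]; a <- combos$annotation[r]
    initial_cluster(paste(b, a, sep = sep), b,
                    which(meta$batch == b & meta$annotation == a))
  })
}

#' Final clustering: complete-linkage merging of initial clusters
#'
#' The similarity matrix is converted to distances `1 - S` (masked
#' within-batch entries count as distance 1, i.e. similarity 0: clusters
#' Louvain already separated should not merge through missing data), then
#' merged by complete-linkage agglomeration and cut at `cut_height`.
#' Rows are ordered by label before linkage so ties break reproducibly.
#'
#' @param sm a `SimilarityMatrix` (or bare symmetric matrix with
#'   dimnames).
#' @param cut_height distance at which the dendrogram is cut
#'   (default 0.55, i.e. clusters merge while similarity stays >= 0.45).
#' @return List with `assignment` (named final-cluster id per initial
#'   cluster), `linkage` (the `hclust` tree) and `distance`.
#' @export
final_clustering <- function(sm, cut_height = 0.55) {
  S <- if (inherits(sm, "SimilarityMatrix")) sm$S else sm
  if (!isSymmetric(unname(ifelse(is.na(S), -2, S))))
    stop_cider("cider_input_error", "similarity matrix is not symmetric")
  ord <- order(rownames(S))
  S <- S[ord, ord, drop = FALSE]
  D <- 1 - S
  D[is.na(D)] <- 1
  diag(D) <- 0
  hc <- hclust(as.dist(D), method = "complete")
  assignment <- cutree(hc, h = cut_height)
  list(assignment = assignment, linkage = hc, distance = D)
}

#' Run the full meta-clustering workflow
#'
#' Initial clustering (de novo Louvain or annotation-derived), pairwise
#' cross-batch IDER similarity, and complete-linkage final merging.
#' With a single batch the similarity scope degenerates to all pairs.
#'
#' @param em `ExpressionMatrix`; `meta` aligned metadata (needs `batch`;
#'   `annotation` for `mode = "as"`).
#' @param mode `"dn"` (Louvain-derived initial clusters) or `"as"`
#'   (annotation-derived).
#' @param extra_covariates metadata columns regressed out besides batch.
#' @param cut_height final dendrogram cut on the `1 - S` distance.
#' @param target downsampling size per initial cluster.
#' @param n_workers workers for the pairwise stage.
#' @param seed integer seed.
#' @param verbose log per-step timings to `message()`.
#' @param ... passed to [initial_clusters_dn()].
#' @return A `ClusterResult`: per-cell `initial` and `final` labels, the
#'   `similarity` matrix, the `linkage` tree, `clusters`, and `config`.
#' @export
run_cider <- function(em, meta, mode = c("dn", "as"),
                      extra_covariates = NULL, cut_height = 0.55,
                      target = 40, n_workers = 1, seed = 1,
                      verbose = FALSE, ...) {
  mode <- match.arg(mode)
  t0 <- Sys.time()
  clusters <- if (mode == "dn")
    initial_clusters_dn(em, meta, target = target, seed = seed, ...)
  else initial_clusters_as(meta)
  say <- function(...) if (verbose) message(sprintf(...))
  say("initial clustering: %d clusters [%.1fs]", length(clusters),
      as.numeric(Sys.time() - t0, units = "secs"))

  scope <- if (length(unique(meta$batch)) > 1L) "cross_batch" else "all_pairs"
  t1 <- Sys.time()
  sm <- pairwise_similarity_matrix(em, meta, clusters,
                                   extra_covariates = extra_covariates,
                                   scope = scope, target = target,
                                   n_workers = n_workers, seed = seed)
  say("similarity matrix: %d pairs [%.1fs]",
      sum(sm$mask[upper.tri(sm$mask)]),
      as.numeric(Sys.time() - t1, units = "secs"))

  fc <- final_clustering(sm, cut_height = cut_height)
  initial <- rep(NA_character_, nrow(em$values))
  for (cl in clusters) initial[cl$cell_indices] <- cl$label
  final <- unname(fc$assignment[initial])
  say("final clustering: %d populations", length(unique(final)))
  structure(list(initial = initial, final = final,
                 cell_ids = em$cell_ids, similarity = sm,
                 linkage = fc$linkage, clusters = clusters,
                 config = list(mode = mode, cut_height = cut_height,
                               target = target, seed = seed,
                               extra_covariates = extra_covariates)),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult (", x$config$mode, "CIDER): ", length(x$initial),
      " cells, ", length(unique(x$initial)), " initial clusters -> ",
      length(unique(x$final)), " final populations\n", sep = "")
  invisible(x)
}

#' Per-cell assignment table of a clustering result
#' @param x a `ClusterResult`; `meta` optional metadata to carry `batch`.
#' @return data.frame with cell, batch, initial and final columns.
#' @export
assignment_table <- function(x, meta = NULL) {
  stopifnot(inherits(x, "ClusterResult"))
  data.frame(cell = x$cell_ids,
             batch = if (!is.null(meta)) meta$batch else NA_character_,
             initial = x$initial, final = x$final,
             stringsAsFactors = FALSE)
}

#' Export the merge dendrogram as Newick with heights
#' @param x a `ClusterResult` or `hclust`; `path` output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(x, path) {
  hc <- if (inherits(x, "ClusterResult")) x$linkage else x
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Naive joint Louvain baseline on uncorrected expression
#'
#' HVG selection, PCA and SNN Louvain over all batches pooled, with no
#' batch handling: the comparison baseline that batch effects confound.
#'
#' @inheritParams initial_clusters_dn
#' @return Integer cluster label per cell.
#' @export
cluster_joint_louvain <- function(em, n_hvgs = 2000, n_pcs = 10, k = 20,
                                  resolution = 0.4, seed = 1) {
  hvgs <- select_hvgs(em, n = min(n_hvgs, length(em$gene_ids)))
  pcs <- compute_pca(em, genes = hvgs, n_pcs = n_pcs)
  snn_louvain(pcs, k = k, resolution = resolution,
              seed = hash_seed(seed, "joint"))
}
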