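#' Partition a batch-corrected embedding into cross-batch clusters
#'
#' Graph-based (SNN + Louvain) clustering of the corrected low-dimensional
#' representation. Communities smaller than `min_cluster_size` are
#' relabelled `"unclustered"` and excluded from downstream evaluation.
#'
#' @param embedding cells x dims numeric matrix (>= 2 dims).
#' @param method clustering backend; `"louvain"`.
#' @param k,resolution SNN-Louvain parameters.
#' @param min_cluster_size clusters below this size become
#'   `"unclustered"` (default 75).
#' @param seed integer seed.
#' @return Character cluster label per cell.
#' @export
partition_corrected_space <- function(embedding, method = "louvain",
                                      k = 20, resolution = 0.4,
                                      min_cluster_size = 75, seed = 1) {
  method <- match.arg(method, "louvain")
  embedding <- as.matrix(embedding)
  if (ncol(embedding) < 2L)
    stop_cider("cider_input_error", "embedding needs >= 2 dimensions")
  memb <- snn_louvain(embedding, k = k, resolution = resolution,
                      seed = hash_seed(seed, "partition"))
  labels <- paste0("c", memb)
  sizes <- table(labels)
  labels[labels %in% names(sizes)[sizes < min_cluster_size]] <- "unclustered"
  labels
}

# Split corrected-space clusters into batch-specific subclusters with at
# least `min_cells` cells; returns the subcluster list plus a map of
# which corrected-space cluster each subcluster belongs to.
batch_subclusters <- function(meta, cluster_labels, min_cells = 15) {
  subs <- list(); parent <- character(0)
  for (cl in sort(unique(cluster_labels))) {
    if (cl == "unclustered") next
    for (b in sort(unique(meta$batch))) {
      cells <- which(cluster_labels == cl & meta$batch == b)
      if (length(cells) >= min_cells) {
        lab <- paste(cl, b, sep = ".")
        subs[[lab]] <- initial_cluster(lab, b, cells)
        parent[lab] <- cl
      }
    }
  }
  list(subclusters = unname(subs), parent = parent)
}

#' Cross-batch similarity within corrected-space clusters
#'
#' Each corrected-space cluster is split into batch-specific subclusters;
#' the IDER similarity is computed for every cross-batch subcluster pair
#' on the ORIGINAL log-normalized expression (the corrected space only
#' defines the clusters), with batch regressed out. Clusters represented
#' in fewer than two batches are reported as non-evaluable.
#'
#' @param em `ExpressionMatrix` (original expression); `meta` metadata.
#' @param cluster_labels per-cell labels from
#'   [partition_corrected_space()] (or any partition).
#' @param extra_covariates regressed out besides batch.
#' @param min_cells minimum subcluster size (default 15).
#' @param target,seed similarity-stage parameters.
#' @return List with `pairs` (data.frame: cluster, sub_a, sub_b,
#'   similarity), `similarity` (the full cross-batch `SimilarityMatrix`
#'   over subclusters), `subclusters`, `parent`, and `non_evaluable`.
#' @export
within_cluster_similarity <- function(em, meta, cluster_labels,
                                      extra_covariates = NULL,
                                      min_cells = 15, target = 40,
                                      seed = 1) {
  bs <- batch_subclusters(meta, cluster_labels, min_cells = min_cells)
  subs <- bs$subclusters
  if (length(subs) < 2L)
    stop_cider("cider_input_error",
               "fewer than 2 evaluable batch-specific subclusters")
  labels <- vapply(subs, `[[`, character(1), "label")
  evaluable <- names(table(bs$parent))[table(bs$parent) >= 2L]
  non_evaluable <- setdiff(unique(bs$parent), evaluable)
  # full cross-batch matrix: within-cluster pairs are read off it and the
  # mutual-nearest anchor search needs the between-cluster entries too
  sm <- suppressWarnings(
    pairwise_similarity_matrix(em, meta, subs,
                               extra_covariates = extra_covariates,
                               scope = "cross_batch", target = target,
                               seed = seed))
  rows <- list()
  for (cl in evaluable) {
    members <- labels[bs$parent[labels] == cl]
    for (pair in utils::combn(members, 2L, simplify = FALSE)) {
      s <- sm$S[pair[1L], pair[2L]]
      if (!is.na(s))
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, sub_a = pair[1L], sub_b = pair[2L],
          similarity = s, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    stop_cider("cider_input_error", "no evaluable cross-batch pairs")
  list(pairs = pairs, similarity = sm, subclusters = subs,
       parent = bs$parent, non_evaluable = non_evaluable)
}

# Mutually-nearest cross-batch subcluster pair with the highest
# similarity: b is a's best match and a is b's.
mutual_nearest_anchor <- function(sm) {
  S <- sm$S
  diag(S) <- NA
  best <- apply(S, 1L, function(r) if (all(is.na(r))) NA_integer_
                else which.max(r))
  anchors <- list(); vals <- numeric(0)
  for (i in seq_along(best)) {
    j <- best[i]
    if (!is.na(j) && !is.na(best[j]) && best[j] == i && i < j) {
      anchors[[length(anchors) + 1L]] <- c(sm$labels[i], sm$labels[j])
      vals <- c(vals, S[i, j])
    }
  }
  if (!length(anchors))
    stop_cider("cider_input_error", "no mutual-nearest subcluster pair")
  anchors[[which.max(vals)]]
}

#' Background distribution of within-population similarity
#'
#' The anchor pair (assumed to be one biological population seen in two
#' batches) is repeatedly re-partitioned: a random half of its first
#' batch's cells is compared against a random half of its second batch's
#' cells, with batch regressed out, mirroring exactly the statistic
#' computed for every observed cross-batch pair. The samples estimate
#' how similar two batch-specific subclusters look when they truly come
#' from one population. (Mixing batches within each half instead would
#' cancel the confounder-estimation noise every real cross-batch pair
#' carries and push the background above any observable similarity.)
#'
#' @param em,meta expression and metadata.
#' @param subclusters all batch-specific subclusters (background pool).
#' @param anchor_pair character vector of the two anchor subcluster
#'   labels (see [mutual_nearest_anchor()]).
#' @param n_splits number of random splits (default 20).
#' @param extra_covariates,target,min_cells,seed as elsewhere.
#' @return Numeric vector of `n_splits` similarity samples.
#' @export
background_distribution <- function(em, meta, subclusters, anchor_pair,
                                    n_splits = 20, extra_covariates = NULL,
                                    target = 40, min_cells = 15, seed = 1) {
  labels <- vapply(subclusters, `[[`, character(1), "label")
  a <- subclusters[[match(anchor_pair[1L], labels)]]
  b <- subclusters[[match(anchor_pair[2L], labels)]]
  pool <- c(a$cell_indices, b$cell_indices)
  pool_batch <- meta$batch[pool]
  if (length(pool) < 2L * min_cells)
    stop_cider("cider_input_error", "anchor union has ", length(pool),
               " cells (< ", 2L * min_cells, "); use larger clusters")
  others <- subclusters[!labels %in% anchor_pair]
  vapply(seq_len(n_splits), function(s) {
    halves <- with_seed(hash_seed(seed, "split", s), {
      list(a = sample(a$cell_indices, floor(a$size / 2)),
           b = sample(b$cell_indices, floor(b$size / 2)))
    })
    g_a <- initial_cluster("bg.half_a", a$batch, halves$a)
    g_b <- initial_cluster("bg.half_b", b$batch, halves$b)
    des <- suppressWarnings(
      compute_des_pair(em, meta, g_a, g_b, clusters = c(list(g_a, g_b),
                                                        others),
                       extra_covariates = extra_covariates, target = target,
                       seed = hash_seed(seed, "split_pair", s)))
    ider_similarity(des$d_i, des$d_j)
  }, numeric(1))
}

#' Empirical probability of rejecting an alignment
#'
#' Add-one smoothed upper-tail empirical probability
#' `(#\{b > observed\} + 1) / (B + 1)`: high when the observed cross-batch
#' similarity sits below the within-population background, flagging a
#' putatively false alignment.
#'
#' @param observed observed similarity.
#' @param background numeric background samples.
#' @return Probability in `(0, 1]`.
#' @export
empirical_rejection_probability <- function(observed, background) {
  if (length(background) == 0L)
    stop_cider("cider_input_error", "empty background distribution")
  (sum(background > observed) + 1) / (length(background) + 1)
}

#' Evaluate an integration result without ground truth
#'
#' Orchestrates the evaluation workflow: partition the corrected
#' embedding, compute within-cluster cross-batch similarities on the
#' original expression, build the background distribution from the best
#' mutual-nearest pair, and report per-cluster and per-cell similarity
#' and rejection probability (plus cLISI when an annotation is supplied).
#'
#' @param em `ExpressionMatrix` (original expression); `meta` metadata.
#' @param embedding cells x dims corrected embedding.
#' @param cluster_labels optional precomputed per-cell partition;
#'   computed by [partition_corrected_space()] when `NULL`.
#' @param annotation optional per-cell population labels for cLISI.
#' @param extra_covariates,n_splits,min_cells,target,seed as elsewhere.
#' @param ... passed to [partition_corrected_space()].
#' @return An `EvaluationReport`: `clusters` (per-cluster table),
#'   `pairs`, `cells` (per-cell table), `background`, `anchor`.
#' @export
evaluate_integration <- function(em, meta, embedding, cluster_labels = NULL,
                                 annotation = NULL, extra_covariates = NULL,
                                 n_splits = 20, min_cells = 15, target = 40,
                                 seed = 1, ...) {
  cluster_labels <- cluster_labels %||%
    partition_corrected_space(embedding, seed = seed, ...)
  wc <- within_cluster_similarity(em, meta, cluster_labels,
                                  extra_covariates = extra_covariates,
                                  min_cells = min_cells, target = target,
                                  seed = seed)
  anchor <- mutual_nearest_anchor(wc$similarity)
  bg <- background_distribution(em, meta, wc$subclusters, anchor,
                                n_splits = n_splits,
                                extra_covariates = extra_covariates,
                                target = target, min_cells = min_cells,
                                seed = seed)
  pairs <- wc$pairs
  pairs$p_reject <- vapply(pairs$similarity,
                           empirical_rejection_probability,
                           numeric(1), background = bg)
  agg <- stats::aggregate(cbind(similarity, p_reject) ~ cluster,
                          data = pairs, FUN = mean)
  clusters <- data.frame(cluster = agg$cluster,
                         similarity = agg$similarity,
                         p_reject = agg$p_reject,
                         n_pairs = as.integer(table(pairs$cluster)[agg$cluster]),
                         stringsAsFactors = FALSE)

  # per-cell projection: mean over the pairs involving the cell's subcluster
  labels <- vapply(wc$subclusters, `[[`, character(1), "label")
  cell_sim <- rep(NA_real_, nrow(meta))
  cell_p <- rep(NA_real_, nrow(meta))
  for (lab in labels) {
    rows <- pairs$sub_a == lab | pairs$sub_b == lab
    if (!any(rows)) next
    cl <- wc$subclusters[[match(lab, labels)]]
    cell_sim[cl$cell_indices] <- mean(pairs$similarity[rows])
    cell_p[cl$cell_indices] <- mean(pairs$p_reject[rows])
  }
  cells <- data.frame(cell = em$cell_ids, cluster = cluster_labels,
                      similarity = cell_sim, p_reject = cell_p,
                      stringsAsFactors = FALSE)
  if (!is.null(annotation))
    cells$clisi <- clisi(embedding, annotation)
  structure(list(clusters = clusters, pairs = pairs, cells = cells,
                 background = bg, anchor = anchor,
                 non_evaluable = wc$non_evaluable),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport:", nrow(x$clusters), "evaluated clusters;",
      "anchor pair", paste(x$anchor, collapse = " / "), "\n")
  print(x$clusters)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting ARI from the contingency table; 1 for identical
#' partitions, ~0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return A single numeric value.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop_cider("cider_input_error", "label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

#' Population and batch ARI metrics for a clustering result
#'
#' @param assignment clustering labels per cell.
#' @param population,batch ground-truth labels.
#' @return Named list: `ARI_population`, `ARI_batch`,
#'   `one_minus_ARI_batch`.
#' @export
ari_metrics <- function(assignment, population, batch) {
  list(ARI_population = ari(assignment, population),
       ARI_batch = ari(assignment, batch),
       one_minus_ARI_batch = 1 - ari(assignment, batch))
}

#' Cell-type local inverse Simpson index
#'
#' For each cell, neighbor weights follow a Gaussian kernel whose
#' bandwidth is tuned by bisection so the neighborhood entropy matches
#' `log(perplexity)`; the cLISI is the inverse Simpson index of the
#' kernel-weighted label frequencies: 1 in a pure neighborhood, up to the
#' number of labels in a fully mixed one.
#'
#' @param embedding cells x dims numeric matrix.
#' @param labels per-cell population labels.
#' @param perplexity effective neighborhood size (default 30; must be
#'   below the number of cells).
#' @return Numeric cLISI per cell, in `[1, n_labels]`.
#' @export
clisi <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (perplexity >= n)
    stop_cider("cider_input_error", "perplexity must be < number of cells")
  labels <- as.character(labels)
  k <- min(n - 1L, as.integer(3 * perplexity))
  D2 <- as.matrix(dist(embedding))^2
  logU <- log(perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    nb <- order(d)[seq_len(k)]
    di <- d[nb]
    li <- labels[-i][nb]
    if (max(di) <= 0) {          # duplicated points: uniform fallback
      warn_cider("cider_clisi_warning",
                 "duplicate points around cell ", i, "; uniform weights")
      w <- rep(1 / k, k)
    } else {
      m <- min(di)
      entropy_w <- function(beta) {   # shift by min(d) for stability
        q <- exp(-beta * (di - m))
        sp <- sum(q)
        list(H = log(sp) + beta * (sum(di * q) / sp - m), w = q / sp)
      }
      beta <- 1
      lo <- -Inf; hi <- Inf
      for (iter in 1:200) {
        H <- entropy_w(beta)$H
        if (abs(H - logU) < 1e-10) break
        if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
        else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
      }
      w <- entropy_w(beta)$w
    }
    pl <- tapply(w, li, sum)
    out[i] <- 1 / sum(pl^2)
  }
  out
}
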