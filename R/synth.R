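#' Configuration for the gamma-Poisson multi-batch simulator
#'
#' The simulator realizes an additive (in log space) effect model: the
#' expected expression of gene j in cell i is
#' `L_i * lambda_j * 2^delta_{j,pop(i)} * 2^eps_{j,batch(i)} * 2^tau_{j,cov(i)}`
#' with Poisson sampling. Group effects hit a `de_prob` fraction of genes;
#' batch (and covariate) effects hit all genes — the asymmetry the
#' regress-out step exploits.
#'
#' @param n_genes number of genes.
#' @param groups character group names.
#' @param batches character batch names.
#' @param cells matrix batches x groups of cell counts per block (0 drops
#'   a block).
#' @param de_prob per-group probability that a gene carries a group
#'   effect (default 0.2).
#' @param group_lfc_sd sd of the group log2 effects (default 1.5).
#' @param batch_lfc_sd sd of the batch log2 effects, all genes
#'   (default 1).
#' @param covariate optional nested covariate: list with `n_per_batch`
#'   (levels per batch, e.g. donors) and `lfc_sd`.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size factor.
#' @param gene_shape,gene_rate gamma prior on base gene means.
#' @param seed integer seed.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = 1000,
                       groups = paste0("g", 1:2),
                       batches = paste0("b", 1:2),
                       cells = matrix(100, length(batches), length(groups),
                                      dimnames = list(batches, groups)),
                       de_prob = 0.2, group_lfc_sd = 1.5, batch_lfc_sd = 1,
                       covariate = NULL,
                       libsize_meanlog = log(5), libsize_sdlog = 0.3,
                       gene_shape = 2, gene_rate = 2, seed = 1) {
  cfg <- list(n_genes = n_genes, groups = groups, batches = batches,
              cells = cells, de_prob = de_prob,
              group_lfc_sd = group_lfc_sd, batch_lfc_sd = batch_lfc_sd,
              covariate = covariate, libsize_meanlog = libsize_meanlog,
              libsize_sdlog = libsize_sdlog, gene_shape = gene_shape,
              gene_rate = gene_rate, seed = seed)
  if (any(c(cfg$de_prob < 0, cfg$de_prob > 1, cfg$group_lfc_sd < 0,
            cfg$batch_lfc_sd < 0, cfg$n_genes < 1)))
    stop_cider("cider_config_error", "invalid simulator configuration")
  if (!all(dim(cells) == c(length(batches), length(groups))))
    stop_cider("cider_config_error",
               "cells matrix must be batches x groups")
  if (all(cells == 0))
    stop_cider("cider_config_error", "all (batch, group) blocks empty")
  structure(cfg, class = "SimConfig")
}

#' Simulate multi-batch single-cell counts with known structure
#'
#' @param cfg a [sim_config()].
#' @return List: `cm` ([count_matrix()]), `meta` (data.frame with
#'   `batch`, `population`, optional `covariate`), `truth` (`SimTruth`:
#'   per-gene group / batch log2 factors and the per-cell labels).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, {
    G <- cfg$n_genes
    lambda <- rgamma(G, shape = cfg$gene_shape, rate = cfg$gene_rate)
    delta <- sapply(cfg$groups, function(g)
      rbinom(G, 1, cfg$de_prob) * rnorm(G, 0, cfg$group_lfc_sd))
    eps <- sapply(cfg$batches, function(b) rnorm(G, 0, cfg$batch_lfc_sd))
    cov_levels <- NULL; tau <- NULL
    if (!is.null(cfg$covariate)) {
      cov_levels <- unlist(lapply(cfg$batches, function(b)
        paste0(b, "_d", seq_len(cfg$covariate$n_per_batch))))
      tau <- sapply(cov_levels, function(l)
        rnorm(G, 0, cfg$covariate$lfc_sd))
    }

    blocks <- which(cfg$cells > 0, arr.ind = TRUE)
    cell_batch <- character(0); cell_pop <- character(0)
    cell_cov <- character(0)
    counts_list <- vector("list", nrow(blocks))
    for (r in seq_len(nrow(blocks))) {
      b <- cfg$batches[blocks[r, 1L]]
      g <- cfg$groups[blocks[r, 2L]]
      nc <- cfg$cells[blocks[r, 1L], blocks[r, 2L]]
      L <- rlnorm(nc, cfg$libsize_meanlog, cfg$libsize_sdlog)
      mu_gene <- lambda * 2^(delta[, g] + eps[, b])
      covs <- rep(NA_character_, nc)
      if (!is.null(tau)) {
        lv <- cov_levels[startsWith(cov_levels, paste0(b, "_d"))]
        covs <- sample(lv, nc, replace = TRUE)
      }
      block <- matrix(0L, nc, G)
      for (i in seq_len(nc)) {
        mu <- L[i] * mu_gene
        if (!is.null(tau)) mu <- mu * 2^tau[, covs[i]]
        block[i, ] <- rpois(G, mu)
      }
      counts_list[[r]] <- block
      cell_batch <- c(cell_batch, rep(b, nc))
      cell_pop <- c(cell_pop, rep(g, nc))
      cell_cov <- c(cell_cov, covs)
    }
    counts <- do.call(rbind, counts_list)
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
    colnames(counts) <- sprintf("gene%04d", seq_len(G))
    meta <- data.frame(batch = cell_batch, population = cell_pop,
                       stringsAsFactors = FALSE)
    if (!is.null(tau)) meta$donor <- cell_cov
    rownames(meta) <- rownames(counts)
    truth <- structure(list(population = cell_pop, batch = cell_batch,
                            covariate = if (!is.null(tau)) cell_cov,
                            group_lfc = delta, batch_lfc = eps,
                            covariate_lfc = tau, base_mean = lambda),
                       class = "SimTruth")
    list(cm = count_matrix(counts), meta = meta, truth = truth)
  })
}

#' Non-identical-composition scenario: five populations, three batches
#'
#' Five groups across three batches with groups 4 and 5 removed from
#' batch 1, groups 1 and 5 from batch 2, and groups 1 and 3 from batch 3,
#' so every batch holds a different subset \{1,2,3\} / \{2,3,4\} /
#' \{2,4,5\} and only group 2 spans all batches. This is the stress test
#' where naive joint clustering and overcorrecting integration both fail.
#'
#' @param seed integer seed.
#' @param cells_per_block cells per present (batch, group) block
#'   (default 250; 9 blocks, 2250 cells).
#' @param ... overrides passed to [sim_config()].
#' @return As [simulate_counts()].
#' @export
dataset2_scenario <- function(seed = 1, cells_per_block = 250, ...) {
  groups <- paste0("g", 1:5)
  batches <- paste0("b", 1:3)
  cells <- matrix(cells_per_block, 3, 5, dimnames = list(batches, groups))
  cells["b1", c("g4", "g5")] <- 0
  cells["b2", c("g1", "g5")] <- 0
  cells["b3", c("g1", "g3")] <- 0
  cfg <- sim_config(groups = groups, batches = batches, cells = cells,
                    seed = seed, ...)
  simulate_counts(cfg)
}

#' Overcorrection fixture: a deliberately false alignment
#'
#' Simulates four populations in two batches (batch 1 holds p1, p2, p4;
#' batch 2 holds p2, p3, p4) and emits a synthetic "corrected" embedding
#' in which the two distinct populations p1 (batch 1) and p3 (batch 2)
#' are collapsed onto one blob while p2 and p4 stay correctly aligned —
#' the canonical input for the evaluation workflow.
#'
#' @param seed integer seed.
#' @param cells_per_block cells per present block (default 150).
#' @param blob_sd spread of each embedding blob (default 0.4, centers 6
#'   apart).
#' @param ... overrides passed to [sim_config()].
#' @return List: `cm`, `meta`, `embedding` (cells x 2), `truth`,
#'   `collapsed` (the two falsely aligned population names).
#' @export
overcorrection_fixture <- function(seed = 1, cells_per_block = 150,
                                   blob_sd = 0.4, ...) {
  groups <- paste0("p", 1:4)
  batches <- paste0("b", 1:2)
  cells <- matrix(cells_per_block, 2, 4, dimnames = list(batches, groups))
  cells["b1", "p3"] <- 0
  cells["b2", "p1"] <- 0
  cfg <- sim_config(groups = groups, batches = batches, cells = cells,
                    seed = seed, ...)
  sim <- simulate_counts(cfg)
  centers <- rbind(p2 = c(0, 0), p4 = c(6, 0), false = c(0, 6))
  key <- ifelse(sim$meta$population %in% c("p1", "p3"), "false",
                sim$meta$population)
  emb <- with_seed(hash_seed(seed, "embedding"), {
    centers[key, , drop = FALSE] +
      matrix(rnorm(2L * nrow(sim$meta), 0, blob_sd), ncol = 2L)
  })
  rownames(emb) <- sim$cm$cell_ids
  colnames(emb) <- c("dim1", "dim2")
  c(sim, list(embedding = emb, collapsed = c("p1", "p3")))
}

#' True differential expression signature correlation of two populations
#'
#' Correlation of the simulated per-gene group log2 effects — the
#' noise-free analogue of the IDER similarity, used for generator
#' self-checks.
#'
#' @param truth a `SimTruth`.
#' @param g_a,g_b group names.
#' @return A single correlation.
#' @export
true_signature_cor <- function(truth, g_a, g_b) {
  stopifnot(inherits(truth, "SimTruth"))
  cor(truth$group_lfc[, g_a], truth$group_lfc[, g_b])
}
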