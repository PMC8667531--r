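# Shared fixtures and independent oracles for the test suite.

# Dense strictly positive expression fixture with two biological patterns
# ("popA"/"popB") replicated across two batches, 4 initial clusters.
# Strictly positive values keep the detection pattern (and hence the CDR)
# invariant under additive shifts, isolating the regress-out guarantee.
make_positive_fixture <- function(n_per = 40, n_genes = 60, noise = 0.1,
                                  seed = 11) {
  withr::with_seed(seed, {
    patA <- runif(n_genes, 1, 6)
    patB <- runif(n_genes, 1, 6)
    blocks <- list(gA = list("b1", patA), gB = list("b2", patA),
                   gC = list("b1", patB), gD = list("b2", patB))
    vals <- NULL; batch <- character(0); cl <- character(0)
    for (nm in names(blocks)) {
      m <- matrix(rep(blocks[[nm]][[2]], each = n_per), n_per, n_genes)
      m <- m + matrix(abs(rnorm(n_per * n_genes, 0, noise)), n_per)
      vals <- rbind(vals, m)
      batch <- c(batch, rep(blocks[[nm]][[1]], n_per))
      cl <- c(cl, rep(nm, n_per))
    }
    dimnames(vals) <- list(sprintf("c%03d", seq_len(nrow(vals))),
                           sprintf("g%03d", seq_len(n_genes)))
    em <- expression_matrix(vals)
    meta <- data.frame(batch = batch, cluster = cl,
                       row.names = rownames(vals))
    clusters <- lapply(names(blocks), function(nm)
      initial_cluster(nm, blocks[[nm]][[1]], which(cl == nm)))
    list(em = em, meta = meta, clusters = clusters)
  })
}

# Small multi-batch simulation with annotation column attached.
make_sim <- function(seed = 1, cells_per_block = 50, n_genes = 400, ...) {
  sim <- dataset2_scenario(seed = seed, cells_per_block = cells_per_block,
                           n_genes = n_genes, ...)
  sim$meta$annotation <- sim$meta$population
  sim$em <- lognormalize(sim$cm)
  sim
}

# --- independent oracles -------------------------------------------------

# Brute-force all-pairs adjusted Rand index (pair agreement counting,
# a different formula from the implementation's contingency version).
ari_bruteforce <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) return(0)
  2 * (s11 * s00 - s10 * s01) / den
}

# Naive O(k^3) complete-linkage agglomeration; returns merge heights and
# the partition (as a per-item integer label) after each merge.
naive_complete_linkage <- function(D) {
  k <- nrow(D)
  groups <- as.list(seq_len(k))
  heights <- numeric(0)
  partitions <- list()
  while (length(groups) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      d <- max(D[groups[[i]], groups[[j]]])
      if (d < bestd - 1e-15) { bestd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
    lab <- integer(k)
    for (g in seq_along(groups)) lab[groups[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Reference LISI: full (all-neighbor) Gaussian kernel with beta found by
# uniroot on the Shannon entropy, independent of the package code path.
lisi_reference <- function(embedding, labels, perplexity) {
  D2 <- as.matrix(dist(embedding))^2
  n <- nrow(D2)
  logU <- log(perplexity)
  sapply(seq_len(n), function(i) {
    d <- D2[i, -i]
    m <- min(d)
    entropy <- function(beta) {   # numerically stable in beta
      q <- exp(-beta * (d - m)); sp <- sum(q)
      log(sp) + beta * (sum(d * q) / sp - m) - logU
    }
    beta <- uniroot(entropy, c(1e-12, 1e12), tol = 1e-12)$root
    w <- exp(-beta * (d - m)); w <- w / sum(w)
    pl <- tapply(w, labels[-i], sum)
    1 / sum(pl^2)
  })
}

# Two partitions are the same set partition (label-permutation invariant).
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(table(a, b) %in% c(0, table(a))) &&
    ari_contingency_identical(a, b)
}
ari_contingency_identical <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
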