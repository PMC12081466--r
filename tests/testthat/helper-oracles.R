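# Shared oracles and fixture builders, independent of the implementation
# paths they check.

# Pairwise path-length (patristic) distances on a phylo tree by direct
# graph traversal of the edge matrix -- the additivity oracle for NJ.
path_distance_oracle <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n_tip)) {
    dist_to <- rep(NA_real_, n_node)
    dist_to[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1L]
        if (is.na(dist_to[u])) {
          dist_to[u] <- dist_to[v] + adj[[v]][k, 2L]
          queue <- c(queue, u)
        }
      }
    }
    d[s, ] <- dist_to[seq_len(n_tip)]
  }
  d
}

# 2x2-table similarity oracle for a single genotype pair.
pair_similarity_oracle <- function(x, y, method) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  switch(method,
    simple_matching = (a + d) / (a + b + cc + d),
    dice = 2 * a / (2 * a + b + cc),
    jaccard = a / (a + b + cc))
}

# Random valid band matrix (no all-zero locus).
random_band_matrix <- function(n_geno = 6L, n_loci = 40L) {
  repeat {
    p <- matrix(rbinom(n_geno * n_loci, 1L, runif(1, 0.3, 0.7)), n_geno, n_loci)
    if (all(colSums(p) > 0L)) break
  }
  rownames(p) <- paste0("g", seq_len(n_geno))
  band_matrix(p, primer = rep(c("P1", "P2"), length.out = n_loci))
}

# Random distance matrix on n labelled points (Euclidean, hence valid).
random_distance <- function(n = 6L, dim = 4L) {
  pts <- matrix(rnorm(n * dim), n)
  rownames(pts) <- paste0("g", seq_len(n))
  as.matrix(dist(pts))
}
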