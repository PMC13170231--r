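# Independent oracles used across the suite. Each is deliberately naive
# (brute force / enumeration) and shares no code with the implementation.

# Step-up FDR by direct application of the definition.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  adj <- m * sorted / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[o] <- pmin(adj, 1)
  q
}

# Connected components of TRUE voxels by flood fill (6-connectivity).
bruteLabel6 <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dm)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- co; nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1L || nb[ax] > dm[ax]) next
        lin <- nb[1] + dm[1] * (nb[2] - 1L) + dm[1] * dm[2] * (nb[3] - 1L)
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Highest-k core of an undirected graph given as a 0/1 adjacency matrix,
# by iterative pruning at increasing k. Returns list(k, members).
bruteMaxCore <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(list(k = 0L, members = integer(0)))
  best <- list(k = 0L, members = seq_len(n))
  for (k in seq_len(n)) {
    keep <- rep(TRUE, n)
    repeat {
      deg <- colSums(adj[keep, keep, drop = FALSE])
      low <- deg < k
      if (!any(low) || !any(keep)) break
      keep[which(keep)[low]] <- FALSE
    }
    if (!any(keep)) break
    best <- list(k = k, members = which(keep))
  }
  best
}

# MCODE vertex weight of node v from the definition, adjacency-matrix form.
bruteVertexWeight <- function(adj, v) {
  nb <- which(adj[v, ] > 0)
  if (length(nb) < 2L) return(0)
  sub <- adj[nb, nb, drop = FALSE]
  if (sum(sub) == 0) return(0)
  core <- bruteMaxCore(sub)
  m <- core$members
  nn <- length(m)
  dens <- sum(sub[m, m]) / (nn * (nn - 1))
  core$k * dens
}

# Differential stability by exhaustive pairwise correlation over donors.
bruteDS <- function(profiles) {
  # profiles: list (per donor) of probe x region matrices (colnames = regions)
  nd <- length(profiles)
  nP <- nrow(profiles[[1]])
  pairs <- combn(nd, 2)
  vals <- matrix(NA_real_, nP, ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- profiles[[pairs[1, j]]]; b <- profiles[[pairs[2, j]]]
    shared <- intersect(colnames(a), colnames(b))
    if (length(shared) < 3L) next
    for (i in seq_len(nP)) {
      x <- a[i, shared]; y <- b[i, shared]
      if (sd(x) > 0 && sd(y) > 0) vals[i, j] <- cor(x, y)
    }
  }
  rowMeans(vals, na.rm = TRUE)
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets.
bruteHyperTail <- function(N, K, n, k) {
  items <- seq_len(N)
  marked <- items <= K
  hits <- 0L; tot <- 0L
  cmb <- combn(N, n)
  for (j in seq_len(ncol(cmb))) {
    tot <- tot + 1L
    if (sum(marked[cmb[, j]]) >= k) hits <- hits + 1L
  }
  hits / tot
}

# ssGSEA ES for a singleton set at alpha = 0, walked by hand.
bruteSingletonES <- function(vals, genes, gene) {
  N <- length(vals)
  ord <- order(vals, genes, decreasing = TRUE, method = "radix")
  pos <- which(genes[ord] == gene)
  es <- 0
  outSeen <- 0
  for (i in seq_len(N)) {
    pin <- as.numeric(i >= pos)
    if (genes[ord][i] != gene) outSeen <- outSeen + 1
    es <- es + pin - outSeen / (N - 1)
  }
  es
}

# Small helper: map list of VoxelMaps to matrix of in-mask values.
maskValues <- function(maps) vapply(maps, inMask, numeric(sum(mapMask(maps[[1]]))))
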