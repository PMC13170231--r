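# Cluster-level inference on voxel-wise statistic maps: Gaussian random field
# correction (the default) and a permutation backend used as its oracle.

# Convert a StatMap (r or t) or a z VoxelMap to a standard-normal-equivalent
# z array (signed), via the statistic's CDF. Returns list(z, mask, voxelSize).
.toZField <- function(stat) {
  if (is(stat, "VoxelMap")) {
    stopifnot(mapKind(stat) == "z")
    return(list(z = stat@data, mask = stat@mask, voxelSize = stat@voxelSize))
  }
  stopifnot(is(stat, "StatMap"))
  s <- stat@stat@data
  mask <- stat@stat@mask
  df <- stat@df
  tval <- if (stat@statKind == "r") {
    s * sqrt(df / pmax(1 - s^2, .Machine$double.eps))
  } else s
  # z with matched tail probability; log scale keeps extreme tails finite
  lz <- stats::pt(abs(tval), df = df, lower.tail = FALSE, log.p = TRUE)
  z <- sign(tval) * stats::qnorm(lz, lower.tail = FALSE, log.p = TRUE)
  z[!mask] <- NA_real_
  list(z = z, mask = mask, voxelSize = stat@stat@voxelSize)
}

# GRF corrected cluster-level p for a cluster of k voxels at threshold u,
# given FWHM in voxels and V in-mask voxels (Friston-style expected Euler
# characteristic / cluster-extent approximation, D = 3).
.grfClusterP <- function(k, u, fwhmVox, V) {
  resels <- V / prod(fwhmVox)
  Em <- resels * (4 * log(2))^(3 / 2) * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
  Em <- max(Em, .Machine$double.xmin)
  EN <- V * stats::pnorm(u, lower.tail = FALSE)
  nbar <- EN / Em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)
  Pk <- exp(-beta * k^(2 / 3))
  p <- 1 - exp(-Em * Pk)
  min(max(p, .Machine$double.xmin), 1)
}

# Form supra-threshold clusters of one sign and summarize them.
.formClusters <- function(z, mask, voxelSize, u, sgn, connectivity) {
  supra <- mask & is.finite(z) & (sgn * z >= u)
  lab <- labelClusters(supra, connectivity)
  nclust <- max(lab)
  if (nclust == 0L) return(list(lab = lab, table = NULL))
  dm <- dim(z)
  rows <- lapply(seq_len(nclust), function(cl) {
    idx <- which(lab == cl)
    zi <- z[idx]
    pk <- idx[which.max(abs(zi))]
    mm <- voxelToMM(arrayInd(pk, dm), dm, voxelSize)
    data.frame(size = length(idx), peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
               peak_stat = z[pk] , sign = if (sgn > 0) "positive" else "negative",
               stringsAsFactors = FALSE)
  })
  list(lab = lab, table = do.call(rbind, rows))
}

#' Gaussian-random-field cluster-level correction
#'
#' Thresholds the statistic field at the voxel-level p (after conversion to a
#' standard-normal-equivalent z field through the statistic's CDF), forms
#' clusters by face adjacency (6-connectivity by default), and assigns each
#' cluster a corrected cluster-level p from random-field theory: the expected
#' number of clusters above the threshold times the tail probability of the
#' observed extent given the resel volume. Two-tailed testing is performed as
#' two one-sided analyses, one per sign, each at the stated voxel p.
#' The peak statistic reported is the z-equivalent value at the cluster peak.
#'
#' @param stat a [StatMap-class], or a [VoxelMap-class] of kind `"z"`.
#' @param fwhm smoothness FWHM in mm (3 axes), from [estimateSmoothness()]
#'   or known by construction.
#' @param voxelP cluster-defining voxel-level p (one per tail).
#' @param clusterP cluster-level corrected p threshold.
#' @param connectivity 6 (default), 18 or 26.
#' @param tails `"two"` (default), `"positive"` or `"negative"`.
#' @return a [ClusterResult-class]; only surviving clusters are labelled.
#' @export
grfClusterThreshold <- function(stat, fwhm, voxelP = 0.005, clusterP = 0.05,
                                connectivity = 6L,
                                tails = c("two", "positive", "negative")) {
  tails <- match.arg(tails)
  if (missing(fwhm) || is.null(fwhm))
    stop("fwhm missing: estimate smoothness first (estimateSmoothness)")
  stopifnot(length(fwhm) == 3L, all(is.finite(fwhm)), all(fwhm > 0))
  zf <- .toZField(stat)
  fwhmVox <- pmax(fwhm / zf$voxelSize, 1)
  V <- sum(zf$mask & is.finite(zf$z))
  u <- stats::qnorm(1 - voxelP)
  sgns <- switch(tails, two = c(1, -1), positive = 1, negative = -1)
  lab <- array(0L, dim(zf$z))
  tab <- NULL
  for (sgn in sgns) {
    fc <- .formClusters(zf$z, zf$mask, zf$voxelSize, u, sgn, connectivity)
    if (is.null(fc$table)) next
    fc$table$p <- vapply(fc$table$size, .grfClusterP, numeric(1),
                         u = u, fwhmVox = fwhmVox, V = V)
    keep <- which(fc$table$p <= clusterP)
    for (cl in keep) {
      lab[fc$lab == cl] <- max(lab) + 1L
    }
    if (length(keep)) tab <- rbind(tab, fc$table[keep, , drop = FALSE])
  }
  if (is.null(tab)) {
    tab <- data.frame(cluster = integer(0), size = integer(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0), peak_stat = numeric(0),
                      p = numeric(0), sign = character(0))
  } else {
    tab <- cbind(cluster = seq_len(nrow(tab)), tab)
    ord <- order(-tab$size)
    tab <- tab[ord, c("cluster", "size", "peak_x", "peak_y", "peak_z",
                      "peak_stat", "p", "sign")]
    rownames(tab) <- NULL
    # relabel array so labels follow the (size-ordered) table
    relab <- array(0L, dim(lab))
    for (i in seq_len(nrow(tab))) relab[lab == tab$cluster[i]] <- i
    tab$cluster <- seq_len(nrow(tab))
    lab <- relab
  }
  labmap <- VoxelMap(array(as.numeric(lab), dim(lab)), mask = zf$mask,
                     voxelSize = zf$voxelSize, kind = "z")
  new("ClusterResult", labels = labmap, table = tab, voxelP = voxelP,
      clusterP = clusterP, fwhm = as.numeric(fwhm))
}

#' Permutation-based cluster-level correction
#'
#' Same cluster formation as [grfClusterThreshold()], but the cluster-level p
#' is the permutation tail probability of the maximum supra-threshold cluster
#' extent (both tails pooled) under random relabelling of the design. Serves
#' as the assumption-free oracle for the random-field backend.
#'
#' @inheritParams voxelwiseStatMap
#' @inheritParams grfClusterThreshold
#' @param nPerm number of permutations.
#' @param seed integer seed for the permutation draw.
#' @return a [ClusterResult-class].
#' @export
permClusterThreshold <- function(maps, design, voxelP = 0.005, clusterP = 0.05,
                                 nPerm = 1000L, seed = 1L, connectivity = 6L,
                                 tails = c("two", "positive", "negative")) {
  tails <- match.arg(tails)
  obs <- voxelwiseStatMap(maps, design)
  zf <- .toZField(obs)
  u <- stats::qnorm(1 - voxelP)
  sgns <- switch(tails, two = c(1, -1), positive = 1, negative = -1)
  maxSize <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      d <- sample(design)
      zp <- .toZField(voxelwiseStatMap(maps, d))
      mx <- 0L
      for (sgn in sgns) {
        supra <- zp$mask & is.finite(zp$z) & (sgn * zp$z >= u)
        if (any(supra)) {
          l <- labelClusters(supra, connectivity)
          mx <- max(mx, max(tabulate(l[l > 0L])))
        }
      }
      mx
    }, integer(1))
  })
  lab <- array(0L, dim(zf$z))
  tab <- NULL
  for (sgn in sgns) {
    fc <- .formClusters(zf$z, zf$mask, zf$voxelSize, u, sgn, connectivity)
    if (is.null(fc$table)) next
    fc$table$p <- vapply(fc$table$size,
                         function(k) (1 + sum(maxSize >= k)) / (nPerm + 1),
                         numeric(1))
    keep <- which(fc$table$p <= clusterP)
    for (cl in keep) lab[fc$lab == cl] <- max(lab) + 1L
    if (length(keep)) tab <- rbind(tab, fc$table[keep, , drop = FALSE])
  }
  if (is.null(tab)) {
    tab <- data.frame(cluster = integer(0), size = integer(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0), peak_stat = numeric(0),
                      p = numeric(0), sign = character(0))
  } else {
    tab <- cbind(cluster = seq_len(nrow(tab)), tab)
    tab <- tab[order(-tab$size), c("cluster", "size", "peak_x", "peak_y", "peak_z",
                                   "peak_stat", "p", "sign")]
    rownames(tab) <- NULL
    relab <- array(0L, dim(lab))
    for (i in seq_len(nrow(tab))) relab[lab == tab$cluster[i]] <- i
    tab$cluster <- seq_len(nrow(tab))
    lab <- relab
  }
  labmap <- VoxelMap(array(as.numeric(lab), dim(lab)), mask = zf$mask,
                     voxelSize = zf$voxelSize, kind = "z")
  new("ClusterResult", labels = labmap, table = tab, voxelP = voxelP,
      clusterP = clusterP, fwhm = rep(NA_real_, 3))
}

#' Map surviving clusters onto atlas parcels (ROI rule)
#'
#' Counts, for each atlas parcel, how many voxels belong to any retained
#' cluster, and keeps parcels with at least `minVoxels` overlapping voxels
#' (the spatial-extent criterion used to call a parcel a region of interest).
#'
#' @param clusters a [ClusterResult-class].
#' @param parcellation a [Parcellation-class] on the same grid.
#' @param minVoxels minimum overlap (default 6 voxels).
#' @return data.frame `id`, `name`, `n_voxels`, sorted by descending overlap.
#' @export
clustersToROIs <- function(clusters, parcellation, minVoxels = 6L) {
  lab <- clusters@labels@data
  .assertSameGrid(lab, parcellation@labels, "clusters and parcellation")
  sig <- is.finite(lab) & lab > 0
  reg <- parcellation@labels
  cnt <- tapply(rep(1L, sum(sig & reg != 0L)), reg[sig & reg != 0L], sum)
  tab <- parcellation@regions
  out <- data.frame(id = tab$id, name = tab$name,
                    n_voxels = as.integer(ifelse(is.na(match(as.character(tab$id), names(cnt))),
                                                 0L, cnt[as.character(tab$id)])),
                    stringsAsFactors = FALSE)
  out <- out[out$n_voxels >= minVoxels, , drop = FALSE]
  out <- out[order(-out$n_voxels, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
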