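# Internal helpers shared across modules.

#' @importFrom withr with_seed
.withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Voxel centers in mm: index i on an axis of length d with voxel size v maps to
# (i - (d + 1)/2) * v, so the grid is centred on the origin and the x = 0 plane
# separates hemispheres (negative x = left, the MNI convention).
voxelCentersMM <- function(dim, voxelSize) {
  lapply(seq_along(dim), function(a) (seq_len(dim[a]) - (dim[a] + 1) / 2) * voxelSize[a])
}

mmToVoxel <- function(mm, dim, voxelSize) {
  # mm: matrix n x 3 -> integer voxel indices (may fall outside the grid)
  idx <- sweep(sweep(mm, 2L, voxelSize, "/"), 2L, (dim + 1) / 2, "+")
  round(idx)
}

voxelToMM <- function(idx, dim, voxelSize) {
  sweep(sweep(idx, 2L, (dim + 1) / 2, "-"), 2L, voxelSize, "*")
}

# Neighbour offsets for 6/18/26-connectivity in 3D.
.connOffsets <- function(connectivity = 6L) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  d <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6"  = d == 1L,
    "18" = d <= 2L,
    "26" = rep(TRUE, nrow(off)),
    stop("connectivity must be 6, 18 or 26")
  )
  off[keep, , drop = FALSE]
}

#' Label connected components of a logical 3D array
#'
#' Face- (6-), edge- (18-) or corner- (26-) connected components among TRUE
#' voxels. Labels are assigned in order of each component's smallest linear
#' index, so labelling is deterministic.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (default), 18 or 26.
#' @return integer array of the same shape; 0 outside components.
#' @keywords internal
labelClusters <- function(mask, connectivity = 6L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  co <- arrayInd(idx, dm)
  pos <- integer(prod(dm))
  pos[idx] <- seq_along(idx)
  off <- .connOffsets(connectivity)
  # half-space offsets suffice for undirected edges
  off <- off[off[, 1] + 10 * off[, 2] + 100 * off[, 3] > 0, , drop = FALSE]
  ea <- integer(0); eb <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- co + matrix(off[r, ], nrow(co), 3L, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] & nb[, 2] >= 1L & nb[, 2] <= dm[2] &
      nb[, 3] >= 1L & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1L) + dm[1] * dm[2] * (nb[ok, 3] - 1L)
    hit <- pos[lin] > 0L
    if (!any(hit)) next
    ea <- c(ea, which(ok)[hit])
    eb <- c(eb, pos[lin][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ea)) g <- igraph::add_edges(g, rbind(ea, eb))
  comp <- igraph::components(g)$membership
  # relabel by first (smallest linear index) appearance
  first <- tapply(seq_along(idx), comp, min)
  newlab <- integer(max(comp))
  newlab[order(first)] <- seq_along(first)
  lab[idx] <- newlab[comp]
  lab
}

.assertSameGrid <- function(a, b, what = "objects") {
  if (!identical(dim(a), dim(b)))
    stop(what, " are on different grids: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
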