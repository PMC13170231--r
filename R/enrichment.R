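# Gene-set scoring per region/sample (ssGSEA), over-representation tests,
# immune-signature scoring, and the group/correlation statistics applied to
# those scores.

.ssgseaOne <- function(vals, genes, set, alpha) {
  N <- length(vals)
  ord <- order(vals, genes, decreasing = TRUE, method = "radix")
  g <- genes[ord]
  w <- (N - seq_len(N) + 1)^alpha
  ind <- g %in% set
  nIn <- sum(ind)
  if (nIn == 0L || nIn == N) return(NA_real_)
  Pin <- cumsum(w * ind) / sum(w * ind)
  Pout <- cumsum(!ind) / (N - nIn)
  sum(Pin - Pout)
}

# Simplified distribution-based backend: genes are first transformed to
# z-scores of their cross-unit Gaussian-kernel cumulative density (an
# expression-level rather than pure-rank statistic), then scored with the
# same integrated running sum.
.gsvaTransform <- function(expr) {
  n <- nrow(expr)
  h <- apply(expr, 2L, stats::sd) / 4
  h[h == 0 | !is.finite(h)] <- 1e-8
  out <- expr
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    cdf <- vapply(x, function(xi) mean(stats::pnorm((xi - x) / h[j])), numeric(1))
    cdf <- pmin(pmax(cdf, 1e-8), 1 - 1e-8)
    out[, j] <- stats::qnorm(cdf)
  }
  out
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each unit (region or sample), genes are ranked by expression in
#' descending order and the enrichment score of a set is the integrated
#' running-sum difference \eqn{ES = \sum_i [P_{in}(i) - P_{out}(i)]}, where
#' \eqn{P_{in}} accumulates the rank weights \eqn{(N - i + 1)^\alpha} of
#' in-set genes and \eqn{P_{out}} accumulates uniform mass over out-set
#' genes. The score is rank-invariant: any strictly increasing transform of a
#' unit's expression leaves it unchanged. `method = "gsva"` first maps each
#' gene through a cross-unit Gaussian-kernel CDF (a distribution-based
#' variant) before the same running sum.
#'
#' Sets with no gene in the matrix, or covering every gene (no out-set mass),
#' score `NA` with a warning.
#'
#' @param expr numeric matrix, units x genes (column names = gene ids).
#' @param sets named list of character vectors of gene ids.
#' @param alpha rank-weight exponent (default 0.25; 0 = unweighted).
#' @param normalize divide all scores by (max - min) over the whole matrix.
#' @param method `"ssgsea"` (default) or `"gsva"`.
#' @return numeric matrix, units x sets.
#' @export
ssgseaScore <- function(expr, sets, alpha = 0.25, normalize = FALSE,
                        method = c("ssgsea", "gsva")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), ncol(expr) >= 2L, !is.null(colnames(expr)),
            is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  genes <- colnames(expr)
  if (method == "gsva") expr <- .gsvaTransform(expr)
  sets2 <- lapply(sets, intersect, x = genes)
  es <- matrix(NA_real_, nrow(expr), length(sets),
               dimnames = list(rownames(expr), names(sets)))
  for (s in seq_along(sets)) {
    ns <- length(sets2[[s]])
    if (ns == 0L || ns == length(genes)) {
      warning("set '", names(sets)[s], "' has ",
              if (ns == 0L) "no gene in" else "all genes of",
              " the matrix; score is NA")
      next
    }
    for (u in seq_len(nrow(expr)))
      es[u, s] <- .ssgseaOne(expr[u, ], genes, sets2[[s]], alpha)
  }
  if (normalize) {
    rng <- range(es, na.rm = TRUE)
    if (diff(rng) > 0) es <- es / diff(rng)
  }
  es
}

#' Hypergeometric over-representation test
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} of drawing at least the
#' observed overlap `k` between a gene list (size n) and a marker set
#' (size K) from a universe of N genes.
#'
#' @param listGenes character vector (the query list).
#' @param markerSet character vector (the annotated set).
#' @param universe character vector; both inputs are intersected with it.
#' @return data.frame `k`, `n`, `K`, `N`, `p`.
#' @export
hypergeomOverlap <- function(listGenes, markerSet, universe) {
  if (length(universe) == 0L) stop("empty universe")
  lg <- intersect(unique(listGenes), universe)
  ms <- intersect(unique(markerSet), universe)
  k <- length(intersect(lg, ms))
  N <- length(unique(universe)); n <- length(lg); K <- length(ms)
  p <- if (k == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(k = k, n = n, K = K, N = N, p = min(max(p, .Machine$double.xmin), 1))
}

#' Test a gene list against a collection of marker sets
#'
#' Runs [hypergeomOverlap()] per set and adds BH q-values across sets.
#'
#' @inheritParams hypergeomOverlap
#' @param markerSets named list of character vectors.
#' @return data.frame, one row per set, with `set`, `k`, `n`, `K`, `N`,
#'   `p`, `q`.
#' @export
overlapTest <- function(listGenes, markerSets, universe) {
  rows <- lapply(names(markerSets), function(s)
    cbind(set = s, hypergeomOverlap(listGenes, markerSets[[s]], universe)))
  out <- do.call(rbind, rows)
  out$q <- bhFDR(out$p)
  out
}

#' Immune-signature infiltration scores from RNA-seq counts
#'
#' Converts counts to log2 counts-per-million and scores each sample against
#' each immune cell-type signature with [ssgseaScore()]. Signature genes
#' absent from the count matrix are dropped (the set is scored on the
#' intersection); per-set coverage fractions are attached as the
#' `"coverage"` attribute.
#'
#' @param counts gene x sample integer matrix.
#' @param signatures named list of gene-id vectors (e.g. 24 immune cell
#'   types).
#' @param alpha rank-weight exponent for ssGSEA.
#' @return samples x cell-types score matrix.
#' @export
immuneScores <- function(counts, signatures, alpha = 0.25) {
  lc <- logCPM(counts)
  cov <- vapply(signatures, function(s) mean(s %in% rownames(lc)), numeric(1))
  sc <- ssgseaScore(t(lc), signatures, alpha = alpha)
  attr(sc, "coverage") <- cov
  sc
}

#' Compare per-set scores between two groups
#'
#' For each set, both groups pass a D'Agostino-Pearson normality gate at
#' 0.05: if both look normal an equal-variance two-sample t-test is used,
#' otherwise a Mann-Whitney U test. Sets constant in both groups get p = 1.
#' BH q-values are computed across sets.
#'
#' @param scores units x sets numeric matrix.
#' @param labels group labels (2 levels), one per row of `scores`.
#' @return data.frame `set`, `test`, `statistic`, `delta` (mean of first
#'   level minus second), `p`, `q`.
#' @export
scoreGroupCompare <- function(scores, labels) {
  g <- as.factor(labels)
  stopifnot(nlevels(g) == 2L, nrow(scores) == length(g))
  i1 <- g == levels(g)[1L]
  stopifnot(sum(i1) >= 3L, sum(!i1) >= 3L)
  rows <- lapply(colnames(scores), function(s) {
    x <- scores[i1, s]; y <- scores[!i1, s]
    if (anyNA(x) || anyNA(y))
      return(data.frame(set = s, test = NA_character_, statistic = NA_real_,
                        delta = NA_real_, p = NA_real_))
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(data.frame(set = s, test = "degenerate", statistic = NA_real_,
                        delta = mean(x) - mean(y), p = 1))
    normal <- dagostinoPearson(x)$p.value > 0.05 && dagostinoPearson(y)$p.value > 0.05
    if (normal) {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      data.frame(set = s, test = "t", statistic = unname(tt$statistic),
                 delta = mean(x) - mean(y), p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      data.frame(set = s, test = "wilcoxon", statistic = unname(wt$statistic),
                 delta = mean(x) - mean(y), p = wt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bhFDR(out$p[ok])
  out
}

#' Spearman correlation between a per-subject scalar and per-subject scores
#'
#' E.g. cluster-mean ALFF per subject against immune cell-type scores.
#' All-tied inputs give `NA` (undefined).
#'
#' @param subjectValues numeric vector, one value per subject.
#' @param scores subjects x sets numeric matrix.
#' @return data.frame `set`, `rho`, `p`.
#' @export
scoreMapCorrelation <- function(subjectValues, scores) {
  stopifnot(length(subjectValues) == nrow(scores), length(subjectValues) >= 5L)
  rows <- lapply(colnames(scores), function(s) {
    y <- scores[, s]
    if (length(unique(y)) < 2L || length(unique(subjectValues)) < 2L)
      return(data.frame(set = s, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(subjectValues, y, method = "spearman",
                                           exact = FALSE))
    data.frame(set = s, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Voxel-wise correlation of subject maps with a per-subject score
#'
#' Correlates the subject ALFF maps voxel-wise with a per-subject score (an
#' immune cell type or pathway score), applies GRF cluster correction, and
#' maps surviving clusters onto atlas parcels with the minimum-overlap ROI
#' rule.
#'
#' @param maps list of subject [VoxelMap-class]s.
#' @param score numeric per-subject score.
#' @param parcellation a [Parcellation-class].
#' @param voxelP,clusterP,minVoxels thresholds (defaults 0.005, 0.05, 6).
#' @return list: `stat` ([StatMap-class]), `clusters`
#'   ([ClusterResult-class]), `rois` (data.frame).
#' @export
scoreVoxelCorrelation <- function(maps, score, parcellation, voxelP = 0.005,
                                  clusterP = 0.05, minVoxels = 6L) {
  sm <- voxelwiseStatMap(maps, score)
  fwhm <- estimateSmoothness(voxelResiduals(maps, score))
  cl <- grfClusterThreshold(sm, fwhm, voxelP = voxelP, clusterP = clusterP)
  list(stat = sm, clusters = cl,
       rois = clustersToROIs(cl, parcellation, minVoxels = minVoxels))
}
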