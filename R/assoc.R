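# Gene-wise spatial correlation between a regional ALFF profile and regional
# expression, with BH FDR control and the |r| / q selection rule.

#' Correlate a regional ALFF profile with every gene's expression
#'
#' Pearson correlation between the ALFF regional vector and each gene column
#' of the regional expression matrix, over the regions present in both (the
#' intersection; its size is recorded per gene). Two-tailed p on n-2 df.
#' Genes with zero variance over the shared regions are skipped with a
#' warning.
#'
#' @param alffByRegion named numeric vector (names = region ids).
#' @param expr a [RegionalExpression-class] or a region x gene matrix with
#'   region-id rownames.
#' @return data.frame `gene`, `r`, `p`, `q` (BH), `direction`, `n_regions`.
#' @export
correlateGeneMaps <- function(alffByRegion, expr) {
  if (is(expr, "RegionalExpression")) expr <- exprMatrix(expr)
  alffByRegion <- alffByRegion[!is.na(alffByRegion)]
  shared <- intersect(names(alffByRegion), rownames(expr))
  if (length(shared) < 4L)
    stop("need >= 4 overlapping regions; got ", length(shared))
  a <- alffByRegion[shared]
  E <- expr[shared, , drop = FALSE]
  res <- lapply(colnames(E), function(g) {
    x <- E[, g]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 4L || stats::sd(x[ok]) == 0 || stats::sd(a[ok]) == 0)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_, n_regions = n))
    r <- stats::cor(a[ok], x[ok])
    df <- n - 2
    tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    data.frame(gene = g, r = r, p = max(2 * stats::pt(-abs(tt), df),
                                        .Machine$double.xmin), n_regions = n)
  })
  out <- do.call(rbind, res)
  nBad <- sum(is.na(out$r))
  if (nBad) warning(nBad, " gene(s) skipped (zero variance over shared regions)")
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bhFDR(out$p[ok])
  out$direction <- ifelse(out$r >= 0, "positive", "negative")
  out[, c("gene", "r", "p", "q", "direction", "n_regions")]
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values: \eqn{q_i = \min_{j \ge rank(i)} m p_{(j)} / j},
#' capped at 1. Thin wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bhFDR <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Select genes significantly correlated with the ALFF profile
#'
#' Keeps genes with `q < qMax` AND `|r| > rMinAbs` (both bounds strict) and
#' splits them by correlation sign.
#'
#' @param assoc result of [correlateGeneMaps()].
#' @param qMax FDR threshold (default 0.05).
#' @param rMinAbs absolute-correlation threshold (default 0.8).
#' @return list with character vectors `positive` and `negative`.
#' @export
selectCorrelatedGenes <- function(assoc, qMax = 0.05, rMinAbs = 0.8) {
  stopifnot(qMax > 0, qMax <= 1, rMinAbs >= 0, rMinAbs < 1)
  sel <- !is.na(assoc$q) & assoc$q < qMax & abs(assoc$r) > rMinAbs
  list(positive = assoc$gene[sel & assoc$r > 0],
       negative = assoc$gene[sel & assoc$r < 0])
}
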