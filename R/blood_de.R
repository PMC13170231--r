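# RNA-seq normalization and empirical-Bayes moderated-t differential
# expression (two-group design), with the raw-p / |logFC| selection rule.

#' Log2 counts-per-million
#'
#' \deqn{\log_2\left(\frac{c_{gs} + prior}{L_s + 2 \cdot prior} \cdot 10^6\right)}
#' with \eqn{L_s} the column library size. The prior count keeps zeros finite.
#'
#' @param counts gene x sample non-negative matrix.
#' @param priorCount prior count (default 0.5).
#' @return gene x sample real matrix.
#' @export
logCPM <- function(counts, priorCount = 0.5) {
  stopifnot(all(counts >= 0), all(colSums(counts) > 0))
  L <- colSums(counts)
  log2(sweep(counts + priorCount, 2L, L + 2 * priorCount, "/") * 1e6)
}

# Newton inversion of the trigamma function (psigamma deriv = 1).
.trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi)) return(NA_real_)
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- psigamma(x, 1L)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

# Fit the prior df d0 and prior variance s0^2 by matching the theoretical
# moments of log s^2 across genes (scaled chi-square model for s^2).
.fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - psigamma(df / 2, 1L)
  if (evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # log-variance spread within sampling noise: fully pooled variance
    d0 <- Inf
    s02 <- mean(s2[ok])
    message("variance prior fit divergent; using pooled variance (d0 = Inf)")
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated-t differential expression on log-expression values
#'
#' Per gene, the two-group contrast (first level minus second) is estimated by
#' ordinary least squares with residual variance \eqn{s^2} on \eqn{n - 2} df.
#' The gene-wise variances are shrunk toward an empirical-Bayes prior fitted
#' by matching the moments of \eqn{\log s^2} (digamma/trigamma relations),
#' giving prior df \eqn{d_0} and prior variance \eqn{s_0^2}; the posterior
#' variance is \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)} and the
#' moderated t is the contrast over \eqn{\tilde s \sqrt{1/n_1 + 1/n_2}} on
#' \eqn{d_0 + d} df. When the log-variance spread is no larger than sampling
#' noise the fit diverges to \eqn{d_0 = \infty} (fully pooled variance); with
#' `moderate = FALSE` the ordinary per-gene t is returned instead.
#'
#' @param logexpr gene x sample matrix (e.g. from [logCPM()]).
#' @param groups two-level labels; the *first* level is the case group.
#' @param moderate apply variance shrinkage (default TRUE).
#' @return data.frame `gene`, `logFC`, `t`, `p`, `q`, `meanExpr`, plus
#'   attributes `d0` and `s02`.
#' @export
moderatedTDE <- function(logexpr, groups, moderate = TRUE) {
  g <- as.factor(groups)
  stopifnot(nlevels(g) == 2L, ncol(logexpr) == length(g))
  i1 <- g == levels(g)[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  stopifnot(n1 >= 2L, n2 >= 2L)
  m1 <- rowMeans(logexpr[, i1, drop = FALSE])
  m2 <- rowMeans(logexpr[, !i1, drop = FALSE])
  ss <- rowSums((logexpr[, i1, drop = FALSE] - m1)^2) +
    rowSums((logexpr[, !i1, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- ss / df
  beta <- m1 - m2
  sf <- sqrt(1 / n1 + 1 / n2)
  if (moderate) {
    pri <- .fitVariancePrior(s2, df)
    d0 <- pri$d0; s02 <- pri$s02
    st2 <- if (is.infinite(d0)) rep(s02, length(s2)) else
      (d0 * s02 + df * s2) / (d0 + df)
    dft <- if (is.infinite(d0)) Inf else d0 + df
  } else {
    d0 <- 0; s02 <- NA_real_
    st2 <- s2
    dft <- df
  }
  tt <- beta / (sqrt(st2) * sf)
  p <- 2 * stats::pt(-abs(tt), dft)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  out <- data.frame(gene = rownames(logexpr), logFC = beta, t = tt, p = p,
                    q = bhFDR(p), meanExpr = rowMeans(logexpr),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df.total") <- dft
  out
}

#' Select differentially expressed genes
#'
#' Raw-p rule: genes with `p < pMax` AND `|logFC| > lfcMin` (both strict),
#' split by sign. q-values remain available in the DE table for
#' transparency; selection deliberately uses the unadjusted p.
#'
#' @param de result of [moderatedTDE()].
#' @param pMax p threshold (default 0.05).
#' @param lfcMin absolute log2-fold-change threshold (default 1).
#' @return list with character vectors `up` and `down`.
#' @export
selectDEGenes <- function(de, pMax = 0.05, lfcMin = 1) {
  stopifnot(pMax > 0, lfcMin >= 0)
  sel <- !is.na(de$p) & de$p < pMax & abs(de$logFC) > lfcMin
  list(up = de$gene[sel & de$logFC > 0], down = de$gene[sel & de$logFC < 0])
}
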