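#' Compute the amplitude of low-frequency fluctuations (ALFF)
#'
#' Each in-mask voxel time series is linearly detrended, transformed to the
#' frequency domain with the FFT, and converted to a one-sided amplitude
#' spectrum \eqn{a_k = (2/N) |X_k|}. ALFF is the mean of \eqn{a_k} over the
#' frequency bins falling inside the band (default 0.01-0.08 Hz). Defining
#' ALFF as the band *mean* (not sum) makes it invariant to how many bins the
#' band happens to contain; a noise-free sinusoid of amplitude A sitting on
#' one of m in-band bins yields exactly A/m.
#'
#' @param ts a [TimeSeriesImage-class].
#' @param bandLow,bandHigh band edges in Hz; `bandHigh` must be below the
#'   Nyquist frequency 1/(2 TR).
#' @param detrend remove the per-voxel linear trend before the transform
#'   (default TRUE). Note the trend regressor is not exactly orthogonal to a
#'   finite sinusoid, so detrending perturbs single-sinusoid closed forms
#'   slightly; signals already orthogonal to \{1, t\} are untouched.
#' @return a [VoxelMap-class] of kind `"alff"`.
#' @export
computeALFF <- function(ts, bandLow = 0.01, bandHigh = 0.08, detrend = TRUE) {
  stopifnot(is(ts, "TimeSeriesImage"), bandLow >= 0, bandHigh > bandLow)
  nyq <- 1 / (2 * ts@tr)
  if (bandHigh >= nyq)
    stop(sprintf("band edge %.4g Hz is not below Nyquist %.4g Hz (TR = %g s)",
                 bandHigh, nyq, ts@tr))
  dm <- dim(ts@data)
  n <- dm[4]
  vox <- which(ts@mask)
  X <- matrix(aperm(ts@data, c(4, 1, 2, 3)), nrow = n)[, vox, drop = FALSE]
  if (detrend) {
    tt <- seq_len(n)
    B <- cbind(1, tt - mean(tt))
    X <- X - B %*% solve(crossprod(B), crossprod(B, X))
  }
  freqs <- (seq_len(n %/% 2)) / (n * ts@tr)   # one-sided, DC excluded
  inband <- which(freqs >= bandLow & freqs <= bandHigh)
  if (length(inband) == 0L)
    stop(sprintf("no frequency bin inside [%.4g, %.4g] Hz; bin spacing is %.4g Hz",
                 bandLow, bandHigh, 1 / (n * ts@tr)))
  amp <- (2 / n) * Mod(stats::mvfft(X)[1L + inband, , drop = FALSE])
  vals <- colMeans(amp)
  out <- array(NA_real_, dm[1:3])
  out[vox] <- vals
  VoxelMap(out, mask = ts@mask, voxelSize = ts@voxelSize, kind = "alff")
}

#' Standardize an ALFF map
#'
#' `"global-mean-divide"` divides by the in-mask mean (mALFF; in-mask mean
#' becomes exactly 1). `"z"` subtracts the in-mask mean and divides by the
#' in-mask standard deviation (in-mask mean 0, sd 1).
#'
#' @param map a [VoxelMap-class].
#' @param mode `"global-mean-divide"` or `"z"`.
#' @return a [VoxelMap-class] of kind `"malff"` or `"z"`.
#' @export
standardizeMap <- function(map, mode = c("global-mean-divide", "z")) {
  mode <- match.arg(mode)
  stopifnot(is(map, "VoxelMap"))
  v <- inMask(map)
  d <- map@data
  if (mode == "global-mean-divide") {
    m <- mean(v)
    if (!is.finite(m) || m <= 0) stop("in-mask mean must be > 0 for mALFF")
    VoxelMap(d / m, mask = map@mask, voxelSize = map@voxelSize, kind = "malff")
  } else {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero in-mask variance: z-map undefined")
    VoxelMap((d - mean(v)) / s, mask = map@mask, voxelSize = map@voxelSize,
             kind = "z")
  }
}

# Stack subject maps into a voxels x subjects matrix over the common mask.
.stackMaps <- function(maps) {
  stopifnot(length(maps) >= 2L, all(vapply(maps, is, TRUE, class2 = "VoxelMap")))
  m1 <- maps[[1L]]
  for (m in maps[-1L]) .assertSameGrid(m@data, m1@data, "subject maps")
  mask <- Reduce(`&`, lapply(maps, mapMask))
  X <- vapply(maps, function(m) m@data[mask], numeric(sum(mask)))
  list(X = X, mask = mask, voxelSize = m1@voxelSize)
}

#' Voxel-wise statistic map: covariate correlation or two-sample contrast
#'
#' With a numeric `design` (one value per subject) computes the voxel-wise
#' Pearson correlation r with a two-tailed p on n-2 df. With a two-level
#' factor/character `design` computes the equal-variance two-sample t
#' (first level minus second) with a two-tailed p on n1+n2-2 df.
#' Voxels with zero variance across subjects get `NA` statistics and are
#' excluded from later cluster formation.
#'
#' @param maps list of [VoxelMap-class], one per subject, identical grids.
#' @param design numeric covariate, or group labels with exactly 2 levels.
#' @return a [StatMap-class].
#' @export
voxelwiseStatMap <- function(maps, design) {
  st <- .stackMaps(maps)
  X <- st$X
  n <- ncol(X)
  dm <- dim(maps[[1L]]@data)
  mkMap <- function(vals, kind) {
    a <- array(NA_real_, dm)
    a[st$mask] <- vals
    bad <- st$mask & !is.finite(a)
    msk <- st$mask & !bad
    VoxelMap(a, mask = msk, voxelSize = st$voxelSize, kind = kind)
  }
  if (is.numeric(design)) {
    stopifnot(length(design) == n, all(is.finite(design)), n >= 4L)
    xc <- design - mean(design)
    Xc <- X - rowMeans(X)
    sx <- sqrt(rowSums(Xc^2))
    sy <- sqrt(sum(xc^2))
    r <- as.vector(Xc %*% xc) / (sx * sy)
    r[sx == 0] <- NA_real_
    df <- n - 2
    tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df)
    p <- pmax(p, .Machine$double.xmin)
    new("StatMap", stat = mkMap(r, "r"), p = mkMap(p, "p"),
        statKind = "r", df = df, n = as.integer(n))
  } else {
    g <- as.factor(design)
    stopifnot(length(g) == n, nlevels(g) == 2L)
    n1 <- sum(g == levels(g)[1L]); n2 <- sum(g == levels(g)[2L])
    stopifnot(n1 >= 3L, n2 >= 3L)
    i1 <- g == levels(g)[1L]
    m1 <- rowMeans(X[, i1, drop = FALSE]); m2 <- rowMeans(X[, !i1, drop = FALSE])
    ss1 <- rowSums((X[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((X[, !i1, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2
    sp2 <- (ss1 + ss2) / df
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    tt[sp2 == 0] <- NA_real_
    p <- 2 * stats::pt(-abs(tt), df)
    p <- pmax(p, .Machine$double.xmin)
    new("StatMap", stat = mkMap(tt, "t"), p = mkMap(p, "p"),
        statKind = "t", df = df, n = as.integer(n))
  }
}

#' Per-subject residual maps from the voxel-wise model
#'
#' Residuals of each subject's map after removing the fitted voxel-wise model
#' (intercept + covariate, or group means). Feed these to
#' [estimateSmoothness()].
#'
#' @inheritParams voxelwiseStatMap
#' @return list of [VoxelMap-class] residual maps.
#' @export
voxelResiduals <- function(maps, design) {
  st <- .stackMaps(maps)
  X <- st$X
  B <- if (is.numeric(design)) cbind(1, design) else stats::model.matrix(~ as.factor(design))
  H <- B %*% solve(crossprod(B), t(B))
  R <- X - X %*% t(H)
  dm <- dim(maps[[1L]]@data)
  lapply(seq_len(ncol(R)), function(j) {
    a <- array(NA_real_, dm)
    a[st$mask] <- R[, j]
    VoxelMap(a, mask = st$mask, voxelSize = st$voxelSize, kind = "z")
  })
}

#' Estimate spatial smoothness (FWHM) from residual maps
#'
#' Each residual map is variance-normalized in-mask, and per axis the variance
#' of spatial first differences (pooled over maps and voxels whose neighbour is
#' also in-mask) gives the lag-one autocorrelation
#' \eqn{\rho = 1 - v_d / 2}; for a Gaussian autocorrelation field this implies
#' \eqn{FWHM_{vox} = \sqrt{-2 \ln 2 / \ln \rho}}. Estimates are floored at one
#' voxel (white noise attains the floor).
#'
#' @param residuals list of [VoxelMap-class] residual maps (>= 2).
#' @return numeric length-3 FWHM in mm.
#' @export
estimateSmoothness <- function(residuals) {
  stopifnot(length(residuals) >= 2L)
  mask <- mapMask(residuals[[1L]])
  dm <- dim(mask)
  vs <- voxelSize(residuals[[1L]])
  fwhm <- numeric(3L)
  norm <- lapply(residuals, function(m) {
    v <- m@data
    s <- stats::sd(v[mask])
    if (!is.finite(s) || s == 0) s <- 1
    v / s
  })
  for (ax in 1:3) {
    if (dm[ax] < 2L) stop("mask too small for differences on axis ", ax)
    lo <- rep(list(quote(expr = )), 3L); hi <- lo
    lo[[ax]] <- 1:(dm[ax] - 1L); hi[[ax]] <- 2:dm[ax]
    mlo <- do.call(`[`, c(list(mask), lo, drop = FALSE))
    mhi <- do.call(`[`, c(list(mask), hi, drop = FALSE))
    ok <- mlo & mhi
    if (!any(ok)) stop("mask too small for differences on axis ", ax)
    dif <- unlist(lapply(norm, function(v) {
      (do.call(`[`, c(list(v), hi, drop = FALSE)) -
         do.call(`[`, c(list(v), lo, drop = FALSE)))[ok]
    }))
    vd <- mean(dif^2)
    rho <- 1 - vd / 2
    f <- if (rho <= 0) 0 else sqrt(-2 * log(2) / log(rho))
    fwhm[ax] <- max(f, 1) * vs[ax]
  }
  fwhm
}

#' Mean map value per atlas parcel
#'
#' Arithmetic mean of in-mask voxel values within each parcel. Parcels with no
#' in-mask voxel are reported as `NA` (missing), never 0.
#'
#' @param map a [VoxelMap-class].
#' @param parcellation a [Parcellation-class] on the same grid.
#' @return named numeric vector, one entry per region id in the region table.
#' @export
regionalMeans <- function(map, parcellation) {
  .assertSameGrid(map@data, parcellation@labels, "map and parcellation")
  ids <- parcellation@regions$id
  lab <- parcellation@labels
  ok <- map@mask & lab != 0L
  mv <- tapply(map@data[ok], lab[ok], mean)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  out[names(mv)] <- mv
  out
}
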