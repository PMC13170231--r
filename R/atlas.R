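# Donor microarray -> regional expression matrix.
#
# Processing order mirrors the standard atlas-expression workflow: probe
# filtering, sample-to-parcel assignment (2 mm tolerance, hemisphere
# constrained), per-donor robust sigmoid normalization, differential-stability
# probe selection, then within-donor / across-donor averaging.

#' Filter unreliable probes
#'
#' Removes probes lacking a valid gene id and probes whose intensity is below
#' background in at least 50% of samples (inclusive rule), pooled across
#' donors. The background threshold comes from the bundle (`@background`) when
#' supplied; otherwise it defaults to the bundle-wide median of all
#' intensities. Counts removed per criterion are attached as the
#' `"filter_counts"` attribute.
#'
#' @param bundle a [DonorBundle-class].
#' @param background optional numeric override of the background threshold.
#' @return the filtered [DonorBundle-class].
#' @export
filterProbes <- function(bundle, background = NULL) {
  stopifnot(is(bundle, "DonorBundle"))
  thr <- background
  if (is.null(thr)) thr <- bundle@background
  if (is.null(thr)) thr <- stats::median(bundle@expr)
  gid <- bundle@probes$gene_id
  badId <- is.na(gid) | !nzchar(as.character(gid))
  lowFrac <- rowMeans(bundle@expr < thr)
  badLow <- lowFrac >= 0.5
  drop <- badId | badLow
  if (all(drop)) stop("probe filter removed all probes (threshold ", thr, ")")
  out <- DonorBundle(bundle@expr[!drop, , drop = FALSE],
                     bundle@probes[!drop, , drop = FALSE],
                     bundle@samples, bundle@background)
  attr(out, "filter_counts") <- c(invalid_id = sum(badId),
                                  low_intensity = sum(badLow & !badId),
                                  kept = sum(!drop))
  out
}

#' Assign donor samples to atlas parcels
#'
#' A sample is assigned to the parcel of its containing voxel; failing that,
#' to the parcel of the nearest labelled voxel provided the Euclidean distance
#' is at most `maxDistMM` and the hemisphere matches (sign of the x
#' coordinate; midline `"M"` parcels match either side). Anything else is
#' unassigned (`NA`) — a legal outcome that downstream stages must tolerate.
#'
#' @param bundle a [DonorBundle-class].
#' @param parcellation a [Parcellation-class].
#' @param maxDistMM assignment tolerance in mm (default 2).
#' @return integer vector of region ids (NA = unassigned), one per sample.
#' @export
assignSamples <- function(bundle, parcellation, maxDistMM = 2) {
  stopifnot(is(bundle, "DonorBundle"), is(parcellation, "Parcellation"))
  dm <- dim(parcellation@labels)
  vs <- parcellation@voxelSize
  co <- as.matrix(bundle@samples[, c("x", "y", "z")])
  hemOf <- stats::setNames(as.character(parcellation@regions$hemisphere),
                           parcellation@regions$id)
  labIdx <- which(parcellation@labels != 0L)
  labCo <- voxelToMM(arrayInd(labIdx, dm), dm, vs)
  labReg <- parcellation@labels[labIdx]
  out <- rep(NA_integer_, nrow(co))
  vox <- mmToVoxel(co, dm, vs)
  for (i in seq_len(nrow(co))) {
    v <- vox[i, ]
    if (all(v >= 1L) && all(v <= dm)) {
      r <- parcellation@labels[v[1], v[2], v[3]]
      if (r != 0L) { out[i] <- r; next }
    }
    d2 <- colSums((t(labCo) - co[i, ])^2)
    sampleHem <- if (co[i, 1] < 0) "L" else "R"
    okHem <- hemOf[as.character(labReg)] %in% c(sampleHem, "M")
    d2[!okHem] <- Inf
    j <- which.min(d2)
    if (length(j) && is.finite(d2[j]) && sqrt(d2[j]) <= maxDistMM)
      out[i] <- labReg[j]
  }
  out
}

#' Robust sigmoid normalization
#'
#' Outlier-resistant scaling
#' \deqn{x' = 1 / (1 + \exp(-(x - median(x)) / (IQR(x)/1.35)))}
#' optionally followed by min-max rescaling to the unit interval. When the
#' IQR is zero the standard deviation replaces it; if both are zero the
#' values cannot be scaled and `NA`s are returned (the gene is dropped for
#' that donor).
#'
#' @param x numeric vector (>= 2 distinct values for a meaningful result).
#' @param rescale rescale to `[0, 1]` after the sigmoid (default TRUE).
#' @return numeric vector of scaled values.
#' @export
robustSigmoid <- function(x, rescale = TRUE) {
  med <- stats::median(x)
  sc <- stats::IQR(x) / 1.35
  if (sc == 0) sc <- stats::sd(x)
  if (!is.finite(sc) || sc == 0) return(rep(NA_real_, length(x)))
  y <- 1 / (1 + exp(-(x - med) / sc))
  if (rescale) {
    rng <- range(y)
    y <- if (diff(rng) == 0) rep(NA_real_, length(x)) else (y - rng[1]) / diff(rng)
  }
  y
}

# Per-probe donor-level region-mean profiles on normalized data.
# Returns list(profiles = list per donor of probe x region matrix, regions).
.donorProfiles <- function(bundle, assignment, normalize = TRUE) {
  donors <- unique(bundle@samples$donor)
  lapply(stats::setNames(donors, donors), function(d) {
    cols <- which(bundle@samples$donor == d & !is.na(assignment))
    if (!length(cols)) return(NULL)
    ex <- bundle@expr[, cols, drop = FALSE]
    if (normalize) ex <- t(apply(ex, 1L, robustSigmoid))
    reg <- assignment[cols]
    regs <- sort(unique(reg))
    prof <- vapply(regs, function(r) rowMeans(ex[, reg == r, drop = FALSE], na.rm = TRUE),
                   numeric(nrow(ex)))
    prof <- matrix(prof, nrow = nrow(ex), dimnames = list(bundle@probes$probe_id, regs))
    prof
  })
}

#' Select one probe per gene by differential stability
#'
#' Differential stability (DS) of a probe is the mean, over all donor pairs,
#' of the Pearson correlation between its donor-level region-mean profiles
#' restricted to regions sampled in both donors (pairs sharing fewer than 3
#' regions contribute nothing). Per gene the probe with maximal DS wins; ties
#' break to the higher mean intensity, then the lexicographically smaller
#' probe id. Genes whose probes never attain a defined DS are dropped with a
#' warning.
#'
#' @param bundle a (filtered) [DonorBundle-class] with >= 2 donors.
#' @param assignment sample-to-region vector from [assignSamples()].
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return data.frame `gene_id`, `symbol`, `probe_id`, `ds`.
#' @export
selectProbesByDS <- function(bundle, assignment, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  donors <- unique(bundle@samples$donor)
  if (length(donors) < 2L) stop("differential stability needs >= 2 donors")
  prof <- Filter(Negate(is.null), .donorProfiles(bundle, assignment))
  nP <- nrow(bundle@expr)
  ds <- rep(NA_real_, nP)
  pairs <- utils::combn(length(prof), 2L)
  cors <- matrix(NA_real_, nP, ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- prof[[pairs[1, j]]]; b <- prof[[pairs[2, j]]]
    shared <- intersect(colnames(a), colnames(b))
    if (length(shared) < 3L) next
    A <- a[, shared, drop = FALSE]; B <- b[, shared, drop = FALSE]
    for (i in seq_len(nP)) {
      if (stats::sd(A[i, ]) > 0 && stats::sd(B[i, ]) > 0)
        cors[i, j] <- stats::cor(A[i, ], B[i, ], method = method)
    }
  }
  ds <- rowMeans(cors, na.rm = TRUE)
  ds[!is.finite(ds)] <- NA_real_
  meanInt <- rowMeans(bundle@expr)
  pr <- bundle@probes
  keep <- !is.na(ds)
  if (!any(keep)) stop("no probe attained a defined differential stability")
  dropped <- unique(pr$gene_id[!pr$gene_id %in% pr$gene_id[keep]])
  if (length(dropped))
    warning("dropping ", length(dropped), " gene(s) with no defined DS")
  df <- data.frame(gene_id = pr$gene_id, symbol = pr$symbol,
                   probe_id = pr$probe_id, ds = ds, meanInt = meanInt,
                   stringsAsFactors = FALSE)[keep, ]
  df <- df[order(df$gene_id, -df$ds, -df$meanInt, df$probe_id), ]
  sel <- df[!duplicated(df$gene_id), c("gene_id", "symbol", "probe_id", "ds")]
  rownames(sel) <- NULL
  sel
}

#' Build the region x gene expression matrix
#'
#' For each selected probe, samples are robust-sigmoid normalized per donor,
#' averaged first within each donor's samples of a region, then unweighted
#' across donors. Regions sampled by no donor are absent from the matrix.
#' With `zscore = TRUE` each gene column is z-standardized across the present
#' regions afterwards.
#'
#' @param bundle a (filtered) [DonorBundle-class].
#' @param selection probe selection from [selectProbesByDS()].
#' @param assignment sample-to-region vector from [assignSamples()].
#' @param zscore z-standardize each gene across regions (default FALSE).
#' @return a [RegionalExpression-class] (region rows named by region id,
#'   gene columns named by symbol).
#' @export
buildRegionalMatrix <- function(bundle, selection, assignment, zscore = FALSE) {
  rows <- match(selection$probe_id, bundle@probes$probe_id)
  stopifnot(!anyNA(rows))
  sub <- DonorBundle(bundle@expr[rows, , drop = FALSE],
                     bundle@probes[rows, , drop = FALSE],
                     bundle@samples, bundle@background)
  prof <- Filter(Negate(is.null), .donorProfiles(sub, assignment))
  regs <- sort(unique(as.integer(unlist(lapply(prof, colnames)))))
  acc <- array(NA_real_, c(length(rows), length(regs), length(prof)),
               dimnames = list(selection$symbol, regs, names(prof)))
  for (d in seq_along(prof))
    acc[, colnames(prof[[d]]), d] <- prof[[d]]
  mat <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  mat[is.nan(mat)] <- NA_real_
  counts <- vapply(names(prof), function(d) {
    cols <- bundle@samples$donor == d & !is.na(assignment)
    tab <- table(factor(assignment[cols], levels = regs))
    as.integer(tab)
  }, integer(length(regs)))
  counts <- matrix(counts, nrow = length(regs),
                   dimnames = list(regs, names(prof)))
  out <- t(mat)  # regions x genes
  state <- "sigmoid-scaled"
  if (zscore) {
    mu <- colMeans(out, na.rm = TRUE)
    sdv <- apply(out, 2L, stats::sd, na.rm = TRUE)
    keepG <- is.finite(sdv) & sdv > 0
    out <- sweep(sweep(out[, keepG, drop = FALSE], 2L, mu[keepG], "-"),
                 2L, sdv[keepG], "/")
    state <- "z"
  }
  new("RegionalExpression", mat = unclass(out), sampleCounts = counts,
      state = state)
}
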