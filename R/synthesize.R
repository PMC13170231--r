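# Synthetic-data generators with planted ground truth. Every input the
# pipeline consumes can be generated here, fully determined by a seed, so all
# downstream stages are verifiable at desk scale without any download.

#' Rectangular-block atlas parcellation on a centred grid
#'
#' The grid is split into hemispheres at the x = 0 plane (negative x = left),
#' and each hemisphere is tiled with rectangular (y, z) blocks; left gets
#' ceiling(n/2) parcels. Block geometry makes parcel voxel counts exactly
#' enumerable.
#'
#' @param gridShape integer length-3 grid dimensions.
#' @param nParcels number of parcels (>= 2).
#' @param voxelSize voxel edge lengths in mm.
#' @return a [Parcellation-class].
#' @export
synthParcellation <- function(gridShape, nParcels, voxelSize = c(3, 3, 3)) {
  stopifnot(length(gridShape) == 3L, nParcels >= 2L)
  dm <- as.integer(gridShape)
  if (prod(dm) < nParcels) stop("grid too small to host ", nParcels, " parcels")
  xmm <- voxelCentersMM(dm, voxelSize)[[1L]]
  left <- which(xmm < 0)
  right <- setdiff(seq_len(dm[1]), left)
  nLeft <- ceiling(nParcels / 2)
  nRight <- nParcels - nLeft
  lab <- array(0L, dm)
  cutIdx <- function(n, b) {
    if (b <= 1L) rep(1L, n) else as.integer(cut(seq_len(n), b, labels = FALSE))
  }
  fill <- function(xidx, m, offset) {
    if (m == 0L) return(invisible())
    by <- ceiling(sqrt(m)); bz <- ceiling(m / by)
    iy <- cutIdx(dm[2], by)
    iz <- cutIdx(dm[3], bz)
    for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
      id <- (iz[z] - 1L) * by + iy[y]
      if (id > m) id <- m
      lab[xidx, y, z] <<- offset + id
    }
  }
  fill(left, nLeft, 0L)
  fill(right, nRight, nLeft)
  counts <- tabulate(lab, nParcels)
  if (any(counts == 0L))
    stop("grid too small to host ", nParcels, " parcels (empty parcel)")
  regions <- data.frame(
    id = seq_len(nParcels),
    name = c(sprintf("lh_region_%02d", seq_len(nLeft)),
             sprintf("rh_region_%02d", seq_len(nRight))),
    hemisphere = c(rep("L", nLeft), rep("R", nRight)),
    stringsAsFactors = FALSE)
  Parcellation(lab, voxelSize = voxelSize, regions = regions)
}

# Snap a target frequency to the nearest exact FFT bin (>= first bin).
.snapToBin <- function(f, n, tr) max(1L, round(f * n * tr)) / (n * tr)

#' Synthesize an imaging cohort with a planted regional amplitude pattern
#'
#' Each subject's voxel time series is a sum of three sinusoids at fixed
#' in-band (0.01-0.08 Hz) frequencies (snapped to exact FFT bins where
#' possible, keeping the amplitude spectrum analytically tractable) whose
#' amplitude is region-specific, plus white noise. All voxels of a region
#' share the subject's regional signal; amplitudes get optional per-subject
#' jitter, and the realized subject x region amplitudes are recorded in the
#' ground truth (they drive the clinical couplings).
#'
#' @param nSubjects number of subjects.
#' @param gridShape,nParcels,voxelSize passed to [synthParcellation()].
#' @param trSeconds repetition time (s); must keep Nyquist above 0.08 Hz.
#' @param nTimepoints timepoints per subject (>= 64).
#' @param effectSpec named numeric: region id -> target amplitude; regions
#'   not named get `baseAmplitude`.
#' @param baseAmplitude default regional amplitude.
#' @param subjectJitterSd sd of the per-subject additive amplitude jitter.
#' @param noiseSd white-noise sd.
#' @param seed integer; fully determines the output.
#' @return list: `subjects` (list of [TimeSeriesImage-class]),
#'   `parcellation`, `groundTruth` (list with `plantedRegionPattern`,
#'   `subjectAmplitude` (subjects x regions), `signalFreqs`, `seed`).
#' @export
synthCohort <- function(nSubjects, gridShape = c(20, 20, 12), nParcels = 24,
                        trSeconds = 2, nTimepoints = 200,
                        effectSpec = NULL, baseAmplitude = 1,
                        subjectJitterSd = 0, noiseSd = 0.5,
                        voxelSize = c(3, 3, 3), seed = 1L) {
  stopifnot(nParcels >= 2L, nTimepoints >= 64L)
  if (1 / (2 * trSeconds) <= 0.08)
    stop(sprintf("TR = %g s puts Nyquist at %.3g Hz, inside the 0.01-0.08 Hz band",
                 trSeconds, 1 / (2 * trSeconds)))
  parc <- synthParcellation(gridShape, nParcels, voxelSize)
  dm <- as.integer(gridShape)
  ids <- parc@regions$id
  pattern <- stats::setNames(rep(baseAmplitude, nParcels), ids)
  if (!is.null(effectSpec)) {
    bad <- setdiff(names(effectSpec), as.character(ids))
    if (length(bad)) stop("unknown region id in effectSpec: ",
                          paste(bad, collapse = ", "))
    pattern[names(effectSpec)] <- effectSpec
  }
  freqs <- vapply(c(0.02, 0.04, 0.06), .snapToBin, numeric(1),
                  n = nTimepoints, tr = trSeconds)
  tt <- seq_len(nTimepoints) * trSeconds
  lab <- parc@labels
  vox <- which(lab != 0L)
  regOfVox <- lab[vox]
  .withSeed(seed, {
    amp <- matrix(rep(pattern, each = nSubjects), nSubjects, nParcels,
                  dimnames = list(NULL, ids))
    if (subjectJitterSd > 0)
      amp <- amp + matrix(stats::rnorm(nSubjects * nParcels, 0, subjectJitterSd),
                          nSubjects, nParcels)
    amp[amp < 0] <- 0
    subjects <- lapply(seq_len(nSubjects), function(s) {
      phases <- matrix(stats::runif(nParcels * length(freqs), 0, 2 * pi),
                       nParcels, length(freqs))
      sig <- matrix(0, nTimepoints, nParcels)
      for (r in seq_len(nParcels)) {
        w <- 0
        for (j in seq_along(freqs))
          w <- w + sin(2 * pi * freqs[j] * tt + phases[r, j])
        sig[, r] <- amp[s, r] * w
      }
      arr <- array(0, c(dm, nTimepoints))
      flat <- matrix(0, prod(dm), nTimepoints)
      flat[vox, ] <- t(sig[, regOfVox, drop = FALSE])
      if (noiseSd > 0)
        flat[vox, ] <- flat[vox, ] +
          matrix(stats::rnorm(length(vox) * nTimepoints, 0, noiseSd),
                 length(vox), nTimepoints)
      arr <- array(flat, c(dm, nTimepoints))
      TimeSeriesImage(arr, mask = array(lab != 0L, dm), tr = trSeconds,
                      voxelSize = voxelSize)
    })
    list(subjects = subjects, parcellation = parc,
         groundTruth = list(plantedRegionPattern = pattern,
                            subjectAmplitude = amp,
                            signalFreqs = freqs, seed = seed))
  })
}

#' Synthesize a clinical indicator table coupled to regional amplitudes
#'
#' Each indicator is `slope * subjectAmplitude[, region] + noise`; slope 0
#' makes a pure-noise (null) indicator. An `integer0to7` indicator (the CAS
#' convention) is rounded and clamped to 0..7.
#'
#' @param cohort output of [synthCohort()].
#' @param couplingSpec named list: indicator -> list(region, slope, noiseSd,
#'   offset = 0, integer0to7 = FALSE).
#' @param seed integer seed.
#' @return data.frame, one row per subject, one column per indicator.
#' @export
synthClinicalTable <- function(cohort, couplingSpec, seed = 1L) {
  amp <- cohort$groundTruth$subjectAmplitude
  n <- nrow(amp)
  .withSeed(seed, {
    cols <- lapply(couplingSpec, function(sp) {
      reg <- as.character(sp$region)
      if (!reg %in% colnames(amp)) stop("unknown region id: ", reg)
      off <- if (is.null(sp$offset)) 0 else sp$offset
      v <- off + sp$slope * amp[, reg] + stats::rnorm(n, 0, sp$noiseSd)
      if (isTRUE(sp$integer0to7)) v <- pmin(7, pmax(0, round(v)))
      v
    })
    out <- as.data.frame(cols)
    names(out) <- names(couplingSpec)
    cbind(subject = sprintf("sub%03d", seq_len(n)), out,
          stringsAsFactors = FALSE)
  })
}

#' Synthesize donor microarray bundles coupled to a regional pattern
#'
#' Planted genes have regional expected expression that is an affine map of
#' the (z-scored) planted pattern achieving correlation ~ `couplingR` across
#' regions; background genes follow independent regional profiles. Each gene
#' has `probesPerGene` probes: the first carries the signal, extra probes add
#' independent noise (so differential stability prefers the first). A
#' `badProbeFraction` of the background-gene probes is made unreliable (half
#' lose their gene id, half drop below the recorded background intensity in
#' at least half the samples). Intensities are bimodal by design (good ~ N(9, .7),
#' bad ~ N(2, .7)) and the separating background threshold 5 is recorded in
#' the bundle.
#'
#' @param parcellation a [Parcellation-class].
#' @param pattern named numeric region pattern (e.g. the planted ALFF
#'   pattern).
#' @param nGenes,nPlanted gene universe size and number of planted genes.
#' @param nDonors,samplesPerDonor donors and samples per donor (a warning is
#'   issued when `samplesPerDonor` < number of parcels: unsampled regions are
#'   legal and handled downstream).
#' @param probesPerGene probes per gene (>= 1).
#' @param badProbeFraction fraction of all probes made unreliable.
#' @param couplingR planted gene-pattern correlation in `[0, 1]`.
#' @param sampleNoiseSd per-sample intensity noise sd (0 = noise-free).
#' @param probeNoiseSd independent noise sd added to secondary probes.
#' @param seed integer seed.
#' @return list: `bundle` ([DonorBundle-class]), `groundTruth` (list with
#'   `plantedGenes`, `badProbes`, `couplingR`, `geneProfiles`).
#' @export
synthDonorExpression <- function(parcellation, pattern, nGenes = 400,
                                 nPlanted = 25, nDonors = 6,
                                 samplesPerDonor = 40, probesPerGene = 2,
                                 badProbeFraction = 0.1, couplingR = 0.9,
                                 sampleNoiseSd = 0.2, probeNoiseSd = 0.5,
                                 seed = 1L) {
  stopifnot(probesPerGene >= 1L, couplingR >= 0, couplingR <= 1,
            nPlanted < nGenes)
  ids <- parcellation@regions$id
  nR <- length(ids)
  if (samplesPerDonor < nR)
    warning("samplesPerDonor < number of parcels: some regions will lack samples")
  zp <- pattern[as.character(ids)]
  zp <- if (stats::sd(zp) > 0) as.numeric(scale(zp)) else rep(0, nR)
  .withSeed(seed, {
    symbols <- sprintf("G%04d", seq_len(nGenes))
    planted <- sort(sample(symbols, nPlanted))
    prof <- matrix(stats::rnorm(nGenes * nR), nGenes, nR,
                   dimnames = list(symbols, ids))
    isPl <- symbols %in% planted
    prof[isPl, ] <- couplingR * matrix(zp, sum(isPl), nR, byrow = TRUE) +
      sqrt(1 - couplingR^2) * prof[isPl, , drop = FALSE]
    # probes
    probeTab <- data.frame(
      probe_id = sprintf("%s_p%d", rep(symbols, each = probesPerGene),
                         rep(seq_len(probesPerGene), nGenes)),
      gene_id = rep(seq_len(nGenes) + 1000L, each = probesPerGene),
      symbol = rep(symbols, each = probesPerGene),
      stringsAsFactors = FALSE)
    nProbes <- nrow(probeTab)
    nBad <- round(badProbeFraction * nProbes)
    eligible <- which(!probeTab$symbol %in% planted)
    badProbes <- sort(sample(eligible, min(nBad, length(eligible))))
    badId <- badProbes[seq_len(floor(length(badProbes) / 2))]
    badLow <- setdiff(badProbes, badId)
    probeTab$gene_id[badId] <- NA_integer_
    # samples
    lab <- parcellation@labels
    labIdx <- which(lab != 0L)
    dm <- dim(lab)
    vs <- parcellation@voxelSize
    sampRows <- lapply(seq_len(nDonors), function(d) {
      vidx <- sample(labIdx, samplesPerDonor, replace = TRUE)
      mm <- voxelToMM(arrayInd(vidx, dm), dm, vs) +
        matrix(stats::runif(samplesPerDonor * 3, -0.4, 0.4) * rep(vs, each = samplesPerDonor),
               samplesPerDonor, 3L)
      data.frame(donor = sprintf("donor%02d", d),
                 x = mm[, 1], y = mm[, 2], z = mm[, 3],
                 region = lab[vidx], stringsAsFactors = FALSE)
    })
    samples <- do.call(rbind, sampRows)
    nS <- nrow(samples)
    regIdx <- match(samples$region, ids)
    expr <- matrix(NA_real_, nProbes, nS,
                   dimnames = list(probeTab$probe_id, NULL))
    geneOf <- match(probeTab$symbol, symbols)
    base <- 9 + 0.8 * prof[, regIdx, drop = FALSE]   # genes x samples
    for (j in seq_len(probesPerGene)) {
      rows <- seq(j, nProbes, by = probesPerGene)
      e <- base
      if (sampleNoiseSd > 0)
        e <- e + matrix(stats::rnorm(nGenes * nS, 0, sampleNoiseSd), nGenes, nS)
      if (j > 1L)
        e <- e + matrix(stats::rnorm(nGenes * nS, 0, probeNoiseSd), nGenes, nS)
      expr[rows, ] <- e
    }
    for (b in badLow) {
      low <- sample(nS, ceiling(0.6 * nS))
      expr[b, low] <- stats::rnorm(length(low), 2, 0.5)
    }
    bundle <- DonorBundle(expr, probeTab,
                          samples[, c("donor", "x", "y", "z")],
                          background = 5)
    list(bundle = bundle,
         groundTruth = list(plantedGenes = planted,
                            badProbes = probeTab$probe_id[badProbes],
                            couplingR = couplingR,
                            geneProfiles = prof, seed = seed))
  })
}

#' Direct regional-level association instance
#'
#' Generates a regional profile and a region x gene expression matrix in
#' which `nPlanted` genes track the profile with planted correlation
#' `couplingR` — the distilled input of the gene-association stage, used for
#' recovery/FDR studies at full scale (82 regions, thousands of genes)
#' without the donor-microarray machinery.
#'
#' @param nRegions,nGenes,nPlanted instance size.
#' @param couplingR planted correlation.
#' @param seed integer seed.
#' @return list: `alff` (named vector), `expr` (regions x genes), `planted`
#'   (gene names).
#' @export
synthRegionalAssoc <- function(nRegions = 82, nGenes = 5000, nPlanted = 50,
                               couplingR = 0.9, seed = 1L) {
  .withSeed(seed, {
    ids <- as.character(seq_len(nRegions))
    zp <- stats::rnorm(nRegions)
    zp <- as.numeric(scale(zp))
    genes <- sprintf("G%05d", seq_len(nGenes))
    planted <- sort(sample(genes, nPlanted))
    E <- matrix(stats::rnorm(nRegions * nGenes), nRegions, nGenes,
                dimnames = list(ids, genes))
    isPl <- genes %in% planted
    E[, isPl] <- couplingR * matrix(zp, nRegions, sum(isPl)) +
      sqrt(1 - couplingR^2) * E[, isPl, drop = FALSE]
    list(alff = stats::setNames(zp, ids), expr = E, planted = planted)
  })
}

#' 24 immune cell-type marker signatures over a gene universe
#'
#' Disjoint synthetic marker sets named after the 24 immune cell types of the
#' ImmuneCellAI convention (monocytes, memory/naive/helper/regulatory T
#' subsets, B, NK, NKT, MAIT, gamma-delta T, DC, macrophage, neutrophil...).
#'
#' @param geneIds gene universe to draw members from.
#' @param nPerSet genes per signature (default 30).
#' @param seed integer seed.
#' @return named list of 24 character vectors.
#' @export
synthImmuneSignatures <- function(geneIds, nPerSet = 30, seed = 1L) {
  types <- c("B_cell", "CD4_T", "CD8_T", "CD4_naive", "CD8_naive",
             "Cytotoxic_T", "Exhausted_T", "Tr1", "nTreg", "iTreg",
             "Th1", "Th2", "Th17", "Tfh", "Central_memory_T",
             "Effector_memory_T", "NKT", "MAIT", "DC", "Monocyte",
             "Macrophage", "NK", "Neutrophil", "Gamma_delta_T")
  need <- length(types) * nPerSet
  stopifnot(length(geneIds) >= need)
  .withSeed(seed, {
    pick <- sample(geneIds, need)
    stats::setNames(split(pick, rep(seq_along(types), each = nPerSet)), types)
  })
}

#' Synthesize an RNA-seq count matrix with planted effects
#'
#' Counts are negative binomial with \eqn{Var = \mu + \phi \mu^2}; per-group
#' means shift by the planted log2 fold changes, and genes belonging to
#' shifted signatures are co-shifted in the stated direction. Optional
#' per-sample effects couple a signature's genes to an external per-sample
#' covariate (e.g. a subject's regional amplitude), planting a brain-immune
#' correlation.
#'
#' @param nGenes gene universe size (ids `B0001`...).
#' @param nPerGroup named c(case =, control =) sample counts.
#' @param plantedDE named numeric: gene -> log2 fold change (case vs
#'   control).
#' @param dispersion NB dispersion phi (> 0).
#' @param librarySizeRange library sizes drawn uniformly from this range.
#' @param signatureSets named list of signature gene vectors (all members
#'   must exist in the universe).
#' @param signatureShifts named numeric: signature -> log2 shift in cases.
#' @param sampleEffects optional list of `list(set =, log2 = per-sample
#'   numeric)` applied on top (length = total samples, case samples first).
#' @param seed integer seed.
#' @return list: `counts` (gene x sample), `samples` (data.frame `sample`,
#'   `group`), `groundTruth`.
#' @export
synthCountsAndSignatures <- function(nGenes = 3000,
                                     nPerGroup = c(case = 20, control = 20),
                                     plantedDE = NULL, dispersion = 0.1,
                                     librarySizeRange = c(1e6, 2e6),
                                     signatureSets = NULL,
                                     signatureShifts = NULL,
                                     sampleEffects = NULL, seed = 1L) {
  stopifnot(dispersion > 0, all(c("case", "control") %in% names(nPerGroup)))
  genes <- sprintf("B%04d", seq_len(nGenes))
  if (!is.null(plantedDE)) {
    miss <- setdiff(names(plantedDE), genes)
    if (length(miss)) stop("planted DE gene absent from universe: ",
                           paste(miss, collapse = ", "))
  }
  if (!is.null(signatureSets)) {
    miss <- setdiff(unlist(signatureSets), genes)
    if (length(miss)) stop("signature gene absent from universe: ",
                           paste(miss, collapse = ", "))
  }
  nCase <- nPerGroup[["case"]]; nCtrl <- nPerGroup[["control"]]
  nS <- nCase + nCtrl
  group <- c(rep("case", nCase), rep("control", nCtrl))
  .withSeed(seed, {
    baseLog2 <- stats::rnorm(nGenes, 5, 1.5)
    lfc <- stats::setNames(rep(0, nGenes), genes)
    if (!is.null(plantedDE)) lfc[names(plantedDE)] <- plantedDE
    if (!is.null(signatureShifts)) {
      for (s in names(signatureShifts))
        lfc[signatureSets[[s]]] <- lfc[signatureSets[[s]]] + signatureShifts[[s]]
    }
    log2mu <- matrix(baseLog2, nGenes, nS, dimnames = list(genes, NULL))
    log2mu[, group == "case"] <- log2mu[, group == "case"] + lfc
    if (!is.null(sampleEffects)) {
      for (ef in sampleEffects) {
        stopifnot(length(ef$log2) == nS)
        gi <- match(ef$set, genes)
        log2mu[gi, ] <- log2mu[gi, ] +
          matrix(ef$log2, length(gi), nS, byrow = TRUE)
      }
    }
    rel <- 2^log2mu
    props <- sweep(rel, 2L, colSums(rel), "/")
    libs <- stats::runif(nS, librarySizeRange[1], librarySizeRange[2])
    mu <- sweep(props, 2L, libs, "*")
    counts <- matrix(stats::rnbinom(nGenes * nS, size = 1 / dispersion, mu = mu),
                     nGenes, nS, dimnames = list(genes, NULL))
    samples <- data.frame(sample = sprintf("%s%02d", group,
                                           c(seq_len(nCase), seq_len(nCtrl))),
                          group = group, stringsAsFactors = FALSE)
    colnames(counts) <- samples$sample
    list(counts = counts, samples = samples,
         groundTruth = list(plantedDE = plantedDE,
                            signatureShifts = signatureShifts,
                            dispersion = dispersion, seed = seed))
  })
}

#' Synthesize an interaction graph with one planted dense module
#'
#' Erdos-Renyi background with edge probability `backgroundEdgeP`, plus a
#' planted module of `moduleSize` nodes whose internal edges appear with
#' probability `moduleEdgeP`. Background edges get confidence weights in
#' `[0.4, 0.9]`, module edges in `[0.7, 0.99]`.
#'
#' @param nodes character node names, or an integer count.
#' @param backgroundEdgeP,moduleEdgeP edge probabilities; the module must be
#'   denser.
#' @param moduleSize planted module size.
#' @param moduleNodes optional explicit module node names.
#' @param seed integer seed.
#' @return list: `edges` (data.frame `node_a`, `node_b`, `weight`),
#'   `groundTruth` (list with `moduleNodes`).
#' @export
synthPpiGraph <- function(nodes = 60, backgroundEdgeP = 0.05, moduleSize = 6,
                          moduleEdgeP = 1, moduleNodes = NULL, seed = 1L) {
  stopifnot(moduleEdgeP > backgroundEdgeP)
  if (is.numeric(nodes) && length(nodes) == 1L)
    nodes <- sprintf("N%03d", seq_len(nodes))
  .withSeed(seed, {
    if (is.null(moduleNodes)) moduleNodes <- sort(sample(nodes, moduleSize))
    stopifnot(all(moduleNodes %in% nodes))
    pairs <- utils::combn(nodes, 2L)
    inMod <- pairs[1, ] %in% moduleNodes & pairs[2, ] %in% moduleNodes
    pEdge <- ifelse(inMod, moduleEdgeP, backgroundEdgeP)
    keep <- stats::runif(ncol(pairs)) < pEdge
    w <- ifelse(inMod[keep], stats::runif(sum(keep), 0.7, 0.99),
                stats::runif(sum(keep), 0.4, 0.9))
    edges <- data.frame(node_a = pairs[1, keep], node_b = pairs[2, keep],
                        weight = w, stringsAsFactors = FALSE)
    list(edges = edges, groundTruth = list(moduleNodes = moduleNodes, seed = seed))
  })
}

#' Smooth Gaussian null field of known FWHM
#'
#' White noise convolved (circularly, via FFT) with a Gaussian kernel of the
#' stated per-axis FWHM in voxels, renormalized to unit variance — a null
#' field for random-field calibration studies.
#'
#' @param gridShape integer length-3.
#' @param fwhmVox per-axis FWHM in voxels.
#' @param voxelSize mm.
#' @param seed integer seed.
#' @return a [VoxelMap-class] of kind `"z"`.
#' @export
synthSmoothField <- function(gridShape, fwhmVox = c(2, 2, 2),
                             voxelSize = c(3, 3, 3), seed = 1L) {
  dm <- as.integer(gridShape)
  sig <- fwhmVox / sqrt(8 * log(2))
  kern1 <- function(n, s) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  kx <- kern1(dm[1], sig[1]); ky <- kern1(dm[2], sig[2]); kz <- kern1(dm[3], sig[3])
  K <- outer(outer(fft(kx), fft(ky)), fft(kz))
  .withSeed(seed, {
    noise <- array(stats::rnorm(prod(dm)), dm)
    sm <- Re(fft(fft(noise) * K, inverse = TRUE)) / prod(dm)
    sm <- sm / sqrt(mean(Mod(K)^2))
    VoxelMap(sm, mask = array(TRUE, dm), voxelSize = voxelSize, kind = "z")
  })
}
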