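# Preset synthetic bundles: the complete input sets for the retrospective and
# prospective arms, with planted ground truth, at desk scale.

#' Retrospective synthetic bundle
#'
#' Imaging cohort with one high-amplitude parcel, a clinical table whose CAS
#' and TRAb indicators track that parcel's subject amplitudes (the remaining
#' indicators are nulls), donor expression bundles whose planted genes track
#' the amplitude pattern across regions, pathway gene sets (the planted set
#' plus random sets), and an interaction graph over gene symbols with a
#' planted module of 6 planted genes.
#'
#' @param seed integer; determines everything.
#' @param nSubjects,gridShape,nParcels cohort geometry.
#' @param plantedParcel region id given the largest amplitude (the clinical
#'   couplings attach to it).
#' @param amplitudeRange regional amplitudes are spread evenly over this
#'   range (a graded spatial pattern; the planted parcel gets the maximum).
#' @param couplingR planted gene-pattern correlation.
#' @param null if TRUE, all couplings and effects are switched off (pure
#'   noise bundle for calibration).
#' @return list with `cohort`, `clinical`, `donor`, `geneSets`, `ppi`,
#'   `groundTruth`.
#' @export
synthRetroBundle <- function(seed = 1L, nSubjects = 30, gridShape = c(20, 20, 12),
                             nParcels = 24, plantedParcel = 7,
                             amplitudeRange = c(0.8, 1.6), couplingR = 0.9,
                             null = FALSE) {
  eff <- if (null) NULL else .withSeed(seed + 10L, {
    amps <- seq(amplitudeRange[1], amplitudeRange[2], length.out = nParcels)
    e <- stats::setNames(numeric(nParcels), seq_len(nParcels))
    e[as.character(sample(setdiff(seq_len(nParcels), plantedParcel)))] <-
      amps[-nParcels]
    e[as.character(plantedParcel)] <- amps[nParcels]
    e
  })
  cohort <- synthCohort(nSubjects, gridShape, nParcels,
                        effectSpec = eff, subjectJitterSd = 0.15,
                        noiseSd = 0.5, seed = seed)
  # under the null the indicators are pure noise around clinically typical
  # central values (slope 0 with a sensible offset keeps CAS non-degenerate)
  clin <- synthClinicalTable(cohort, if (null) list(
    duration  = list(region = plantedParcel, slope = 0, noiseSd = 10, offset = 18),
    cas       = list(region = plantedParcel, slope = 0, noiseSd = 1.2,
                     offset = 2, integer0to7 = TRUE),
    proptosis = list(region = plantedParcel, slope = 0, noiseSd = 2.6, offset = 19.5),
    tsh       = list(region = plantedParcel, slope = 0, noiseSd = 1.2, offset = 1.5),
    ft3       = list(region = plantedParcel, slope = 0, noiseSd = 0.9, offset = 3.7),
    ft4       = list(region = plantedParcel, slope = 0, noiseSd = 7, offset = 6.6),
    trab      = list(region = plantedParcel, slope = 0, noiseSd = 9.6, offset = 8.2)
  ) else list(
    duration  = list(region = plantedParcel, slope = 0, noiseSd = 10, offset = 18),
    cas       = list(region = plantedParcel, slope = 6, noiseSd = 0.4,
                     offset = -7.6, integer0to7 = TRUE),
    proptosis = list(region = plantedParcel, slope = 0, noiseSd = 2.6, offset = 19.5),
    tsh       = list(region = plantedParcel, slope = 0, noiseSd = 1.2, offset = 1.5),
    ft3       = list(region = plantedParcel, slope = 0, noiseSd = 0.9, offset = 3.7),
    ft4       = list(region = plantedParcel, slope = 0, noiseSd = 7, offset = 6.6),
    trab      = list(region = plantedParcel, slope = 12, noiseSd = 1.5,
                     offset = -11)), seed = seed + 1L)
  donor <- synthDonorExpression(cohort$parcellation,
                                cohort$groundTruth$plantedRegionPattern,
                                couplingR = if (null) 0 else couplingR,
                                seed = seed + 2L)
  planted <- donor$groundTruth$plantedGenes
  allGenes <- sort(unique(donor$bundle@probes$symbol))
  sets <- .withSeed(seed + 3L, {
    rand <- lapply(1:5, function(i) sample(allGenes, 30))
    names(rand) <- sprintf("random_set_%d", 1:5)
    c(list(planted_pathway = planted), rand)
  })
  ppiNodes <- .withSeed(seed + 4L,
    sort(unique(c(planted, sample(setdiff(allGenes, planted), 40)))))
  ppi <- synthPpiGraph(nodes = ppiNodes, backgroundEdgeP = 0.05,
                       moduleNodes = sort(planted[1:6]), moduleEdgeP = 1,
                       seed = seed + 5L)
  list(cohort = cohort, clinical = clin, donor = donor, geneSets = sets,
       ppi = ppi,
       groundTruth = c(cohort$groundTruth,
                       list(plantedParcel = if (null) NA else plantedParcel,
                            plantedGenes = planted,
                            moduleNodes = ppi$groundTruth$moduleNodes,
                            null = null)))
}

#' Prospective synthetic bundle
#'
#' Two imaging cohorts (case/control) whose case group has a raised amplitude
#' in the planted parcel; an RNA-seq count matrix with planted DE genes
#' (log2FC +/- 2) and planted immune-signature shifts (monocytes up;
#' central-memory, effector-memory and gamma-delta T cells down); and, in the
#' case group, monocyte-signature expression coupled to each subject's
#' planted-parcel amplitude (a planted brain-immune correlation).
#'
#' @param seed integer seed.
#' @param nPerGroup subjects per group.
#' @param gridShape,nParcels,plantedParcel geometry.
#' @param caseAmplitude case amplitude in the planted parcel (controls 1).
#' @param null switch off all effects.
#' @return list with `cohortCase`, `cohortControl`, `counts`, `samples`,
#'   `signatures`, `groundTruth`.
#' @export
synthProspBundle <- function(seed = 1L, nPerGroup = 20, gridShape = c(20, 20, 12),
                             nParcels = 24, plantedParcel = 7,
                             caseAmplitude = 1.5, null = FALSE) {
  effCase <- if (null) NULL else
    stats::setNames(caseAmplitude, as.character(plantedParcel))
  cohortCase <- synthCohort(nPerGroup, gridShape, nParcels,
                            effectSpec = effCase, subjectJitterSd = 0.1,
                            noiseSd = 0.5, seed = seed)
  cohortControl <- synthCohort(nPerGroup, gridShape, nParcels,
                               effectSpec = NULL, subjectJitterSd = 0.1,
                               noiseSd = 0.5, seed = seed + 1L)
  nGenes <- 3000
  genes <- sprintf("B%04d", seq_len(nGenes))
  de <- .withSeed(seed + 2L, {
    up <- sample(genes, 20); down <- sample(setdiff(genes, up), 20)
    stats::setNames(c(rep(2, 20), rep(-2, 20)), c(up, down))
  })
  sigs <- synthImmuneSignatures(setdiff(genes, names(de)), nPerSet = 30,
                                seed = seed + 3L)
  shifts <- c(Monocyte = 1.5, Central_memory_T = -1.5,
              Effector_memory_T = -1.5, Gamma_delta_T = -1.5)
  if (null) { de <- NULL; shifts <- NULL }
  # brain-immune coupling: monocyte genes track case subjects' parcel amplitude
  ampCase <- cohortCase$groundTruth$subjectAmplitude[, as.character(plantedParcel)]
  couple <- if (null) NULL else list(list(
    set = sigs$Monocyte,
    log2 = c(6 * (ampCase - mean(ampCase)), rep(0, nPerGroup))))
  cnt <- synthCountsAndSignatures(nGenes = nGenes,
                                  nPerGroup = c(case = nPerGroup, control = nPerGroup),
                                  plantedDE = de, dispersion = 0.1,
                                  signatureSets = sigs,
                                  signatureShifts = shifts,
                                  sampleEffects = couple, seed = seed + 4L)
  list(cohortCase = cohortCase, cohortControl = cohortControl,
       counts = cnt$counts, samples = cnt$samples, signatures = sigs,
       groundTruth = list(plantedParcel = if (null) NA else plantedParcel,
                          plantedDE = de, signatureShifts = shifts,
                          subjectAmplitudeCase = ampCase, null = null,
                          seed = seed))
}
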