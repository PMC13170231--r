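# Orchestration of the two analysis arms over synthetic (or user-supplied)
# bundles, with threshold configuration, per-stage logging, artifact output
# and a hashed manifest.

.defaultConfig <- function() {
  list(
    band = c(0.01, 0.08),
    clinical_voxel_p = 0.005,   # clinical-correlation arm voxel threshold
    contrast_voxel_p = 0.001,   # group-contrast arm voxel threshold
    cluster_p = 0.05,
    min_voxels = 6L,
    q_max = 0.05, r_min_abs = 0.8,
    de_p = 0.05, de_lfc = 1,
    max_dist_mm = 2,
    ssgsea_alpha = 0.25,
    seed = 1L)
}

#' Read (or build) a run configuration
#'
#' Thresholds default to the conventional values of the analysis (voxel p
#' 0.005 for correlation maps, 0.001 for the group contrast, cluster p 0.05,
#' 6-voxel ROI rule, gene selection q < 0.05 & |r| > 0.8, DE selection
#' p < 0.05 & |logFC| > 1); any field can be overridden in a YAML file or by
#' the `...` arguments.
#'
#' @param path optional YAML file with overrides.
#' @param ... named overrides applied after the file.
#' @return named list of run parameters.
#' @export
readRunConfig <- function(path = NULL, ...) {
  cfg <- .defaultConfig()
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$cluster_p > 0, cfg$cluster_p <= 1,
            cfg$clinical_voxel_p > 0, cfg$contrast_voxel_p > 0,
            cfg$q_max > 0, cfg$r_min_abs >= 0, cfg$r_min_abs < 1,
            cfg$min_voxels >= 1, !is.null(cfg$seed))
  cfg
}

.emit <- function(outDir, name, writer) {
  if (is.null(outDir)) return(NULL)
  path <- file.path(outDir, name)
  writer(path)
  path
}

.manifest <- function(outDir, files, cfg, log) {
  files <- files[!vapply(files, is.null, logical(1))]
  man <- list(config = cfg, stages = log,
              files = lapply(files, function(f)
                list(path = basename(f),
                     md5 = unname(tools::md5sum(f)))))
  if (!is.null(outDir)) {
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  man
}

#' Run the retrospective arm
#'
#' ALFF mapping with global-mean standardization, voxel-wise
#' clinical-indicator correlation with GRF cluster correction and the
#' minimum-overlap ROI rule, donor-microarray regional expression
#' construction (probe filter, 2 mm hemisphere-constrained sample
#' assignment, robust sigmoid normalization, differential-stability probe
#' selection, within/across-donor averaging, z-scoring), gene-wise spatial
#' correlation against the group-mean regional ALFF profile with BH FDR and
#' the |r| threshold, ssGSEA pathway scoring per region, and MCODE module
#' detection on the interaction graph.
#'
#' @param bundle a bundle as produced by [synthRetroBundle()] (or an
#'   equivalently shaped list of user data).
#' @param config from [readRunConfig()].
#' @param indicator clinical column used for the correlation maps
#'   (default `"cas"`).
#' @param outDir optional output directory for TSV/NIfTI artifacts and
#'   `manifest.json`.
#' @return list of stage results plus the manifest.
#' @export
runRetrospective <- function(bundle, config = readRunConfig(),
                             indicator = "cas", outDir = NULL) {
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  parc <- bundle$cohort$parcellation
  # stage 1: ALFF + standardization
  malff <- lapply(bundle$cohort$subjects, function(ts)
    standardizeMap(computeALFF(ts, config$band[1], config$band[2]),
                   "global-mean-divide"))
  log$alff <- list(n_subjects = length(malff))
  # stage 2: clinical correlation map -> clusters -> ROIs
  cov <- bundle$clinical[[indicator]]
  sm <- voxelwiseStatMap(malff, cov)
  fwhm <- estimateSmoothness(voxelResiduals(malff, cov))
  cl <- grfClusterThreshold(sm, fwhm, voxelP = config$clinical_voxel_p,
                            clusterP = config$cluster_p)
  rois <- clustersToROIs(cl, parc, minVoxels = config$min_voxels)
  log$clusters <- list(indicator = indicator, fwhm_mm = fwhm,
                       n_clusters = nrow(clusterTable(cl)),
                       n_rois = nrow(rois))
  # stage 3: regional expression matrix
  filt <- filterProbes(bundle$donor$bundle)
  log$probe_filter <- as.list(attr(filt, "filter_counts"))
  assign <- assignSamples(filt, parc, maxDistMM = config$max_dist_mm)
  log$sample_assignment <- list(assigned = sum(!is.na(assign)),
                                excluded = sum(is.na(assign)))
  sel <- selectProbesByDS(filt, assign)
  regex <- buildRegionalMatrix(filt, sel, assign, zscore = TRUE)
  log$regional_matrix <- list(n_regions = nrow(exprMatrix(regex)),
                              n_genes = ncol(exprMatrix(regex)))
  # stage 4: gene-ALFF spatial correlation + selection
  groupMean <- Reduce(`+`, lapply(malff, mapData)) / length(malff)
  gm <- VoxelMap(groupMean, mask = mapMask(malff[[1]]),
                 voxelSize = voxelSize(malff[[1]]), kind = "malff")
  alffReg <- regionalMeans(gm, parc)
  assoc <- correlateGeneMaps(alffReg, regex)
  lists <- selectCorrelatedGenes(assoc, qMax = config$q_max,
                                 rMinAbs = config$r_min_abs)
  log$gene_assoc <- list(n_positive = length(lists$positive),
                         n_negative = length(lists$negative))
  # stage 5: ssGSEA pathway scores per region
  scores <- ssgseaScore(exprMatrix(regex), bundle$geneSets,
                        alpha = config$ssgsea_alpha)
  # stage 6: MCODE on the interaction graph
  g <- interactionGraph(bundle$ppi$edges)
  complexes <- mcodeComplexes(g)
  log$mcode <- list(n_complexes = nrow(complexes))
  files <- list(
    rois = .emit(outDir, "rois.tsv", function(p) writeTSV(rois, p)),
    clusters = .emit(outDir, "clusters.tsv",
                     function(p) writeTSV(clusterTable(cl), p)),
    assoc = .emit(outDir, "gene_association.tsv",
                  function(p) writeTSV(assoc, p)),
    pos = .emit(outDir, "genes_positive.txt",
                function(p) writeLines(lists$positive, p)),
    neg = .emit(outDir, "genes_negative.txt",
                function(p) writeLines(lists$negative, p)),
    scores = .emit(outDir, "ssgsea_scores.tsv", function(p)
      writeTSV(data.frame(region = rownames(scores), scores,
                          check.names = FALSE), p)),
    complexes = .emit(outDir, "mcode_complexes.tsv",
                      function(p) writeTSV(complexes, p)),
    alff = .emit(outDir, "group_mean_malff.nii",
                 function(p) writeNIfTI1(gm, p)))
  man <- .manifest(outDir, files, config, log)
  list(malff = malff, statMap = sm, clusters = cl, rois = rois,
       regional = regex, assoc = assoc, geneLists = lists,
       ssgsea = scores, complexes = complexes, log = log, manifest = man)
}

#' Run the prospective arm
#'
#' Case-control ALFF contrast (two-sample t with GRF correction at the
#' stricter contrast voxel threshold), per-subject cluster-mean ALFF,
#' moderated-t differential expression on logCPM with the raw-p / |logFC|
#' rule, immune-signature ssGSEA scoring with the normality-gated group
#' test, Spearman correlation between cluster-mean ALFF and case immune
#' scores, and voxel-wise immune correlation ROIs.
#'
#' @param bundle from [synthProspBundle()].
#' @param config from [readRunConfig()].
#' @param outDir optional artifact directory.
#' @param voxelwiseImmune also run the (slower) voxel-wise immune
#'   correlation stage (default TRUE).
#' @return list of stage results plus the manifest.
#' @export
runProspective <- function(bundle, config = readRunConfig(), outDir = NULL,
                           voxelwiseImmune = TRUE) {
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  parc <- bundle$cohortCase$parcellation
  malffCase <- lapply(bundle$cohortCase$subjects, function(ts)
    standardizeMap(computeALFF(ts, config$band[1], config$band[2]),
                   "global-mean-divide"))
  malffCtrl <- lapply(bundle$cohortControl$subjects, function(ts)
    standardizeMap(computeALFF(ts, config$band[1], config$band[2]),
                   "global-mean-divide"))
  maps <- c(malffCase, malffCtrl)
  groups <- factor(c(rep("case", length(malffCase)),
                     rep("control", length(malffCtrl))),
                   levels = c("case", "control"))
  sm <- voxelwiseStatMap(maps, groups)
  fwhm <- estimateSmoothness(voxelResiduals(maps, groups))
  cl <- grfClusterThreshold(sm, fwhm, voxelP = config$contrast_voxel_p,
                            clusterP = config$cluster_p)
  rois <- clustersToROIs(cl, parc, minVoxels = config$min_voxels)
  log$contrast <- list(fwhm_mm = fwhm, n_clusters = nrow(clusterTable(cl)),
                       n_rois = nrow(rois))
  # per-subject mean mALFF over the surviving clusters
  sig <- mapData(cl@labels) > 0
  clusterMean <- if (any(sig, na.rm = TRUE)) {
    vapply(maps, function(m) mean(mapData(m)[which(sig)]), numeric(1))
  } else rep(NA_real_, length(maps))
  # differential expression
  lc <- logCPM(bundle$counts)
  keep <- rowSums(bundle$counts) > 0
  de <- moderatedTDE(lc[keep, , drop = FALSE],
                     factor(bundle$samples$group, levels = c("case", "control")))
  deLists <- selectDEGenes(de, pMax = config$de_p, lfcMin = config$de_lfc)
  log$de <- list(n_genes = sum(keep), n_up = length(deLists$up),
                 n_down = length(deLists$down),
                 d0 = attr(de, "d0"), s02 = attr(de, "s02"))
  # immune infiltration scores + group comparison
  imm <- immuneScores(bundle$counts, bundle$signatures,
                      alpha = config$ssgsea_alpha)
  cmp <- scoreGroupCompare(imm, bundle$samples$group)
  log$immune <- list(n_types = ncol(imm),
                     n_significant = sum(cmp$p < 0.05, na.rm = TRUE))
  # brain-immune correlation (cases)
  isCase <- bundle$samples$group == "case"
  spear <- if (all(is.finite(clusterMean[seq_len(sum(isCase))]))) {
    scoreMapCorrelation(clusterMean[seq_len(length(malffCase))],
                        imm[isCase, , drop = FALSE])
  } else NULL
  vox <- NULL
  if (voxelwiseImmune) {
    vox <- scoreVoxelCorrelation(malffCase, imm[isCase, "Monocyte"], parc,
                                 voxelP = config$clinical_voxel_p,
                                 clusterP = config$cluster_p,
                                 minVoxels = config$min_voxels)
    log$voxelwise_immune <- list(n_rois = nrow(vox$rois))
  }
  files <- list(
    clusters = .emit(outDir, "contrast_clusters.tsv",
                     function(p) writeTSV(clusterTable(cl), p)),
    rois = .emit(outDir, "contrast_rois.tsv", function(p) writeTSV(rois, p)),
    de = .emit(outDir, "de_table.tsv", function(p) writeTSV(de, p)),
    up = .emit(outDir, "de_up.txt", function(p) writeLines(deLists$up, p)),
    down = .emit(outDir, "de_down.txt", function(p) writeLines(deLists$down, p)),
    immune = .emit(outDir, "immune_scores.tsv", function(p)
      writeTSV(data.frame(sample = rownames(imm), imm, check.names = FALSE), p)),
    cmp = .emit(outDir, "immune_group_tests.tsv", function(p) writeTSV(cmp, p)),
    spear = if (!is.null(spear)) .emit(outDir, "alff_immune_spearman.tsv",
                                       function(p) writeTSV(spear, p)))
  man <- .manifest(outDir, files, config, log)
  list(statMap = sm, clusters = cl, rois = rois, clusterMean = clusterMean,
       de = de, deLists = deLists, immune = imm, immuneCompare = cmp,
       spearman = spear, voxelwiseImmune = vox, log = log, manifest = man)
}
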