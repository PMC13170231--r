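# Generators: determinism, planted structure, error contracts.

test_that("parcellation partitions the grid with hemisphere labels", {
  parc <- synthParcellation(c(10, 8, 6), 11)
  lab <- parcelLabels(parc)
  expect_true(all(lab != 0L))
  expect_identical(sort(unique(as.vector(lab))), 1:11)
  regs <- regionTable(parc)
  xmm <- (seq_len(10) - 5.5) * 3
  for (r in regs$id) {
    xs <- xmm[arrayInd(which(lab == r), dim(lab))[, 1]]
    expect_true(all(sign(xs) == if (regs$hemisphere[r] == "L") -1 else 1))
  }
  expect_error(synthParcellation(c(2, 2, 1), 24), "too small")
})

test_that("the cohort generator is deterministic and respects error contracts", {
  a <- synthCohort(3, c(8, 6, 4), 4, nTimepoints = 80, seed = 42)
  b <- synthCohort(3, c(8, 6, 4), 4, nTimepoints = 80, seed = 42)
  expect_identical(a$subjects[[2]]@data, b$subjects[[2]]@data)
  expect_error(synthCohort(3, c(8, 6, 4), 4, trSeconds = 7), "Nyquist")
  expect_error(synthCohort(3, c(8, 6, 4), 4,
                           effectSpec = c("99" = 2)), "unknown region")
})

test_that("noise-free regional amplitudes map linearly to downstream ALFF", {
  co <- synthCohort(1, c(8, 6, 4), 4, nTimepoints = 128, noiseSd = 0,
                    effectSpec = c("1" = 1, "2" = 2, "3" = 1, "4" = 1), seed = 3)
  # exact-bin sinusoids, no noise, no trend: amplitude linearity is exact
  alff <- computeALFF(co$subjects[[1]], detrend = FALSE)
  rm <- regionalMeans(alff, co$parcellation)
  expect_equal(unname(rm["2"] / rm["1"]), 2, tolerance = 1e-9)
  expect_equal(unname(rm["3"] / rm["1"]), 1, tolerance = 1e-9)
  # direct FFT oracle on one voxel of region 2 vs region 1
  lab <- parcelLabels(co$parcellation)
  oneAmp <- function(r) {
    v <- arrayInd(which(lab == r)[1], dim(lab))
    x <- co$subjects[[1]]@data[v[1], v[2], v[3], ]
    n <- length(x); fr <- seq_len(n %/% 2) / (n * 2)
    mean((2 / n) * Mod(fft(x)[1 + which(fr >= 0.01 & fr <= 0.08)]))
  }
  expect_equal(oneAmp(2) / oneAmp(1), 2, tolerance = 1e-9)
  # uniform amplitudes, no noise: identical regional ALFF everywhere
  u <- synthCohort(1, c(8, 6, 4), 4, nTimepoints = 128, noiseSd = 0, seed = 3)
  ru <- regionalMeans(computeALFF(u$subjects[[1]], detrend = FALSE),
                      u$parcellation)
  expect_lt(diff(range(ru)), 1e-9)
})

test_that("clinical table: couplings, null indicators, CAS range, errors", {
  co <- synthCohort(40, c(8, 6, 4), 4, nTimepoints = 80, subjectJitterSd = 0.3,
                    seed = 5)
  clin <- synthClinicalTable(co, list(
    coupled = list(region = 2, slope = 4, noiseSd = 0),
    nullind = list(region = 2, slope = 0, noiseSd = 1),
    cas = list(region = 2, slope = 3, noiseSd = 0.5, offset = 1,
               integer0to7 = TRUE)), seed = 6)
  amp <- co$groundTruth$subjectAmplitude[, "2"]
  expect_equal(cor(clin$coupled, amp), 1, tolerance = 1e-12)
  expect_lt(abs(cor(clin$nullind, amp)), 0.45)
  expect_true(all(clin$cas >= 0 & clin$cas <= 7 & clin$cas == round(clin$cas)))
  expect_error(synthClinicalTable(co, list(x = list(region = 99, slope = 1,
                                                    noiseSd = 1))), "unknown region")
})

test_that("donor bundles: planted bad probes, exact-fraction flagging, coupling", {
  parc <- synthParcellation(c(10, 8, 6), 8)
  pat <- setNames(seq(0.8, 1.6, length.out = 8), 1:8)
  d <- synthDonorExpression(parc, pat, nGenes = 120, nPlanted = 10,
                            badProbeFraction = 0.2, seed = 9)
  f <- filterProbes(d$bundle)
  flagged <- setdiff(d$bundle@probes$probe_id, f@probes$probe_id)
  expect_setequal(flagged, d$groundTruth$badProbes)
  expect_equal(length(flagged) / nrow(d$bundle@probes), 0.2, tolerance = 0.01)
  # planted genes track the pattern in expectation
  prof <- d$groundTruth$geneProfiles[d$groundTruth$plantedGenes, ]
  rr <- apply(prof, 1, cor, y = pat)
  expect_gt(mean(rr), 0.8)
  expect_warning(synthDonorExpression(parc, pat, nGenes = 20, nPlanted = 2,
                                      samplesPerDonor = 4, seed = 1),
                 "lack samples")
})

test_that("noise-free unit-coupling donors give perfect downstream correlation", {
  parc <- synthParcellation(c(10, 8, 6), 8)
  pat <- setNames(seq(0.8, 1.6, length.out = 8), 1:8)
  d <- synthDonorExpression(parc, pat, nGenes = 60, nPlanted = 6,
                            probesPerGene = 1, badProbeFraction = 0,
                            couplingR = 1, sampleNoiseSd = 0, seed = 11)
  f <- filterProbes(d$bundle)
  asg <- assignSamples(f, parc)
  sel <- selectProbesByDS(f, asg)
  rex <- buildRegionalMatrix(f, sel, asg)
  as <- correlateGeneMaps(pat, rex)
  rpl <- as$r[as$gene %in% d$groundTruth$plantedGenes]
  expect_true(all(rpl > 0.999))
})

test_that("count generator: determinism, planted fold changes, signature guardrail", {
  a <- synthCountsAndSignatures(nGenes = 200, nPerGroup = c(case = 6, control = 6),
                                plantedDE = c(B0001 = 2), seed = 12)
  b <- synthCountsAndSignatures(nGenes = 200, nPerGroup = c(case = 6, control = 6),
                                plantedDE = c(B0001 = 2), seed = 12)
  expect_identical(a$counts, b$counts)
  expect_error(synthCountsAndSignatures(nGenes = 50, plantedDE = c(ZZZ = 1)),
               "absent from universe")
  expect_error(synthCountsAndSignatures(nGenes = 50,
                                        signatureSets = list(s = "nope"),
                                        signatureShifts = c(s = 1)),
               "absent from universe")
  big <- synthCountsAndSignatures(nGenes = 500,
                                  nPerGroup = c(case = 40, control = 40),
                                  plantedDE = c(B0010 = 2), dispersion = 0.05,
                                  seed = 13)
  lc <- logCPM(big$counts)
  lfc <- rowMeans(lc[, big$samples$group == "case"]) -
    rowMeans(lc[, big$samples$group == "control"])
  expect_equal(unname(lfc["B0010"]), 2, tolerance = 0.35)
})

test_that("ppi generator plants the module and is deterministic", {
  a <- synthPpiGraph(seed = 14)
  b <- synthPpiGraph(seed = 14)
  expect_identical(a$edges, b$edges)
  g <- interactionGraph(a$edges)
  mod <- a$groundTruth$moduleNodes
  sub <- igraph::induced_subgraph(g, mod)
  expect_equal(igraph::ecount(sub), choose(length(mod), 2))  # clique at p = 1
  expect_error(synthPpiGraph(backgroundEdgeP = 0.5, moduleEdgeP = 0.3), "module")
})

test_that("smooth null fields have ~unit variance and are seed-reproducible", {
  f1 <- synthSmoothField(c(16, 16, 16), c(2, 2, 2), seed = 15)
  f2 <- synthSmoothField(c(16, 16, 16), c(2, 2, 2), seed = 15)
  expect_identical(mapData(f1), mapData(f2))
  v <- mean(vapply(1:20, function(s)
    var(inMask(synthSmoothField(c(16, 16, 16), c(2, 2, 2), seed = s))), numeric(1)))
  expect_equal(v, 1, tolerance = 0.1)
})

test_that("regional association instances carry the planted coupling", {
  inst <- synthRegionalAssoc(nRegions = 60, nGenes = 300, nPlanted = 30,
                             couplingR = 0.9, seed = 16)
  rr <- cor(inst$alff, inst$expr[, inst$planted])
  expect_equal(mean(rr), 0.9, tolerance = 0.05)
})
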