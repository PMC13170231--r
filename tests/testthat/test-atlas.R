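# Probe filtering, sample assignment geometry, robust sigmoid, differential
# stability, regional aggregation.

mkBundle <- function(expr, geneIds, donors, coords, background = NULL) {
  np <- nrow(expr)
  DonorBundle(expr,
              data.frame(probe_id = sprintf("p%02d", seq_len(np)),
                         gene_id = geneIds,
                         symbol = ifelse(is.na(geneIds), NA,
                                         sprintf("G%02d", geneIds)),
                         stringsAsFactors = FALSE),
              data.frame(donor = donors, x = coords[, 1], y = coords[, 2],
                         z = coords[, 3], stringsAsFactors = FALSE),
              background = background)
}

test_that("probe filter: invalid ids, inclusive 50% low rule, exact planted fraction", {
  co <- matrix(0, 4, 3)
  expr <- rbind(rep(10, 4),          # good
                c(1, 1, 10, 10),     # low in exactly 50% -> removed (inclusive)
                c(1, 10, 10, 10),    # low in 25% -> kept
                rep(10, 4))          # invalid id
  b <- mkBundle(expr, c(1L, 2L, 3L, NA), rep("d1", 4), matrix(0, 4, 3),
                background = 5)
  f <- filterProbes(b)
  expect_setequal(f@probes$probe_id, c("p01", "p03"))
  cnt <- attr(f, "filter_counts")
  expect_identical(unname(cnt["invalid_id"] + cnt["low_intensity"]), 2L)
  allLow <- mkBundle(matrix(1, 2, 3), c(1L, 2L), rep("d1", 3), matrix(0, 3, 3),
                     background = 5)
  expect_error(filterProbes(allLow), "all probes")
})

test_that("empty-string gene ids are invalid", {
  b <- mkBundle(matrix(10, 2, 3), c(1L, 2L), rep("d1", 3), matrix(0, 3, 3),
                background = 5)
  b@probes$gene_id <- c("", "7")
  f <- filterProbes(b)
  expect_identical(f@probes$probe_id, "p02")
})

test_that("sample assignment: containment, 2 mm tolerance, hemisphere constraint", {
  # grid 6x2x2, voxel 3 mm; x centers at -7.5 -4.5 -1.5 1.5 4.5 7.5
  lab <- array(0L, c(6, 2, 2))
  lab[1:2, , ] <- 1L           # left parcel, x in [-9, -3]
  lab[5:6, , ] <- 2L           # right parcel, x in [3, 9]
  parc <- Parcellation(lab, regions = data.frame(
    id = 1:2, name = c("l", "r"), hemisphere = c("L", "R")))
  coords <- rbind(
    c(-4.5, -1.5, -1.5),  # at a left voxel center -> parcel 1
    c(-2.8, -1.5, -1.5),  # 1.7 mm from nearest labelled voxel, hem L -> 1
    c(5.6, 1.5, 1.5),     # inside right parcel -> 2
    c(-0.4, -1.5, -1.5),  # > 2 mm from any labelled voxel -> unassigned
    c(2.6, 1.5, 1.5),     # 1.9 mm from right parcel voxel, hem R -> 2
    c(-2.0, -1.5, -1.5))  # 2.5 mm away -> excluded
  b <- mkBundle(matrix(10, 1, 6), 1L, rep("d1", 6), coords, background = 5)
  asg <- assignSamples(b, parc, maxDistMM = 2)
  expect_identical(asg[1:3], c(1L, 1L, 2L))
  expect_true(is.na(asg[4]))
  expect_identical(asg[5], 2L)
  expect_true(is.na(asg[6]))
  # hemisphere mismatch: sample at x > 0 near a left parcel is excluded
  lab2 <- array(0L, c(6, 2, 2)); lab2[3, , ] <- 1L  # parcel at x [-3, 0]
  parc2 <- Parcellation(lab2, regions = data.frame(
    id = 1, name = "l", hemisphere = "L"))
  b2 <- mkBundle(matrix(10, 1, 1), 1L, "d1", rbind(c(0.5, -1.5, -1.5)),
                 background = 5)
  expect_true(is.na(assignSamples(b2, parc2, maxDistMM = 2)))
  # same point is fine for a midline ("M") parcel
  parc3 <- Parcellation(lab2, regions = data.frame(
    id = 1, name = "m", hemisphere = "M"))
  expect_identical(assignSamples(b2, parc3, maxDistMM = 2), 1L)
})

test_that("robust sigmoid: midpoint, hand value, monotonicity, fallbacks", {
  x <- c(0, 1, 2, 3, 4)
  y <- robustSigmoid(x, rescale = FALSE)
  expect_equal(y[3], 0.5)                       # x = median -> 0.5
  expect_equal(y[4], 1 / (1 + exp(-(3 - 2) / (2 / 1.35))), tolerance = 1e-12)
  expect_true(all(diff(y) > 0))                 # order preserved
  r <- robustSigmoid(x)
  expect_equal(range(r), c(0, 1))
  expect_true(all(order(r) == order(x)))
  # IQR 0 -> sd fallback still monotone
  z <- robustSigmoid(c(5, 5, 5, 5, 9), rescale = FALSE)
  expect_true(z[5] > z[1])
  expect_true(all(is.na(robustSigmoid(rep(3, 4)))))
})

test_that("differential stability: identical donors give DS = 1, noisy copies lose", {
  parc <- synthParcellation(c(10, 8, 6), 8)
  pat <- setNames(seq(1, 2, length.out = 8), 1:8)
  d <- synthDonorExpression(parc, pat, nGenes = 40, nPlanted = 5,
                            probesPerGene = 2, badProbeFraction = 0,
                            sampleNoiseSd = 0.3, probeNoiseSd = 1.2, seed = 21)
  f <- filterProbes(d$bundle)
  asg <- assignSamples(f, parc)
  sel <- selectProbesByDS(f, asg)
  expect_gt(mean(grepl("_p1$", sel$probe_id)), 0.85)  # signal probe wins
  # two identical donors: every probe has DS exactly 1
  oneDonor <- matrix(rnorm(8), 2, 4)          # 2 probes x 4 region samples
  expr <- cbind(oneDonor, oneDonor)
  lab <- array(0L, c(4, 1, 1)); lab[, 1, 1] <- 1:4
  parc2 <- Parcellation(lab, regions = data.frame(
    id = 1:4, name = paste0("r", 1:4), hemisphere = "L"))
  xs <- (rep(1:4, 2) - 2.5) * 3
  b <- mkBundle(expr, 1:2, rep(c("d1", "d2"), each = 4),
                cbind(xs, 0, 0), background = -99)
  sel2 <- selectProbesByDS(b, assignSamples(b, parc2))
  expect_true(all(abs(sel2$ds - 1) < 1e-12))
})

test_that("DS selection equals the exhaustive pairwise-correlation oracle", {
  set.seed(31)
  for (rep in 1:5) {
    nd <- sample(2:4, 1); nr <- sample(5:12, 1); np <- 6
    profiles <- lapply(seq_len(nd), function(d)
      matrix(rnorm(np * nr), np, nr,
             dimnames = list(sprintf("p%02d", 1:np), seq_len(nr))))
    # feed equivalent data through the package path: one sample per region
    donors <- rep(sprintf("d%d", seq_len(nd)), each = nr)
    regByS <- rep(seq_len(nr), nd)
    expr <- do.call(cbind, profiles)
    lab <- array(0L, c(nr, 1, 1)); lab[, 1, 1] <- seq_len(nr)
    parc <- Parcellation(lab, regions = data.frame(
      id = seq_len(nr), name = paste0("r", seq_len(nr)), hemisphere = "L"))
    xs <- (regByS - (nr + 1) / 2) * 3
    b <- DonorBundle(expr,
                     data.frame(probe_id = rownames(profiles[[1]]),
                                gene_id = seq_len(np), symbol = paste0("G", 1:np)),
                     data.frame(donor = donors, x = xs, y = 0, z = 0),
                     background = -99)
    asg <- assignSamples(b, parc)
    prof2 <- lapply(seq_len(nd), function(d) {
      cols <- donors == sprintf("d%d", d)
      ex <- t(apply(expr[, cols, drop = FALSE], 1, robustSigmoid))
      colnames(ex) <- regByS[cols]
      ex
    })
    sel <- selectProbesByDS(b, asg)
    dsOracleNorm <- bruteDS(prof2)
    expect_equal(sort(sel$ds), sort(dsOracleNorm[match(sel$probe_id,
                                                       rownames(profiles[[1]]))]),
                 tolerance = 1e-10)
  }
})

test_that("genes without 3 shared regions across any donor pair are dropped", {
  # two donors sampling disjoint region sets
  lab <- array(0L, c(8, 1, 1)); lab[, 1, 1] <- 1:8
  parc <- Parcellation(lab, regions = data.frame(
    id = 1:8, name = paste0("r", 1:8), hemisphere = "L"))
  xs <- (c(1:4, 5:8) - 4.5) * 3
  b <- DonorBundle(matrix(rnorm(16), 2, 8),
                   data.frame(probe_id = c("pa", "pb"), gene_id = 1:2,
                              symbol = c("GA", "GB")),
                   data.frame(donor = rep(c("d1", "d2"), each = 4),
                              x = xs, y = 0, z = 0), background = -99)
  asg <- assignSamples(b, parc)
  expect_error(suppressWarnings(selectProbesByDS(b, asg)), "no probe attained")
})

test_that("regional matrix: hand-averaged aggregation, exchangeability, z flag", {
  # 2 donors, 2 regions, 1 gene; sigmoid-normalized donor profiles averaged
  lab <- array(0L, c(4, 1, 1)); lab[, 1, 1] <- c(1L, 1L, 2L, 2L)
  parc <- Parcellation(lab, regions = data.frame(
    id = 1:2, name = c("a", "b"), hemisphere = "L"))
  xs <- (c(1, 2, 3, 4, 1, 2, 3, 4) - 2.5) * 3
  expr <- matrix(c(1, 2, 3, 4, 9, 8, 4, 2), 1, 8)
  b <- DonorBundle(expr,
                   data.frame(probe_id = "p1", gene_id = 1L, symbol = "G1"),
                   data.frame(donor = rep(c("d1", "d2"), each = 4),
                              x = xs, y = 0, z = 0), background = -99)
  asg <- assignSamples(b, parc)
  sel <- data.frame(gene_id = 1L, symbol = "G1", probe_id = "p1", ds = 1)
  rex <- buildRegionalMatrix(b, sel, asg)
  s1 <- robustSigmoid(c(1, 2, 3, 4)); s2 <- robustSigmoid(c(9, 8, 4, 2))
  byHand <- c((mean(s1[1:2]) + mean(s2[1:2])) / 2,
              (mean(s1[3:4]) + mean(s2[3:4])) / 2)
  expect_equal(unname(exprMatrix(rex)[, "G1"]), byHand, tolerance = 1e-12)
  # donor order must not matter
  ord <- c(5:8, 1:4)
  b2 <- DonorBundle(expr[, ord, drop = FALSE], b@probes,
                    b@samples[ord, ], background = -99)
  rex2 <- buildRegionalMatrix(b2, sel, assignSamples(b2, parc))
  expect_equal(exprMatrix(rex2), exprMatrix(rex), tolerance = 1e-12)
})

test_that("z-scored matrices have per-gene mean 0 sd 1 across present regions", {
  parc <- synthParcellation(c(10, 8, 6), 8)
  pat <- setNames(seq(1, 2, length.out = 8), 1:8)
  d <- synthDonorExpression(parc, pat, nGenes = 30, nPlanted = 3, seed = 41)
  f <- filterProbes(d$bundle)
  asg <- assignSamples(f, parc)
  rex <- buildRegionalMatrix(f, selectProbesByDS(f, asg), asg, zscore = TRUE)
  M <- exprMatrix(rex)
  expect_lt(max(abs(colMeans(M, na.rm = TRUE))), 1e-10)
  expect_lt(max(abs(apply(M, 2, sd, na.rm = TRUE) - 1)), 1e-10)
  expect_identical(exprState(rex), "z")
})
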