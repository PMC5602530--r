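test_that("hematoma segmentation removes the blooming margin using FLAIR", {
  case <- smallCase(1)
  br <- brainMask(case)
  truthIPH <- truthMask(case, "iph")
  refined <- segmentIPH(case@volumes$T2STAR, case@volumes$FLAIR, br)
  raw <- segmentIPH(case@volumes$T2STAR, case@volumes$FLAIR, br,
                    refineWithFLAIR = FALSE)
  expect_gt(diceCoefficient(refined, truthIPH), 0.80)
  ## refined volume within 10% of truth; unrefined keeps the ~20% blooming
  expect_lt(abs(nVoxels(refined) - nVoxels(truthIPH)) / nVoxels(truthIPH),
            0.10)
  expect_gt(nVoxels(raw) / nVoxels(truthIPH), 1.15)
})

test_that("a featureless T2* yields an empty flagged hematoma mask", {
  dims <- c(16L, 16L, 8L)
  br <- maskFromIndices(seq_len(prod(dims)), dims, label = "BRAIN")
  flat <- flatVolume(100, dims, modality = "T2STAR")
  fl <- flatVolume(100, dims, modality = "FLAIR")
  m <- segmentIPH(flat, fl, br)
  expect_equal(nVoxels(m), 0)
  expect_equal(maskNote(m), "empty")
})

test_that("lesion segmentation recovers hematoma plus edema and contains the IPH", {
  for (s in 1:3) {
    case <- smallCase(s)
    seg <- smallSegmented(s)
    expect_gt(diceCoefficient(seg$masks$LESION, truthMask(case, "lesion")),
              0.80)
    expect_true(all(maskValues(seg$masks$IPH) <= maskValues(seg$masks$LESION)))
    expect_gt(diceCoefficient(seg$masks$PHE, truthMask(case, "phe")), 0.75)
  }
})

test_that("without edema the lesion collapses to the hematoma and is flagged", {
  spec <- smallSpec(pheThickness = 0, pdrPresent = FALSE)
  case <- makePhantom(spec, 2)
  br <- brainMask(case)
  iph <- segmentIPH(case@volumes$T2STAR, case@volumes$FLAIR, br)
  lesion <- segmentLesion(case@volumes$FLAIR, iph, br)
  expect_identical(maskValues(lesion), maskValues(iph))
  expect_equal(maskNote(lesion), "no_phe")
})

test_that("edema subtraction is exact set arithmetic", {
  dims <- c(16L, 16L, 8L)
  lesion <- maskFromIndices(1:500, dims, label = "LESION")
  iph <- maskFromIndices(1:200, dims, label = "IPH")
  phe <- derivePHE(lesion, iph)
  expect_equal(nVoxels(phe), 300)
  expect_false(any(maskValues(phe) & maskValues(iph)))
  ## lesion == iph -> empty edema
  expect_equal(nVoxels(derivePHE(iph, iph)), 0)
  ## iph not nested in lesion -> contract error
  bad <- maskFromIndices(400:600, dims, label = "IPH")
  expect_error(derivePHE(lesion, bad), "contract error")
})

test_that("mirror reflection uses first-axis index arithmetic", {
  dims <- c(64L, 24L, 12L)
  brain <- maskFromIndices(seq_len(prod(dims)), dims, label = "BRAIN")
  lesion <- RoiMask(array(FALSE, dims), c(1, 1, 1), "LESION")
  lv <- maskValues(lesion)
  lv[11, 21, 6] <- TRUE  # 0-based (10, 20, 5)
  lesion <- RoiMask(lv, c(1, 1, 1), "LESION")
  m <- mirrorRegion(lesion, brain, excludeDilation = 2L, minVoxels = 1L)
  expect_equal(which(maskValues(m), arr.ind = TRUE)[1, ],
               c(dim1 = 54, dim2 = 21, dim3 = 6))  # 0-based (53, 20, 5)
})

test_that("mirror adjustment removes lesion overlap and enforces a minimum size", {
  dims <- c(20L, 10L, 6L)
  brain <- maskFromIndices(seq_len(prod(dims)), dims, label = "BRAIN")
  ## lesion straddling the reflection: reflected voxels land inside the
  ## dilated lesion and must be excluded
  lv <- array(FALSE, dims)
  lv[9:12, 5, 3] <- TRUE
  lesion <- RoiMask(lv, c(1, 1, 1), "LESION")
  expect_error(mirrorRegion(lesion, brain, minVoxels = 1L), "mirror error")
  ## default phantom: the mirror lands entirely in contralateral background
  case <- smallCase(1)
  seg <- smallSegmented(1)
  expect_true(all(case@truth[maskValues(seg$masks$MIRROR)] == 1L))
  ## and never intersects the dilated lesion
  excl <- dilateMask(maskValues(seg$masks$LESION), 2L)
  expect_false(any(maskValues(seg$masks$MIRROR) & excl))
})

test_that("mirror statistics are the median and sample SD of the voxels", {
  dims <- c(4L, 4L, 1L)
  adc <- flatVolume(0, dims)
  av <- imgValues(adc); av[1:3] <- c(700, 750, 800)
  adc <- ImageVolume(av, c(1, 1, 1), "ADC")
  b <- flatVolume(100, dims, modality = "B1000")
  mirror <- maskFromIndices(1:3, dims, label = "MIRROR")
  ms <- computeMirrorStats(adc, b, mirror)
  expect_equal(ms@adcMedian, 750)
  expect_equal(ms@adcSD, 50)
  expect_equal(ms@b1000Median, 100)
  expect_equal(ms@b1000SD, 0)
  ## duplicating the median value leaves the median unchanged
  av[4] <- 750
  ms2 <- computeMirrorStats(ImageVolume(av, c(1, 1, 1), "ADC"), b,
                            maskFromIndices(1:4, dims, label = "MIRROR"))
  expect_equal(ms2@adcMedian, 750)
  expect_error(computeMirrorStats(adc, b,
                                  maskFromIndices(integer(0), dims,
                                                  label = "MIRROR")),
               "empty")
})

test_that("rim detection applies the mirror-referenced threshold arithmetic", {
  ## mirror median 800, SD 60 -> ADC cutoff 710; a candidate voxel at 624.5
  ## with hyperintense b1000 must be captured
  dims <- c(10L, 10L, 4L)
  av <- array(800, dims); bv <- array(100, dims)
  av[5, 5, 2] <- 624.5; bv[5, 5, 2] <- 140
  adc <- ImageVolume(av, c(1, 1, 1), "ADC")
  b1000 <- ImageVolume(bv, c(1, 1, 1), "B1000")
  phe <- maskFromIndices(seq_len(prod(dims)), dims, label = "PHE")
  ms <- new("MirrorStats", adcMedian = 800, adcSD = 60, b1000Median = 100,
            b1000SD = 10, nVoxels = 100L)
  pdr <- detectPDR(adc, b1000, phe, ms, minComponentCC = 0)
  expect_equal(attr(pdr, "adcCutoff"), 710)
  expect_true(maskValues(pdr)[5, 5, 2])
  expect_equal(nVoxels(pdr), 1)
  ## inclusive threshold: a voxel exactly at the cutoff is retained
  av[2, 2, 2] <- 710; bv[2, 2, 2] <- 115
  pdr2 <- detectPDR(ImageVolume(av, c(1, 1, 1), "ADC"),
                    ImageVolume(bv, c(1, 1, 1), "B1000"), phe, ms,
                    minComponentCC = 0)
  expect_true(maskValues(pdr2)[2, 2, 2])
})

test_that("phantom rim detection is accurate, confined and rim-specific", {
  for (s in 1:3) {
    case <- smallCase(s)
    seg <- smallSegmented(s)
    expect_gt(diceCoefficient(seg$masks$PDR, truthMask(case, "pdr")), 0.70)
    ## the rim never intersects the hematoma and stays in the candidate zone
    expect_false(any(maskValues(seg$masks$PDR) & maskValues(seg$masks$IPH)))
    lesion <- maskValues(seg$masks$IPH) | maskValues(seg$masks$PHE)
    candidate <- maskValues(seg$masks$PHE) | (dilateMask(lesion, 2L) & !lesion)
    expect_true(all(candidate[maskValues(seg$masks$PDR)]))
  }
  ## rim-absent phantom -> empty mask, negative call
  segNeg <- smallSegmented(4, pdrPresent = FALSE)
  expect_equal(nVoxels(segNeg$masks$PDR), 0)
  expect_false(segNeg$status$positive)
})

test_that("detected rim volume is monotone non-increasing in the ADC factor", {
  case <- smallCase(2)
  seg <- smallSegmented(2)
  vols <- vapply(c(1.0, 1.5, 2.0, 3.0), function(f) {
    pdr <- detectPDR(case@volumes$ADC, case@volumes$B1000, seg$masks$PHE,
                     seg$mirrorStats, iph = seg$masks$IPH,
                     brain = brainMask(case), adcSDFactor = f)
    nVoxels(pdr)
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("detected rim is not FLAIR-hyperintense", {
  case <- smallCase(1)
  seg <- smallSegmented(1)
  fl <- case@volumes$FLAIR@values
  brainVals <- fl[maskValues(brainMask(case))]
  lesionThreshold <- median(brainVals) + 2 * sd(brainVals)
  expect_lt(median(fl[maskValues(seg$masks$PDR)]), lesionThreshold)
})

test_that("positivity classification uses the inclusive volume cutoff", {
  dims <- c(20L, 20L, 10L)
  ## 1.98 cc at 1 mm voxels = 1980 voxels -> positive
  m <- maskFromIndices(1:1980, dims, label = "PDR")
  st <- classifyPDRStatus(m)
  expect_true(st$positive)
  expect_equal(st$volumeCC, 1.98)
  ## empty -> negative, 0 cc
  st0 <- classifyPDRStatus(maskFromIndices(integer(0), dims, label = "PDR"))
  expect_false(st0$positive)
  expect_equal(st0$volumeCC, 0)
  ## exactly at the cutoff -> positive
  st1 <- classifyPDRStatus(maskFromIndices(1:100, dims, label = "PDR"))
  expect_true(st1$positive)
  expect_equal(st1$volumeCC, 0.1)
})
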