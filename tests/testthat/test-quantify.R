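test_that("ROI volume is voxel count times voxel volume", {
  expect_equal(roiVolumeCC(maskFromIndices(1:1000, c(10L, 10L, 10L),
                                           spacing = c(1, 1, 1),
                                           label = "IPH")), 1.0)
  expect_equal(roiVolumeCC(maskFromIndices(integer(0), c(10L, 10L, 10L),
                                           label = "IPH")), 0.0)
  ## anisotropic voxels with slice spacing: 100 x (0.9 * 0.9 * 6.5) mm^3
  m <- maskFromIndices(1:100, c(10L, 10L, 10L), spacing = c(0.9, 0.9, 6.5),
                       label = "PHE")
  expect_equal(roiVolumeCC(m), 0.5265)
})

test_that("ROI ADC statistics use linear-interpolation quantiles", {
  dims <- c(4L, 1L, 1L)
  adc <- ImageVolume(array(c(1, 2, 3, 4), dims), c(1, 1, 1), "ADC")
  s <- roiADCStats(adc, maskFromIndices(1:4, dims, label = "IPH"))
  expect_equal(s$median, 2.5)
  expect_equal(s$p25, 1.75)
  expect_equal(s$p75, 3.25)
  expect_equal(s$mean, 2.5)
  ## constant region: all order statistics coincide
  adc2 <- ImageVolume(array(789, dims), c(1, 1, 1), "ADC")
  s2 <- roiADCStats(adc2, maskFromIndices(1:4, dims, label = "IPH"))
  expect_equal(unlist(s2[c("p25", "mean", "median", "p75")]),
               c(p25 = 789, mean = 789, median = 789, p75 = 789))
  expect_error(roiADCStats(adc, maskFromIndices(integer(0), dims,
                                                label = "IPH")), "empty")
})

test_that("quantile sandwich p25 <= median <= p75 holds on random ROIs", {
  set.seed(11)
  dims <- c(8L, 8L, 4L)
  for (i in 1:10) {
    adc <- ImageVolume(array(abs(rnorm(prod(dims), 800, 150)), dims),
                       c(1, 1, 1), "ADC")
    idx <- sample(prod(dims), 40)
    s <- roiADCStats(adc, maskFromIndices(idx, dims, label = "PHE"))
    expect_lte(s$p25, s$median)
    expect_lte(s$median, s$p75)
  }
})

test_that("relative ADC is the ratio to the mirror median", {
  expect_equal(relativeADC(1030, 1030), 1.0)
  expect_equal(relativeADC(624.5, 750), 0.8327, tolerance = 1e-4)
  expect_error(relativeADC(700, 0), "mirror median")
  expect_error(relativeADC(700, -5), "mirror median")
})

test_that("phantom quantification orders compartments and is deterministic", {
  case <- smallCase(1)
  masks <- list(IPH = truthMask(case, "iph"), PHE = truthMask(case, "phe"),
                PDR = truthMask(case, "pdr"))
  seg <- smallSegmented(1)
  q1 <- quantifyCase(case@volumes, masks, seg$mirrorStats)
  q2 <- quantifyCase(case@volumes, masks, seg$mirrorStats)
  expect_identical(q1, q2)
  expect_lt(q1@roiStats$PDR$median, q1@roiStats$IPH$median)
  expect_lt(q1@roiStats$IPH$median, q1@roiStats$PHE$median)
  ## hematoma median within the expected interquartile band
  expect_gt(q1@roiStats$IPH$median, 710)
  expect_lt(q1@roiStats$IPH$median, 890)
})

test_that("volume additivity: lesion = hematoma + edema exactly", {
  seg <- smallSegmented(2)
  expect_equal(roiVolumeCC(seg$masks$LESION),
               roiVolumeCC(seg$masks$IPH) + roiVolumeCC(seg$masks$PHE))
})

test_that("a negative rim yields zeroed, flagged PDR entries", {
  case <- makePhantom(smallSpec(pdrPresent = FALSE), 3)
  seg <- smallSegmented(3, pdrPresent = FALSE)
  masks <- list(IPH = seg$masks$IPH, PHE = seg$masks$PHE, PDR = seg$masks$PDR)
  q <- quantifyCase(case@volumes, masks, seg$mirrorStats)
  expect_false(q@pdrPositive)
  expect_equal(q@note, "pdr_absent")
  expect_equal(q@roiStats$PDR$volumeCC, 0)
  expect_true(is.na(q@rADC[["PDR"]]))
})

test_that("rADC is invariant under rescaling of the ADC map", {
  case <- smallCase(1)
  seg <- smallSegmented(1)
  masks <- list(IPH = seg$masks$IPH, PHE = seg$masks$PHE, PDR = seg$masks$PDR)
  q1 <- quantifyCase(case@volumes, masks, seg$mirrorStats)
  scaled <- case@volumes
  scaled$ADC <- ImageVolume(scaled$ADC@values * 3, scaled$ADC@spacing, "ADC")
  msScaled <- new("MirrorStats", adcMedian = seg$mirrorStats@adcMedian * 3,
                  adcSD = seg$mirrorStats@adcSD * 3,
                  b1000Median = seg$mirrorStats@b1000Median,
                  b1000SD = seg$mirrorStats@b1000SD,
                  nVoxels = seg$mirrorStats@nVoxels)
  q3 <- quantifyCase(scaled, masks, msScaled)
  expect_equal(q1@rADC, q3@rADC, tolerance = 1e-12)
})
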