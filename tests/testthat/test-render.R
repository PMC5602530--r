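test_that("split-normal draws reproduce the requested median and quartiles", {
  set.seed(42)
  x <- rSplitNormal(2e5, 624.5, 598.5, 670)
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
  expect_equal(unname(q[2]), 624.5, tolerance = 2e-3)
  expect_equal(unname(q[1]), 598.5, tolerance = 2e-3)
  expect_equal(unname(q[3]), 670, tolerance = 2e-3)
  ## degenerate IQR collapses to the median with probability one
  expect_true(all(rSplitNormal(100, 700, 700, 700) == 700))
})

test_that("zero noise and degenerate IQR render the median exactly", {
  comps <- defaultCompartments()
  comps$IPH@adcIQR <- c(789, 789)
  spec <- smallSpec(compartments = comps,
                    noiseSD = c(FLAIR = 0, B1000 = 0, ADC = 0, T2STAR = 0))
  truth <- buildGeometry(spec)
  vols <- renderModalities(truth, spec, seed = 1)
  expect_true(all(vols$ADC@values[truth == 2L] == 789))
})

test_that("rendering is seed-deterministic and seed-sensitive", {
  spec <- smallSpec()
  truth <- buildGeometry(spec)
  a <- renderModalities(truth, spec, seed = 9)
  b <- renderModalities(truth, spec, seed = 9)
  expect_identical(lapply(a, imgValues), lapply(b, imgValues))
  c2 <- renderModalities(truth, spec, seed = 10)
  expect_false(identical(a$ADC@values, c2$ADC@values))
})

test_that("modality contrasts follow the lesion anatomy", {
  case <- smallCase(3)
  truth <- case@truth
  fl <- case@volumes$FLAIR@values
  b1 <- case@volumes$B1000@values
  bg <- truth == 1L
  ## FLAIR hyperintense over hematoma and edema, not over the rim
  expect_gt(median(fl[truth == 2L]), median(fl[bg]) + 30)
  expect_gt(median(fl[truth == 3L]), median(fl[bg]) + 30)
  expect_lt(abs(median(fl[truth == 4L]) - median(fl[bg])), 10)
  ## b1000 hyperintense over the rim only
  expect_gt(median(b1[truth == 4L]), median(b1[bg]) + 30)
  expect_lt(abs(median(b1[truth == 3L]) - median(b1[bg])), 10)
})

test_that("T2* clot hypointensity is inflated by the blooming fraction", {
  spec <- smallSpec(noiseSD = c(FLAIR = 0, B1000 = 0, ADC = 0, T2STAR = 0))
  truth <- buildGeometry(spec)
  vols <- renderModalities(truth, spec, seed = 1)
  hypo <- vols$T2STAR@values < 70 & truth > 0L
  ratio <- sum(hypo) / sum(truth == 2L)
  expect_gt(ratio, 1.10)
  expect_lt(ratio, 1.30)
  ## blooming 0 leaves the clot footprint unchanged
  spec0 <- smallSpec(bloomingFraction = 0,
                     noiseSD = c(FLAIR = 0, B1000 = 0, ADC = 0, T2STAR = 0))
  vols0 <- renderModalities(truth, spec0, seed = 1)
  expect_equal(sum(vols0$T2STAR@values < 70 & truth > 0L), sum(truth == 2L))
})

test_that("compartment ADC medians are ordered PDR < IPH < PHE in every phantom", {
  for (s in 1:5) {
    case <- smallCase(s)
    adc <- case@volumes$ADC@values
    tr <- case@truth
    mPDR <- median(adc[tr == 4L])
    mIPH <- median(adc[tr == 2L])
    mPHE <- median(adc[tr == 3L])
    expect_lt(mPDR, mIPH)
    expect_lt(mIPH, mPHE)
  }
})

test_that("pooled compartment medians recover the generator parameters", {
  ## parameter-recovery invariant: pooled sample median over 20 phantoms
  ## within 2.5% of the specified compartment median
  spec <- smallSpec()
  vals <- list(pdr = c(), iph = c(), phe = c(), bg = c())
  for (s in 1:20) {
    truth <- buildGeometry(spec)
    adc <- renderModalities(truth, spec, seed = 100 + s)$ADC@values
    vals$pdr <- c(vals$pdr, adc[truth == 4L])
    vals$iph <- c(vals$iph, adc[truth == 2L])
    vals$phe <- c(vals$phe, adc[truth == 3L])
  }
  expect_lt(abs(median(vals$pdr) - 624.5) / 624.5, 0.025)
  expect_lt(abs(median(vals$iph) - 789) / 789, 0.025)
  expect_lt(abs(median(vals$phe) - 1030) / 1030, 0.025)
})
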