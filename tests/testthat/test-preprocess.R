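test_that("IFE correction: zero-absorbance identity and hand-derived factor", {
  e <- toyEEM(em = c(300, 310, 320), ex = c(250, 260),
    intensity = matrix(100, 3, 2))
  a0 <- AbsorbanceSpectrum(seq(200, 700, by = 10), rep(0, 51), sampleId = "toy")
  out0 <- ifeCorrect(e, a0)
  expect_equal(out0@intensity, e@intensity, ignore_attr = TRUE)

  # A(ex) = A(em) = 0.1 everywhere -> F_corr = 100 * 10^0.1 = 125.8925...
  a1 <- AbsorbanceSpectrum(seq(200, 700, by = 10), rep(0.1, 51), sampleId = "toy")
  out1 <- ifeCorrect(e, a1)
  expect_equal(out1@intensity[1, 1], 100 * 10^0.1, tolerance = 1e-12)
  expect_equal(unname(out1@intensity[3, 2]), 125.8925, tolerance = 1e-4)
  expect_equal(attr(out1@intensity, "ifeFactors")[2, 2], 10^0.1, tolerance = 1e-12)

  # masked cells pass through untouched
  em <- toyEEM(intensity = matrix(100, 3, 2),
    mask = matrix(c(TRUE, rep(FALSE, 5)), 3))
  outm <- ifeCorrect(em, a1)
  expect_true(is.na(outm@intensity[1, 1]))
})

test_that("IFE correction error and warning contracts", {
  e <- toyEEM()
  short <- AbsorbanceSpectrum(c(305, 315), c(0.1, 0.1), sampleId = "toy")
  expect_error(ifeCorrect(e, short), "cover")

  high <- AbsorbanceSpectrum(seq(200, 700, by = 10), rep(2.5, 51), sampleId = "toy")
  expect_warning(ifeCorrect(e, high), "2.0|optical density")
})

test_that("IFE correction recovers pre-attenuation truth from the generator", {
  cfg <- defaultSyntheticConfig(seed = 42)
  cfg$nDirect <- 3L; cfg$nProcessed <- 3L
  cfg$scatterOn <- FALSE
  cfg$noise$multFraction <- 0
  cfg$noise$addSd <- 1e-9
  sim <- simulateDataset(cfg)
  for (i in c(1, 4)) {
    corrected <- ifeCorrect(sim$replicates[[i]][[1]], sim$absorbance[[i]])
    expect_equal(corrected@intensity, sim$truth$cleanArray[i, , ],
      tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("removeRayleigh excises ridge cells and nothing else", {
  em <- seq(250, 330, by = 10)
  ex <- c(260, 300)
  base <- matrix(5, length(em), length(ex))
  ridge <- base
  ridge[abs(outer(em, ex, `-`)) <= 2] <- 1000 # cells exactly on the diagonal
  e <- toyEEM(em = em, ex = ex, intensity = ridge)
  out <- removeRayleigh(e, scatterSpec(order1Halfwidth = 10, order2Halfwidth = 15,
    fillPolicy = "zero"))
  band <- abs(outer(em, ex, `-`)) <= 10 | abs(outer(em, 2 * ex, `-`)) <= 15
  expect_true(all(out@intensity[band] == 0))
  expect_identical(out@intensity[!band], e@intensity[!band])
  expect_identical(attr(out@intensity, "nExcised"), sum(band))
  expect_true(all(out@intensity != 1000))
})

test_that("removeRayleigh is an identity off-band and idempotent", {
  # grid with no cell within either band
  e <- toyEEM(em = c(400, 410), ex = c(250, 260),
    intensity = matrix(1:4, 2))
  out <- removeRayleigh(e, scatterSpec())
  expect_equal(out@intensity, e@intensity, ignore_attr = TRUE)
  expect_identical(attr(out@intensity, "nExcised"), 0L)

  # idempotence with masking
  e2 <- toyEEM(em = seq(250, 330, by = 10), ex = c(260, 300),
    intensity = matrix(runif(18), 9))
  once <- removeRayleigh(e2, scatterSpec(fillPolicy = "mask"))
  twice <- removeRayleigh(once, scatterSpec(fillPolicy = "mask"))
  expect_equal(once@intensity, twice@intensity, ignore_attr = TRUE)
  expect_identical(once@mask, twice@mask)
})

test_that("removeRayleigh interpolate falls back to mask on all-excised columns", {
  # at ex = 310 with em 300-320 every emission point is within 10 nm
  e <- toyEEM(em = c(300, 310, 320), ex = c(310, 400),
    intensity = matrix(runif(6), 3))
  expect_warning(
    out <- removeRayleigh(e, scatterSpec(fillPolicy = "interpolate_emission")),
    "falling back to mask"
  )
  expect_true(all(is.na(out@intensity[, 1])))
  expect_true(all(out@mask[, 1]))

  # interpolation path: values filled from emission neighbours
  e2 <- toyEEM(em = seq(250, 350, by = 10), ex = c(300, 400),
    intensity = matrix(rep(seq(250, 350, by = 10), 2), ncol = 2)) # linear in em
  out2 <- removeRayleigh(e2, scatterSpec(fillPolicy = "interpolate_emission"))
  expect_equal(out2@intensity, e2@intensity, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("averageReplicates averages cell-wise and unions masks", {
  ints <- lapply(1:3, function(v) toyEEM(intensity = matrix(v, 3, 2)))
  avg <- averageReplicates(ints)
  expect_equal(avg@intensity, matrix(2, 3, 2), ignore_attr = TRUE)

  same <- averageReplicates(list(toyEEM(), toyEEM(), toyEEM()))
  expect_equal(same@intensity, toyEEM()@intensity, ignore_attr = TRUE)

  m1 <- matrix(FALSE, 3, 2); m1[1, 1] <- TRUE
  m2 <- matrix(FALSE, 3, 2); m2[2, 2] <- TRUE
  masked <- averageReplicates(list(
    toyEEM(mask = m1), toyEEM(mask = m2), toyEEM()
  ))
  expect_true(masked@mask[1, 1] && masked@mask[2, 2])
  expect_identical(sum(masked@mask), 2L)

  expect_error(
    averageReplicates(list(toyEEM(sampleId = "a"), toyEEM(sampleId = "b"))),
    "sample ids"
  )
  expect_error(
    averageReplicates(list(toyEEM(), toyEEM(em = c(301, 310, 320)))),
    "grid"
  )
})

test_that("replicate averaging reduces noise like 1/sqrt(3)", {
  set.seed(99)
  n <- 40 * 30
  reps <- lapply(1:3, function(r) {
    toyEEM(em = seq(300, 690, by = 10), ex = seq(250, 540, by = 10),
      intensity = matrix(rnorm(n, 100, 5), 40))
  })
  avg <- averageReplicates(reps)
  expect_equal(sd(avg@intensity), 5 / sqrt(3), tolerance = 0.1)
})

test_that("extractEmissionSlices concatenates, snaps and errors correctly", {
  cfg <- defaultSyntheticConfig(seed = 5)
  cfg$nDirect <- 2L; cfg$nProcessed <- 2L
  sim <- simulateDataset(cfg)
  ds <- suppressWarnings(
    preprocessSimulated(sim, scatterSpec(fillPolicy = "interpolate_emission"))
  )
  sl <- extractEmissionSlices(ds, c(275, 305, 365))
  expect_identical(dim(sl), c(4L, 192L)) # 3 x 64 emission points

  u <- unfoldDataset(ds)
  k <- which(ds@ex == 275)
  block <- u[, attr(u, "ex_nm") == 275]
  expect_equal(unname(sl[, 1:64]), unname(block))

  expect_message(extractEmissionSlices(ds, 276), "snapped")
  expect_error(extractEmissionSlices(ds, 250), "half a grid step")
})

test_that("preprocessSample applies the fixed order IFE -> scatter -> average", {
  cfg <- defaultSyntheticConfig(seed = 7)
  cfg$nDirect <- 2L; cfg$nProcessed <- 2L
  sim <- simulateDataset(cfg)
  manual <- averageReplicates(lapply(
    lapply(sim$replicates[[1]], ifeCorrect, absSpec = sim$absorbance[[1]]),
    removeRayleigh, spec = scatterSpec()
  ))
  auto <- preprocessSample(sim$replicates[[1]], sim$absorbance[[1]])
  expect_equal(auto@intensity, manual@intensity, ignore_attr = TRUE)
})
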