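test_that("default configuration encodes the study design", {
  cfg <- defaultSyntheticConfig()
  expect_identical(cfg$nDirect, 15L)
  expect_identical(cfg$nProcessed, 20L)
  expect_identical(cfg$nReplicates, 3L)
  expect_length(cfg$exGrid, 29L)
  expect_length(cfg$emGrid, 64L)
  expect_length(cfg$absGrid, 113L)
  expect_identical(range(cfg$exGrid), c(260, 400))
  expect_identical(range(cfg$emGrid), c(310, 600))
  expect_identical(range(cfg$absGrid), c(240, 800))

  fl3 <- cfg$fluorophores[[3]]
  expect_identical(fl3$exMaxima, 305)
  expect_identical(fl3$emMaximum, 425)
  expect_identical(cfg$concentrations$processed[[1]][1], 31983)
  expect_identical(cfg$concentrations$processed[[4]], c(8403, 5346))
  expect_identical(cfg$concentrations$direct[[4]], c(615, 418))
})

test_that("configuration validation rejects bad parameters", {
  bad <- defaultSyntheticConfig()
  bad$nDirect <- 1L
  expect_error(simulateDataset(bad), ">= 2 samples")

  bad2 <- defaultSyntheticConfig()
  bad2$fluorophores[[1]]$emWidth <- -1
  expect_error(simulateDataset(bad2), "widths")

  bad3 <- defaultSyntheticConfig()
  bad3$concentrations$direct[[2]][2] <- -5
  expect_error(simulateDataset(bad3), "sd")

  bad4 <- defaultSyntheticConfig()
  bad4$turbidity$processed[1] <- -0.1
  expect_error(simulateDataset(bad4), "turbidity")
})

test_that("a simulated study has the configured dimensions and is reproducible", {
  cfg <- defaultSyntheticConfig(seed = 11)
  sim <- simulateDataset(cfg)
  expect_length(sim$replicates, 35L)
  expect_length(sim$replicates[[1]], 3L)
  expect_identical(dim(sim$truth$cleanArray), c(35L, 64L, 29L))
  expect_identical(as.character(sim$labels),
    rep(c("direct", "processed"), c(15, 20)))
  expect_true(all(sim$truth$scores >= 0))
  expect_true(all(sim$truth$turbidity >= 0))
  expect_identical(sim$truth$scenarios[1:15], rep("none", 15))
  expect_true(all(sim$truth$scenarios[16:35] %in%
    c("none", "shift25", "decomposed")))

  ds <- suppressWarnings(preprocessSimulated(sim))
  expect_identical(dim(ds@array), c(35L, 64L, 29L))
  u <- unfoldDataset(ds)
  expect_identical(dim(u), c(35L, 1856L))

  sim2 <- simulateDataset(cfg)
  expect_identical(sim2$truth$scores, sim$truth$scores)
  expect_identical(sim2$replicates[[7]][[2]]@intensity,
    sim$replicates[[7]][[2]]@intensity)
  sim3 <- simulateDataset(defaultSyntheticConfig(seed = 12))
  expect_false(identical(sim3$truth$scores, sim$truth$scores))
})

test_that("truncated score draws match the configured moments", {
  # the config states the moments of the truncated distribution itself;
  # check the moment-matched parent reproduces them even under severe
  # truncation (direct comp 4: 615 +/- 418 has mass near zero)
  for (ms in list(c(615, 418), c(8403, 5346), c(26552, 10675))) {
    parent <- ateem:::.truncnormParent(ms[1], ms[2])
    set.seed(41)
    draws <- ateem:::.rtruncnorm0(1e5, parent)
    expect_true(all(draws >= 0))
    expect_equal(mean(draws), ms[1], tolerance = 0.02 * ms[1])
    expect_equal(sd(draws), ms[2], tolerance = 0.03 * ms[2])
  }
})

test_that("the clean signal is exactly trilinear", {
  cfg <- defaultSyntheticConfig(seed = 13)
  cfg$nDirect <- 4L; cfg$nProcessed <- 4L
  cfg$scatterOn <- FALSE
  cfg$ifeOn <- FALSE
  cfg$noise$multFraction <- 0
  cfg$noise$addSd <- 1e-9
  sim <- simulateDataset(cfg)
  X <- simplify2array(lapply(sim$replicates, function(r) r[[1]]@intensity))
  X <- aperm(X, c(3, 1, 2))
  m <- fitParafac(X, 4, nStarts = 4, seed = 14)
  expect_gte(m@fitPercent, 99.99)
  mt <- matchComponents(m,
    list(emLoadings = sim$truth$emProfiles, exLoadings = sim$truth$exProfiles))
  expect_true(all(mt$congruence > 0.999))
})

test_that("absorbance bands sit where the configuration says", {
  cfg <- defaultSyntheticConfig()
  aD <- simulateAbsorbance("direct", 0.35, cfg, seed = 15, turbidity = 0)
  g <- aD@wavelength
  uv <- g >= 240 & g <= 320
  expect_lte(abs(g[uv][which.max(aD@absorbance[uv])] - 265), 5)

  aP <- simulateAbsorbance("processed", 0.35, cfg, seed = 16,
    scenario = "none", turbidity = 0)
  expect_lte(abs(g[uv][which.max(aP@absorbance[uv])] - 275), 5)
  expect_identical(attr(simulateAbsorbance("direct", 0.3, cfg, seed = 17,
    turbidity = 0), "scenario"), "none")

  # no pigment, no turbidity, no browning: the visible region is flat
  a0 <- simulateAbsorbance("processed", 0, cfg, scenario = "none",
    uvAmplitude = 0.8, browningAmplitude = 0, turbidity = 0)
  vis <- g >= 420 & g <= 800
  expect_lt(max(a0@absorbance[vis]), 0.01)

  # shift25 moves the anthocyanin maximum to ~525 nm
  aS <- simulateAbsorbance("processed", 0.35, cfg, scenario = "shift25",
    uvAmplitude = 0.8, turbidity = 0)
  visBand <- g >= 420 & g <= 620
  expect_lte(abs(g[visBand][which.max(aS@absorbance[visBand])] - 525), 5)

  # decomposition reduces the band to the configured fraction
  aN <- simulateAbsorbance("processed", 0.35, cfg, scenario = "none",
    uvAmplitude = 0.8, turbidity = 0)
  aX <- simulateAbsorbance("processed", 0.35, cfg, scenario = "decomposed",
    uvAmplitude = 0.8, turbidity = 0)
  at500 <- which(g == 500)
  expect_equal(aX@absorbance[at500] / aN@absorbance[at500],
    cfg$absorbance$decompositionFactor, tolerance = 0.05)

  # turbidity adds a lambda^-4 baseline: 16x larger at 400 than at 800 nm
  aT <- simulateAbsorbance("processed", 0, cfg, scenario = "none",
    uvAmplitude = 0, browningAmplitude = 0, turbidity = 1)
  expect_equal(aT@absorbance[g == 400], cfg$turbidity$abs400, tolerance = 1e-12)
  expect_equal(aT@absorbance[g == 800], cfg$turbidity$abs400 / 16, tolerance = 1e-12)
})

test_that("simulated files round-trip through the readers", {
  cfg <- defaultSyntheticConfig(seed = 18)
  cfg$nDirect <- 2L; cfg$nProcessed <- 2L
  sim <- simulateDataset(cfg)
  dir <- tempfile()
  writeSimulated(sim, dir)
  mf <- readManifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(mf), 4L)
  e <- readEEM(mf$eem_path[1], sampleId = mf$sample_id[1])
  expect_equal(e@intensity, sim$replicates[[1]][[1]]@intensity,
    tolerance = 1e-10, ignore_attr = TRUE)
  a <- readAbsorbance(mf$absorbance_path[3], sampleId = mf$sample_id[3])
  expect_equal(a@absorbance, sim$absorbance[[3]]@absorbance, tolerance = 1e-10)
})

test_that("configuration YAML round trip reproduces the same dataset", {
  cfg <- defaultSyntheticConfig(seed = 19)
  cfg$nDirect <- 2L; cfg$nProcessed <- 2L
  path <- tempfile(fileext = ".yaml")
  writeSyntheticConfig(cfg, path)
  back <- readSyntheticConfig(path)
  expect_identical(back$concentrations, cfg$concentrations)
  expect_identical(back$turbidity, cfg$turbidity)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(back)
  expect_identical(s1$truth$scores, s2$truth$scores)
  # text round trip carries 15 significant digits, not full binary precision
  expect_equal(s1$replicates[[1]][[1]]@intensity,
    s2$replicates[[1]][[1]]@intensity, tolerance = 1e-9)
})
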