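test_that("label maps carry exactly the configured labels in contiguous blocks", {
  cfg <- tinyConfig(k = 2L, gridShape = c(20L, 20L, 20L))
  lab <- generateLabelMap(cfg, 1L)
  expect_setequal(unique(as.integer(lab@data)), c(0L, 1L, 2L, 3L, 4L))
  # each region is one run of consecutive positions in the flattened volume
  flat <- as.integer(lab@data)
  for (l in 1:4) {
    pos <- which(flat == l)
    expect_equal(pos, seq(min(pos), max(pos)))
  }
})

test_that("paired voxel budgets solve the asymmetry-index formula", {
  expect_equal(unname(splitPairedVoxels(250, 0.4)), c(150L, 100L))
  lr <- splitPairedVoxels(200, 0)
  expect_equal(lr[["left"]], lr[["right"]])
  # negative index puts the deficit on the left
  lr <- splitPairedVoxels(250, -0.4)
  expect_equal(unname(lr), c(100L, 150L))
})

test_that("planted thalamus asymmetry round-trips through the label map", {
  for (aiPlanted in c(0, 0.2, 0.4)) {
    cfg <- simulationConfig(nControls = 1L, nPatients = 0L,
                            thalamusAsymmetry = aiPlanted, seed = 5L)
    lab <- generateLabelMap(cfg, 1L)
    reg <- regionTable(lab)
    vl <- reg$voxels[reg$name == "thalamus_L"]
    vr <- reg$voxels[reg$name == "thalamus_R"]
    if (aiPlanted == 0) expect_equal(vl, vr)
    aiGot <- asymmetryIndex(vl, vr)
    quant <- 4 / (vl + vr)   # one-voxel move changes AI by < 4/total
    expect_lt(abs(aiGot - aiPlanted), quant)
  }
})

test_that("a grid too small to host the regions raises a sizing error", {
  cfg <- tinyConfig(k = 2L)
  cfgSmall <- cfg
  cfgSmall@gridShape <- c(2L, 2L, 1L)
  expect_error(generateLabelMap(cfgSmall, 1L), "too small")
})

test_that("identical seed and config reproduce every output exactly", {
  cfg <- tinyConfig(k = 2L, nControls = 1L, nPatients = 1L, r = 0.4,
                    noiseSd = 0.5, confoundAmplitude = 1, seed = 9L)
  lab1 <- generateLabelMap(cfg, 2L); lab2 <- generateLabelMap(cfg, 2L)
  expect_identical(lab1@data, lab2@data)
  g1 <- generateBold(cfg, lab1, 2L); g2 <- generateBold(cfg, lab2, 2L)
  expect_identical(g1$bold@data, g2$bold@data)
  expect_identical(g1$physio@cardiac, g2$physio@cardiac)
  f1 <- generateFaSkeleton(cfg, 2L); f2 <- generateFaSkeleton(cfg, 2L)
  expect_identical(f1@fa, f2@fa)
})

test_that("extending the cohort leaves earlier subjects untouched", {
  cfgA <- tinyConfig(k = 1L, nControls = 3L, r = 0.3, noiseSd = 0.2,
                     seed = 2L)
  cfgB <- tinyConfig(k = 1L, nControls = 6L, r = 0.3, noiseSd = 0.2,
                     seed = 2L)
  labA <- generateLabelMap(cfgA, 2L); labB <- generateLabelMap(cfgB, 2L)
  expect_identical(labA@data, labB@data)
  expect_identical(generateBold(cfgA, labA, 2L)$bold@data,
                   generateBold(cfgB, labB, 2L)$bold@data)
})

test_that("a perfectly correlated pair yields identical mean signals up to scale", {
  cfg <- tinyConfig(k = 1L, r = 1, noiseSd = 0, seed = 3L)
  lab <- generateLabelMap(cfg, 1L)
  gen <- generateBold(cfg, lab, 1L)
  ts <- extractRoiSignals(gen$bold, lab, cfg@networks$tiny)
  expect_equal(abs(stats::cor(ts@signals[1, ], ts@signals[2, ])), 1,
               tolerance = 1e-12)
})

test_that("sample correlations converge to the planted target", {
  # Monte Carlo over subjects: planted r = 0.8 between the two nodes of a
  # bilateral region, 150 timepoints; the mean sample correlation over 200
  # subjects must sit within 0.05 of the target
  cfg <- tinyConfig(k = 1L, nControls = 200L, r = 0.8, noiseSd = 0,
                    seed = 17L)
  lab <- generateLabelMap(cfg, 1L)
  rs <- vapply(seq_len(200L), function(k) {
    gen <- generateBold(cfg, lab, k)
    ts <- extractRoiSignals(gen$bold, lab, cfg@networks$tiny)
    stats::cor(ts@signals[1, ], ts@signals[2, ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.8), 0.05)
})

test_that("patients carry their weakened links and controls do not", {
  cfg <- tinyConfig(k = 2L, nControls = 60L, nPatients = 60L, r = 0.7,
                    noiseSd = 0, weakenedPerNetwork = 1L, seed = 21L)
  # all patients weaken the same number of links
  expect_true(all(vapply(cfg@weakenedLinks, nrow, integer(1)) == 1L))
  lab <- generateLabelMap(cfg, 1L)
  wk <- cfg@weakenedLinks[[1L]]
  net <- cfg@networks$tiny
  ia <- match(wk$node_a, net@nodes$node); ib <- match(wk$node_b, net@nodes$node)
  getR <- function(k) {
    gen <- generateBold(cfg, generateLabelMap(cfg, k), k)
    ts <- extractRoiSignals(gen$bold, generateLabelMap(cfg, k), net)
    stats::cor(ts@signals[ia, ], ts@signals[ib, ])
  }
  rc <- mean(vapply(1:40, getR, numeric(1)))
  # patients whose weakened set contains this same link
  same <- which(vapply(cfg@weakenedLinks, function(w)
    any(cognet:::linkKey(w$node_a, w$node_b) %in%
          cognet:::linkKey(wk$node_a, wk$node_b)), logical(1)))
  rp <- mean(vapply(60L + same[1:min(10, length(same))], getR, numeric(1)))
  expect_gt(rc, 0.55)
  expect_lt(rp, rc - 0.3)
})

test_that("non-PSD planted targets are repaired or rejected", {
  # three mutually exclusive strong correlations cannot coexist
  C <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  R <- psdRepair(C, tol = 2)
  expect_gte(min(eigen(R, symmetric = TRUE)$values), -1e-10)
  expect_equal(diag(R), rep(1, 3))
  expect_error(psdRepair(C, tol = 0.05), "not realizable")
  # an already-PSD matrix is untouched
  ok <- diag(2); ok[1, 2] <- ok[2, 1] <- 0.5
  expect_equal(unname(psdRepair(ok)[1, 2]), 0.5)
})

test_that("FA skeletons respect the white-matter floor and lesion model", {
  cfg <- simulationConfig(nControls = 3L, nPatients = 1L, seed = 8L)
  ctrl <- generateFaSkeleton(cfg, 1L)
  expect_gte(min(ctrl@fa[ctrl@skeletonMask]), 0.2)
  expect_true(all(ctrl@fa[!ctrl@skeletonMask] == 0))
  expect_false(any(faLesionMask(cfg, 1L)))

  pat <- generateFaSkeleton(cfg, 4L)
  les <- faLesionMask(cfg, 4L)
  expect_gt(sum(les), 0)
  # lesion depth 0.15 below the control mean, up to sampling error
  expect_equal(mean(pat@fa[les]), cfg@faMean - cfg@lesionDepth,
               tolerance = 0.03)
  # the patch is contiguous in the Chebyshev sense by construction: all
  # lesion voxels fall inside a cube of side 2*radius+1
  idx <- which(les, arr.ind = TRUE)
  expect_true(all(apply(idx, 2L, function(v) diff(range(v))) <=
                    2L * cfg@lesionRadius))
})

test_that("physiological traces cover the run and match the embedded confound", {
  cfg <- tinyConfig(k = 1L, noiseSd = 0, confoundAmplitude = 2, seed = 4L)
  lab <- generateLabelMap(cfg, 1L)
  gen <- generateBold(cfg, lab, 1L)
  expect_gte(max(gen$physio@time), (cfg@nTimepoints - 1L) * cfg@trSeconds)
  # at a brain voxel, subtracting the two sinusoids evaluated at frame times
  # leaves only the latent signal, constant across voxels of one region
  v <- which(lab@data == 1L)[1:2]
  d <- dim(gen$bold@data)
  M <- matrix(gen$bold@data, prod(d[1:3]), d[4])
  expect_equal(M[v[1], ], M[v[2], ], tolerance = 1e-12)
})
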