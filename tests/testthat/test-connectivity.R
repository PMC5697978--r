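# Hand-built volume: labels and a BOLD run with prescribed voxel series.
mkVolumes <- function(voxelSeries, voxelLabels, tr = 2) {
  nV <- length(voxelLabels)
  nT <- ncol(voxelSeries)
  labs <- sort(unique(voxelLabels[voxelLabels > 0]))
  lab <- new("LabelVolume", data = array(voxelLabels, c(nV, 1, 1)),
             affine = diag(4),
             regions = data.frame(
               name = paste0("roi", rep(seq_len(ceiling(length(labs) / 2)),
                                        each = 2),
                             c("_L", "_R"))[seq_along(labs)],
               label = labs,
               tissue = "GM",
               hemisphere = rep(c("L", "R"), length.out = length(labs))))
  bold <- new("Bold4D", data = array(voxelSeries, c(nV, 1, 1, nT)),
              trSeconds = tr, affine = diag(4))
  list(bold = bold, labels = lab)
}

net2 <- tinyNetwork(1L)   # nodes roi1_L (label 1), roi1_R (label 2)

test_that("node signals are unweighted voxel means per timepoint", {
  v <- mkVolumes(rbind(c(7, 7, 7), c(7, 7, 7), c(1, 2, 3), c(3, 4, 5)),
                 c(1L, 1L, 2L, 2L))
  ts <- extractRoiSignals(v$bold, v$labels, net2)
  expect_equal(unname(ts@signals[1, ]), c(7, 7, 7))
  expect_equal(unname(ts@signals[2, ]), c(2, 3, 4))
  expect_false(any(ts@degenerate))
})

test_that("a label absent from the volume yields a NaN row and a flag", {
  v <- mkVolumes(rbind(c(1, 2, 3)), c(1L))
  expect_warning(ts <- extractRoiSignals(v$bold, v$labels, net2), "absent")
  expect_true(all(is.nan(ts@signals[2, ])))
  expect_true(ts@degenerate[2])
  expect_false(ts@degenerate[1])
})

test_that("misaligned inputs are refused rather than resampled", {
  v <- mkVolumes(rbind(c(1, 2, 3), c(1, 2, 3)), c(1L, 2L))
  shifted <- v$bold
  shifted@affine[1, 4] <- 0.5
  expect_error(extractRoiSignals(shifted, v$labels, net2), "affine")
  small <- new("Bold4D", data = array(0, c(3, 1, 1, 3)), trSeconds = 2,
               affine = diag(4))
  expect_error(extractRoiSignals(small, v$labels, net2), "grids")
})

mkTs <- function(S, nodes = NULL) {
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(S)))
  new("RoiTimeSeries", subjectId = "s", signals = S, trSeconds = 2,
      nodeOrder = nodes, degenerate = rep(FALSE, nrow(S)))
}

test_that("correlation entries follow the Pearson formula", {
  S <- rbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 5)
  expect_equal(unname(corValues(correlationMatrix(mkTs(S)))[1, 2]), 1)
  S2 <- rbind(a = c(1, 2, 3, 4), b = -c(1, 2, 3, 4))
  expect_equal(unname(corValues(correlationMatrix(mkTs(S2)))[1, 2]), -1)
  S3 <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  expect_equal(unname(corValues(correlationMatrix(mkTs(S3)))[1, 2]), 0.8)
})

test_that("the matrix matches a naive double-loop Pearson oracle", {
  set.seed(33)
  for (rep in 1:5) {
    S <- matrix(rnorm(12 * 150), 12)
    got <- corValues(correlationMatrix(mkTs(S)))
    expect_lt(max(abs(unname(got) - naivePearson(S))), 1e-10)
  }
})

test_that("node permutation conjugates the matrix", {
  set.seed(4)
  S <- matrix(rnorm(6 * 50), 6)
  perm <- sample(6)
  r1 <- corValues(correlationMatrix(mkTs(S)))
  r2 <- corValues(correlationMatrix(mkTs(S[perm, , drop = FALSE],
                                         paste0("n", perm))))
  expect_equal(unname(r2), unname(r1[perm, perm]), tolerance = 1e-12)
})

test_that("per-row affine rescaling with positive scale leaves r unchanged", {
  set.seed(5)
  S <- matrix(rnorm(5 * 80), 5)
  scales <- runif(5, 0.5, 3)
  offsets <- rnorm(5, sd = 10)
  r1 <- corValues(correlationMatrix(mkTs(S)))
  r2 <- corValues(correlationMatrix(mkTs(S * scales + offsets)))
  expect_lt(max(abs(r1 - r2)), 1e-10)
})

test_that("zero-variance rows propagate NaN with a warning, diagonal stays 1", {
  S <- rbind(a = rnorm(20), b = rep(3, 20), c = rnorm(20))
  expect_warning(cm <- correlationMatrix(mkTs(S)), "zero-variance")
  r <- corValues(cm)
  expect_true(all(is.nan(r[2, -2])))
  expect_true(all(is.nan(r[-2, 2])))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_false(anyNA(r[c(1, 3), c(1, 3)]))
})

test_that("too few timepoints are rejected and Fisher z is optional", {
  S <- matrix(rnorm(4), 2)
  expect_error(correlationMatrix(mkTs(S)), "3 timepoints")
  set.seed(6)
  S <- matrix(rnorm(2 * 30), 2)
  cm <- correlationMatrix(mkTs(S))
  cz <- correlationMatrix(mkTs(S), fisherZ = TRUE)
  expect_equal(unname(cz@r[1, 2]), atanh(unname(cm@r[1, 2])),
               tolerance = 1e-12)
  expect_equal(cz@scale, "z")
})
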