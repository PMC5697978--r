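mkLabelVolume <- function(counts, names, tissues, hemis, voxelDims = c(1, 1, 1)) {
  flat <- rep(seq_along(counts), counts)
  n <- length(flat)
  dims <- c(n, 1L, 1L)
  new("LabelVolume", data = array(flat, dims),
      affine = diag(c(voxelDims, 1)),
      regions = data.frame(name = names, label = seq_along(counts),
                           tissue = tissues, hemisphere = hemis,
                           stringsAsFactors = FALSE))
}

test_that("normalized volumes partition the total brain volume", {
  lv <- mkLabelVolume(c(50L, 50L), c("a_L", "a_R"), c("GM", "GM"),
                      c("L", "R"))
  m <- computeVolumes(lv)
  expect_equal(regionTable(m)$normVolume, c(0.5, 0.5))
  expect_equal(regionTable(m)$rawVolume, c(50, 50))

  lv3 <- mkLabelVolume(c(45L, 28L, 27L), c("g", "w", "c"),
                       c("GM", "WM", "CSF"), c(NA, NA, NA))
  m3 <- computeVolumes(lv3)
  fr <- tissueFractions(m3)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(unname(fr["GM"]), 0.45)
})

test_that("raw volume scales with the affine's voxel volume", {
  lv <- mkLabelVolume(c(10L, 10L), c("a_L", "a_R"), c("GM", "GM"),
                      c("L", "R"), voxelDims = c(0.94, 0.94, 1))
  m <- computeVolumes(lv)
  expect_equal(regionTable(m)$rawVolume, rep(10 * 0.8836, 2),
               tolerance = 1e-12)
})

test_that("normalized volumes and AI are invariant to voxel rescaling", {
  mk <- function(vd) computeVolumes(mkLabelVolume(
    c(30L, 20L, 50L), c("thal_L", "thal_R", "rest"), c("GM", "GM", "WM"),
    c("L", "R", NA), voxelDims = vd))
  m1 <- mk(c(1, 1, 1)); m2 <- mk(c(2.5, 2.5, 2.5))
  expect_equal(regionTable(m1)$normVolume, regionTable(m2)$normVolume)
  expect_equal(m1@asymmetry$ai, m2@asymmetry$ai)
})

test_that("the asymmetry index follows its defining formula", {
  expect_equal(asymmetryIndex(3, 2), 0.4)
  expect_equal(asymmetryIndex(5, 5), 0)
  expect_equal(asymmetryIndex(1, 0), 2)
  expect_equal(asymmetryIndex(0, 1), 2)
  expect_equal(asymmetryIndex(2, 3, signed = TRUE), -0.4)
  # magnitude is symmetric in its arguments
  expect_equal(asymmetryIndex(7, 3), asymmetryIndex(3, 7))
  expect_error(asymmetryIndex(0, 0), "undefined")
})

test_that("unassigned labels and tissue overrides are validated", {
  lv <- mkLabelVolume(c(10L, 10L), c("a_L", "a_R"), c("GM", "GM"),
                      c("L", "R"))
  expect_error(computeVolumes(lv, tissueGroups = c(a_L = "GM")), "a_R")
  m <- computeVolumes(lv, tissueGroups = c(a_L = "GM", a_R = "WM"))
  expect_equal(unname(tissueFractions(m)[c("GM", "WM")]), c(0.5, 0.5))
  expect_error(computeVolumes(lv, tissueGroups = c(a_L = "GM", a_R = "fat")),
               "GM, WM or CSF")
})

mkRecord <- function(gm, ai = 0.1, id = "s") {
  lv <- mkLabelVolume(c(as.integer(1e4 * gm * (1 + ai / 2) / 2),
                        as.integer(1e4 * gm * (1 - ai / 2) / 2),
                        as.integer(1e4 * (1 - gm))),
                      c("thalamus_L", "thalamus_R", "rest"),
                      c("GM", "GM", "WM"), c("L", "R", NA))
  computeVolumes(lv, subjectId = id)
}

test_that("group comparison is a Welch t-test with symmetric group swap", {
  pats <- lapply(c(0.42, 0.43, 0.44), mkRecord)
  ctrls <- lapply(c(0.45, 0.452, 0.455, 0.458), mkRecord)
  g <- groupCompare(pats, ctrls, "GM")
  # oracle: Welch t-test on the extracted fractions directly
  ref <- stats::t.test(vapply(pats, function(m) tissueFractions(m)[["GM"]],
                              numeric(1)),
                       vapply(ctrls, function(m) tissueFractions(m)[["GM"]],
                              numeric(1)))
  expect_equal(g$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(g$p, ref$p.value, tolerance = 1e-12)
  expect_lt(g$p, 0.05)
  swapped <- groupCompare(ctrls, pats, "GM")
  expect_equal(swapped$t, -g$t, tolerance = 1e-12)
  expect_equal(swapped$p, g$p, tolerance = 1e-12)
  # identical groups: no difference
  same <- groupCompare(pats, pats, "GM")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(groupCompare(pats[1], ctrls, "GM"), "at least 2")
})

test_that("group comparison reaches asymmetry indices by measure name", {
  pats <- lapply(1:3, function(i) mkRecord(0.45, ai = 0.3, id = paste0("p", i)))
  ctrls <- lapply(1:3, function(i) mkRecord(0.45, ai = 0.05,
                                            id = paste0("c", i)))
  g <- groupCompare(pats, ctrls, "thalamus_AI")
  expect_gt(g$patientMean, g$controlMean)
  expect_error(groupCompare(pats, ctrls, "caudate_AI"), "no asymmetry")
})
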