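nodes4 <- paste0("n", 1:4)

test_that("the normative band is the per-link sample mean and SD", {
  c1 <- cmFromValues(rep(0.2, 6), nodes4, "c1")
  c2 <- cmFromValues(rep(0.6, 6), nodes4, "c2")
  m <- fitNormative(list(c1, c2))
  expect_equal(m@links$mean_r, rep(0.4, 6))
  expect_equal(m@links$sd_r, rep(sd(c(0.2, 0.6)), 6), tolerance = 1e-12)
  expect_equal(m@links$sd_r[1], 0.2828, tolerance = 1e-3)
  # identical controls: zero variance everywhere
  m0 <- fitNormative(list(c1, c1, c1))
  expect_equal(m0@links$sd_r, rep(0, 6))
})

test_that("NaN control links are dropped per link with the count recorded", {
  c1 <- cmFromValues(rep(0.5, 6), nodes4, "c1")
  c2 <- cmFromValues(c(NaN, rep(0.3, 5)), nodes4, "c2")
  c3 <- cmFromValues(c(NaN, rep(0.4, 5)), nodes4, "c3")
  m <- fitNormative(list(c1, c2, c3))
  expect_equal(m@links$n, c(1L, rep(3L, 5)))
  expect_true(is.na(m@links$mean_r[1]))   # < 2 usable controls: unmodelable
  expect_equal(m@links$mean_r[2], 0.4)
})

test_that("sex stratification fits per-sex bands and rejects thin strata", {
  cs <- lapply(1:4, function(i)
    cmFromValues(rep(0.1 * i, 6), nodes4, paste0("c", i)))
  ms <- fitNormative(cs, sex = c("F", "F", "M", "M"))
  expect_named(ms, c("F", "M"))
  expect_equal(ms$F@links$mean_r, rep(0.15, 6), tolerance = 1e-12)
  expect_equal(ms$M@links$mean_r, rep(0.35, 6), tolerance = 1e-12)
  expect_error(fitNormative(cs, sex = c("F", "F", "F", "M")),
               "fewer than 2 controls")
  # stratification off pools everyone
  pooled <- fitNormative(cs, sex = c("F", "F", "F", "M"),
                         stratifyBySex = FALSE)
  expect_equal(pooled@links$mean_r, rep(0.25, 6), tolerance = 1e-12)
})

test_that("links are flagged reduced/elevated exactly outside mean +/- 2 SD", {
  cs <- list(cmFromValues(rep(0.3, 6), nodes4, "c1"),
             cmFromValues(rep(0.5, 6), nodes4, "c2"))
  m <- fitNormative(cs)   # mean 0.4, sd ~0.1414 per link
  atMean <- flagAbnormal(cmFromValues(rep(0.4, 6), nodes4, "p0"), m)
  expect_equal(atMean@abnormalCount, 0L)
  low <- flagAbnormal(cmFromValues(c(0.4 - 3 * m@links$sd_r[1],
                                     rep(0.4, 5)), nodes4, "p1"), m)
  expect_equal(low@reducedCount, 1L)
  expect_equal(low@links$status[1], "reduced")
  hi <- flagAbnormal(cmFromValues(c(rep(0.4, 5), 0.95), nodes4, "p2"), m)
  expect_equal(hi@elevatedCount, 1L)
  nanp <- flagAbnormal(cmFromValues(c(NaN, rep(0.4, 5)), nodes4, "p3"), m)
  expect_equal(nanp@links$status[1], "undefined")
  expect_equal(nanp@definedCount, 5L)
  # network mismatch is a contract error
  other <- cmFromValues(rep(0.4, 6), nodes4, "p4", network = "other")
  expect_error(flagAbnormal(other, m), "mismatch")
})

test_that("lowering a patient's r on one link never decreases reduced_count", {
  set.seed(12)
  cs <- lapply(1:10, function(i)
    cmFromValues(runif(6, 0.2, 0.6), nodes4, paste0("c", i)))
  m <- fitNormative(cs)
  for (rep in 1:20) {
    vals <- runif(6, -0.5, 0.9)
    before <- flagAbnormal(cmFromValues(vals, nodes4, "p"), m)@reducedCount
    k <- sample(6, 1)
    vals[k] <- vals[k] - runif(1, 0, 1)
    vals <- pmax(vals, -1)
    after <- flagAbnormal(cmFromValues(vals, nodes4, "p"), m)@reducedCount
    expect_gte(after, before)
  }
})

test_that("frequency maps count flagged patients per link, bounded by n", {
  cs <- list(cmFromValues(rep(0.3, 6), nodes4, "c1"),
             cmFromValues(rep(0.5, 6), nodes4, "c2"))
  m <- fitNormative(cs)
  lowVals <- function(k) { v <- rep(0.4, 6); v[k] <- -0.9; v }
  reps <- list(flagAbnormal(cmFromValues(lowVals(1), nodes4, "p1"), m),
               flagAbnormal(cmFromValues(lowVals(1), nodes4, "p2"), m),
               flagAbnormal(cmFromValues(lowVals(2), nodes4, "p3"), m))
  fm <- frequencyMap(reps)
  expect_equal(fm$count, c(2L, 1L, rep(0L, 4)))
  expect_true(all(fm$count <= 3L))
  # reduced-only and two-sided can differ
  hi <- flagAbnormal(cmFromValues(c(rep(0.4, 5), 0.95), nodes4, "p4"), m)
  expect_equal(frequencyMap(list(hi))$count[6], 1L)
  expect_equal(frequencyMap(list(hi), reducedOnly = TRUE)$count[6], 0L)
  # no patients: all-zero map over a supplied link structure
  fm0 <- frequencyMap(list(), links = enumerateLinks(tinyNetwork(2L)))
  expect_equal(fm0$count, rep(0L, 6))
})

mkReport <- function(reduced, id = "p", network = "net") {
  links <- data.frame(i = 1L, j = 2L, node_i = "a", node_j = "b",
                      r = 0, status = "normal")
  new("AbnormalLinkReport", subjectId = id, networkName = network,
      links = links, reducedCount = as.integer(reduced),
      elevatedCount = 0L, abnormalCount = as.integer(reduced),
      definedCount = max(10L, as.integer(reduced)))
}

test_that("the deficit t-test reproduces hand-computed summaries", {
  d <- deficitTTest(lapply(c(2L, 4L), mkReport))
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(d$sd, 1.414, tolerance = 1e-3)
  # against the spec'd null of the cohort mean itself: centered, degenerate
  dz <- deficitTTest(lapply(rep(3L, 4), mkReport), nullMean = 3)
  expect_equal(dz$t, 0)
  expect_true(is.na(dz$p))
  expect_true(dz$degenerate)
  expect_true(dz$exactEqual)
  # calibrated null equals the Gaussian lower-tail expectation
  dc <- deficitTTest(lapply(c(2L, 4L), mkReport), null = "calibrated")
  expect_equal(dc$nullMean, pnorm(-2) * 10)
  expect_error(deficitTTest(list(mkReport(1L))), "at least 2")
})

test_that("network correlations form a symmetric unit-diagonal matrix", {
  a <- lapply(c(1L, 4L, 2L, 5L), function(x) mkReport(x, network = "A"))
  b <- lapply(c(1L, 4L, 2L, 5L), function(x) mkReport(x, network = "B"))
  c3 <- lapply(c(5L, 1L, 4L, 2L), function(x) mkReport(x, network = "C"))
  nc <- networkCorrelations(list(A = a, B = b, C = c3))
  expect_equal(unname(nc$r["A", "B"]), 1)
  expect_equal(nc$r, t(nc$r))
  expect_equal(unname(diag(nc$r)), rep(1, 3))
  expect_true(all(nc$p[upper.tri(nc$p)] >= 0 & nc$p[upper.tri(nc$p)] <= 1))
  expect_error(networkCorrelations(list(A = a[1:2], B = b[1:2])),
               "at least 3")
})

test_that("independent deficit counts correlate to ~0 on average", {
  set.seed(99)
  rs <- replicate(200, {
    a <- lapply(rpois(8, 3), function(x) mkReport(x, network = "A"))
    b <- lapply(rpois(8, 3), function(x) mkReport(x, network = "B"))
    networkCorrelations(list(A = a, B = b))$r["A", "B"]
  })
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.08)
})
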