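# Programmatic fixtures: tiny networks, configs and hand-built volumes used
# across the suite. Everything is generated in code; no stored binaries.

# Bold4D with one voxel per element of x (a vector) or one voxel per row of
# a (voxels x time) matrix.
boldFromMatrix <- function(M, tr = 2, affine = diag(4)) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  new("Bold4D", data = array(M, c(nrow(M), 1, 1, ncol(M))),
      trSeconds = tr, affine = affine)
}

# A bilateral toy network of k regions (2k nodes), labels 1..2k.
tinyNetwork <- function(k = 1L, name = "tiny") {
  regions <- paste0("roi", seq_len(k))
  nodes <- as.vector(rbind(paste0(regions, "_L"), paste0(regions, "_R")))
  networkDefinition(name, regions, stats::setNames(seq_len(2L * k), nodes))
}

tinyRegionTable <- function(k = 1L) {
  net <- tinyNetwork(k)
  data.frame(name = net@nodes$node, label = net@nodes$label,
             tissue = "GM", hemisphere = net@nodes$hemisphere,
             weight = 1, stringsAsFactors = FALSE)
}

# Small-grid simulation config around a toy network; no confounds by default
# so correlation-level tests see the latent structure directly.
tinyConfig <- function(k = 1L, nControls = 2L, nPatients = 0L, r = 0,
                       nTimepoints = 150L, gridShape = c(8L, 8L, 4L),
                       noiseSd = 0, confoundAmplitude = 0, seed = 1L, ...) {
  net <- tinyNetwork(k)
  simulationConfig(nControls = nControls, nPatients = nPatients,
                   nTimepoints = nTimepoints, gridShape = gridShape,
                   regions = tinyRegionTable(k),
                   networks = stats::setNames(list(net), net@name),
                   withinNetworkR = r, noiseSd = noiseSd,
                   confoundAmplitude = confoundAmplitude,
                   brainFraction = 0.5, seed = seed, ...)
}

# Physio trace with pure sinusoids at the given fundamentals, covering
# nT frames at TR seconds.
sinePhysio <- function(nT = 150L, tr = 2, cardiacHz = 1.1,
                       respiratoryHz = 0.3, fs = 25,
                       phases = c(0.4, 1.1)) {
  t <- seq(0, (nT - 1) * tr, by = 1 / fs)
  new("PhysioTrace", time = t,
      cardiac = sin(2 * pi * cardiacHz * t + phases[1]),
      respiratory = sin(2 * pi * respiratoryHz * t + phases[2]))
}

# Connectivity matrix with prescribed link values over named nodes.
cmFromValues <- function(vals, nodes, subjectId = "s", network = "tiny") {
  n <- length(nodes)
  r <- diag(n)
  r[upper.tri(r)] <- vals
  r <- r + t(r) - diag(diag(r))
  diag(r) <- 1
  new("ConnectivityMatrix", subjectId = subjectId, networkName = network,
      r = r, nodeOrder = nodes, scale = "r")
}

# Amplitude of frequency f in series y sampled at times tf, by projection
# onto the sine/cosine pair (restricted to an interior window to ignore any
# edge effects).
sineAmplitude <- function(y, x, f, tf, window = seq(30L, length(tf) - 30L)) {
  num <- sqrt(sum(y[window] * sin(2 * pi * f * tf[window]))^2 +
                sum(y[window] * cos(2 * pi * f * tf[window]))^2)
  den <- sqrt(sum(x[window] * sin(2 * pi * f * tf[window]))^2 +
                sum(x[window] * cos(2 * pi * f * tf[window]))^2)
  num / den
}

# Connectivity matrices for (a subset of) a config's cohort over its first
# network, optionally through the preprocessing chain.
cohortMatrices <- function(cfg, preprocess = FALSE,
                           idx = seq_len(nrow(cfg@subjects))) {
  net <- cfg@networks[[1L]]
  lapply(idx, function(k) {
    lab <- generateLabelMap(cfg, k)
    gen <- generateBold(cfg, lab, k)
    b <- if (preprocess) lowpass(regressPhysio(gen$bold, gen$physio))
         else gen$bold
    correlationMatrix(extractRoiSignals(b, lab, net,
                                        subjectId = cfg@subjects$id[k]),
                      networkName = net@name)
  })
}

# Naive double-loop Pearson correlation, the independent oracle for
# correlationMatrix.
naivePearson <- function(S) {
  n <- nrow(S)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    x <- S[i, ]; y <- S[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

# FA skeleton map on a small grid with prescribed in-mask values.
faMapFromValues <- function(values, gridShape = c(6L, 6L, 3L)) {
  mask <- array(FALSE, gridShape)
  mask[2:5, 2:5, 2] <- TRUE
  stopifnot(length(values) %in% c(1L, sum(mask)))
  fa <- array(0, gridShape)
  fa[mask] <- values
  new("FASkeletonMap", fa = fa, skeletonMask = mask, affine = diag(4))
}
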