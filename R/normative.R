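## Control-cohort normative band, abnormal-link flagging, aggregation and the
## group statistics (per-patient deficit t-test, inter-network correlations).

checkSameNetwork <- function(matrices) {
  name <- unique(vapply(matrices, function(m) m@networkName, character(1)))
  if (length(name) != 1L)
    stop("connectivity matrices span several networks: ",
         paste(name, collapse = ", "))
  orders <- unique(vapply(matrices, function(m)
    paste(m@nodeOrder, collapse = "|"), character(1)))
  if (length(orders) != 1L)
    stop("connectivity matrices disagree on node order")
  invisible(name)
}

.fitOneStratum <- function(controls, stratum) {
  net <- controls[[1]]@networkName
  nodes <- controls[[1]]@nodeOrder
  n <- length(nodes)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  links <- data.frame(i = as.integer(idx[ord, "row"]),
                      j = as.integer(idx[ord, "col"]))
  links$node_i <- nodes[links$i]
  links$node_j <- nodes[links$j]
  vals <- vapply(controls, function(m) m@r[cbind(links$i, links$j)],
                 numeric(nrow(links)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  usable <- is.finite(vals)
  links$n <- as.integer(rowSums(usable))
  links$mean_r <- ifelse(links$n >= 2L,
                         rowSums(vals * usable, na.rm = TRUE) / links$n, NA)
  links$sd_r <- vapply(seq_len(nrow(links)), function(l) {
    v <- vals[l, usable[l, ]]
    if (length(v) >= 2L) stats::sd(v) else NA_real_
  }, numeric(1))
  new("NormativeLinkModel", networkName = net, nodeOrder = nodes,
      links = links, nControls = length(controls), stratum = stratum)
}

#' Fit the control-cohort normative band per link
#'
#' Computes, for every within-network link, the sample mean and sample SD
#' (n - 1 denominator) of the control correlations, defining the
#' mean +/- 2 SD normality band. NaN correlations are dropped per link with
#' the per-link usable count recorded; links with fewer than two usable
#' controls are unmodelable (NA mean/sd). When sex labels are supplied and
#' \code{stratifyBySex} is TRUE, one model is fitted per sex stratum,
#' matching comparison against same-sex controls.
#'
#' @param controls list of control \code{\linkS4class{ConnectivityMatrix}}
#'   objects sharing network and node order.
#' @param sex optional character vector of control sex labels, parallel to
#'   \code{controls}.
#' @param stratifyBySex fit per-sex models when sex labels exist (default
#'   TRUE).
#' @return a \code{\linkS4class{NormativeLinkModel}}, or a named list of them
#'   (one per stratum) when stratified.
#' @export
fitNormative <- function(controls, sex = NULL, stratifyBySex = TRUE) {
  stopifnot(length(controls) >= 1L)
  checkSameNetwork(controls)
  if (is.null(sex) || !stratifyBySex) {
    if (length(controls) < 2L)
      stop("need at least 2 controls to fit a normative band")
    return(.fitOneStratum(controls, ""))
  }
  stopifnot(length(sex) == length(controls))
  strata <- split(seq_along(controls), sex)
  small <- names(strata)[vapply(strata, length, integer(1)) < 2L]
  if (length(small)) {
    ls <- enumerateLinks0(controls[[1]])
    stop("stratum '", paste(small, collapse = "', '"),
         "' has fewer than 2 controls; unmodelable links: ",
         paste(utils::head(paste(ls$node_i, ls$node_j, sep = "-"), 5L),
               collapse = ", "),
         if (nrow(ls) > 5L) sprintf(" ... (%d links)", nrow(ls)) else "")
  }
  lapply(strata, function(ix) .fitOneStratum(controls[ix], sex[ix[1]]))
}

# Canonical link frame of a connectivity matrix.
enumerateLinks0 <- function(cm) {
  n <- length(cm@nodeOrder)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  data.frame(i = as.integer(idx[ord, "row"]),
             j = as.integer(idx[ord, "col"]),
             node_i = cm@nodeOrder[idx[ord, "row"]],
             node_j = cm@nodeOrder[idx[ord, "col"]])
}

#' Flag a patient's abnormal connectivity links
#'
#' Classifies every link of a patient's connectivity matrix against the
#' normative band: \code{reduced} if r < mean - 2 SD, \code{elevated} if
#' r > mean + 2 SD, \code{undefined} if the link is unmodelable or the
#' patient's value is NaN, otherwise \code{normal}. Counts are over defined
#' links only.
#'
#' @param patient a patient \code{\linkS4class{ConnectivityMatrix}}.
#' @param model a \code{\linkS4class{NormativeLinkModel}}, or a named list of
#'   per-sex models as returned by a stratified \code{\link{fitNormative}}.
#' @param sex the patient's sex label, required when \code{model} is
#'   stratified.
#' @param nSd half-width of the normality band in control SDs (default 2).
#' @return an \code{\linkS4class{AbnormalLinkReport}}.
#' @export
flagAbnormal <- function(patient, model, sex = NULL, nSd = 2) {
  if (is.list(model)) {
    if (is.null(sex) || !sex %in% names(model))
      stop("stratified model: supply the patient's sex (one of ",
           paste(names(model), collapse = ", "), ")")
    model <- model[[sex]]
  }
  stopifnot(is(patient, "ConnectivityMatrix"),
            is(model, "NormativeLinkModel"))
  if (patient@networkName != model@networkName)
    stop(sprintf("network mismatch: patient '%s' vs model '%s'",
                 patient@networkName, model@networkName))
  if (!identical(patient@nodeOrder, model@nodeOrder))
    stop("patient node order does not match the normative model")

  links <- model@links
  r <- patient@r[cbind(links$i, links$j)]
  lo <- links$mean_r - nSd * links$sd_r
  hi <- links$mean_r + nSd * links$sd_r
  status <- rep("normal", nrow(links))
  status[r < lo] <- "reduced"
  status[r > hi] <- "elevated"
  status[!is.finite(r) | links$n < 2L] <- "undefined"
  out <- links[, c("i", "j", "node_i", "node_j")]
  out$r <- r
  out$status <- status
  new("AbnormalLinkReport", subjectId = patient@subjectId,
      networkName = model@networkName, links = out,
      reducedCount = sum(status == "reduced"),
      elevatedCount = sum(status == "elevated"),
      abnormalCount = sum(status %in% c("reduced", "elevated")),
      definedCount = sum(status != "undefined"))
}

#' Frequency of occurrence of abnormal links across patients
#'
#' Counts, per link, how many patients were flagged, the aggregation behind
#' a frequency-of-occurrence bar chart over a network's links.
#'
#' @param reports list of \code{\linkS4class{AbnormalLinkReport}} for one
#'   network.
#' @param reducedOnly count only reduced links (default FALSE: any abnormal).
#' @param links a \code{\linkS4class{LinkSet}} supplying the link structure;
#'   required (only) when \code{reports} is empty, in which case the map is
#'   all zeros.
#' @return data.frame with columns \code{node_i}, \code{node_j},
#'   \code{count}; every count is at most the number of patients.
#' @export
frequencyMap <- function(reports, reducedOnly = FALSE, links = NULL) {
  if (!length(reports)) {
    if (is.null(links))
      stop("no reports supplied; pass a LinkSet to get an all-zero map")
    base <- linkTable(links)[, c("i", "j", "node_i", "node_j")]
    base$count <- 0L
    attr(base, "networkName") <- networkName(links)
    attr(base, "nPatients") <- 0L
    return(base)
  }
  net <- unique(vapply(reports, function(r) r@networkName, character(1)))
  if (length(net) != 1L) stop("reports span several networks")
  base <- reports[[1]]@links[, c("i", "j", "node_i", "node_j")]
  hits <- vapply(reports, function(rep) {
    st <- rep@links$status
    if (reducedOnly) st == "reduced"
    else st %in% c("reduced", "elevated")
  }, logical(nrow(base)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = 1L)
  base$count <- as.integer(rowSums(hits))
  attr(base, "networkName") <- net
  attr(base, "nPatients") <- length(reports)
  base
}

#' One-sample t-test on per-patient reduced-link counts
#'
#' Tests whether the per-patient number of reduced links in a network departs
#' from a null count, and reports the cohort mean and SD of the counts
#' (the "mean (sd)" deficit summary per network). The default null of 0
#' tests that deficit counts exceed nothing; a calibrated null equal to the
#' false-positive count expected from the +/- 2 SD rule under Gaussian links
#' is available via \code{null = "calibrated"}.
#'
#' @param reports list of \code{\linkS4class{AbnormalLinkReport}} (>= 2
#'   patients) for one network.
#' @param nullMean null value for the mean count (default 0).
#' @param null \code{"value"} to use \code{nullMean}, or \code{"calibrated"}
#'   to test against \code{pnorm(-2) * L} expected spuriously reduced links
#'   (L = defined link count).
#' @param measure \code{"reduced"} (default) or \code{"abnormal"}.
#' @return list with \code{counts}, \code{mean}, \code{sd}, \code{t},
#'   \code{df}, \code{p} (NA with \code{degenerate = TRUE} when the counts
#'   have zero variance), \code{nullMean} and \code{network}.
#' @export
deficitTTest <- function(reports, nullMean = 0,
                         null = c("value", "calibrated"),
                         measure = c("reduced", "abnormal")) {
  null <- match.arg(null)
  measure <- match.arg(measure)
  if (length(reports) < 2L) stop("need at least 2 patients")
  net <- unique(vapply(reports, function(r) r@networkName, character(1)))
  if (length(net) != 1L) stop("reports span several networks")
  x <- vapply(reports, function(r)
    if (measure == "reduced") r@reducedCount else r@abnormalCount,
    integer(1))
  if (null == "calibrated") {
    L <- stats::median(vapply(reports, function(r) r@definedCount,
                              integer(1)))
    nullMean <- if (measure == "reduced") stats::pnorm(-2) * L
                else 2 * stats::pnorm(-2) * L
  }
  m <- mean(x); s <- stats::sd(x); n <- length(x)
  if (s == 0) {
    return(list(counts = x, mean = m, sd = 0, t = 0, df = n - 1, p = NA,
                degenerate = TRUE, exactEqual = (m == nullMean),
                nullMean = nullMean, network = net))
  }
  tt <- stats::t.test(x, mu = nullMean)
  list(counts = x, mean = m, sd = s, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE,
       nullMean = nullMean, network = net)
}

#' Pearson correlations of per-patient deficit counts between networks
#'
#' Correlates per-patient reduced-link counts across networks: a symmetric
#' unit-diagonal matrix of pairwise Pearson r with two-sided p values,
#' measuring whether patients impaired in one network tend to be impaired in
#' another.
#'
#' @param reportsByNetwork named list (one entry per network) of lists of
#'   \code{\linkS4class{AbnormalLinkReport}}; every network must cover the
#'   same patients in the same order (>= 3 patients).
#' @param measure \code{"reduced"} (default) or \code{"abnormal"}.
#' @return list with \code{r} (network x network correlation matrix),
#'   \code{p} (two-sided p values, NA on the diagonal) and \code{counts}
#'   (patients x networks matrix).
#' @export
networkCorrelations <- function(reportsByNetwork,
                                measure = c("reduced", "abnormal")) {
  measure <- match.arg(measure)
  nets <- names(reportsByNetwork)
  if (is.null(nets)) stop("reportsByNetwork must be a named list")
  ids <- lapply(reportsByNetwork, function(reps)
    vapply(reps, function(r) r@subjectId, character(1)))
  if (length(unique(ids)) != 1L)
    stop("every network must cover the same patients in the same order")
  nPat <- length(ids[[1]])
  if (nPat < 3L) stop("need at least 3 patients")
  counts <- vapply(reportsByNetwork, function(reps)
    vapply(reps, function(r)
      if (measure == "reduced") r@reducedCount else r@abnormalCount,
      integer(1)),
    integer(nPat))
  r <- matrix(1, length(nets), length(nets), dimnames = list(nets, nets))
  p <- matrix(NA_real_, length(nets), length(nets),
              dimnames = list(nets, nets))
  for (a in seq_along(nets)) for (b in seq_along(nets)) {
    if (a >= b) next
    xa <- counts[, a]; xb <- counts[, b]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
      r[a, b] <- r[b, a] <- NA_real_
    } else {
      ct <- stats::cor.test(xa, xb)
      r[a, b] <- r[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
    }
  }
  list(r = r, p = p, counts = counts)
}
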