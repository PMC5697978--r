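#' Load cognitive network definitions from a JSON document
#'
#' Reads a network-definition document: a JSON object with a
#' \code{parcellation} dictionary mapping node names (\code{<region>_L},
#' \code{<region>_R}) to integer labels, and a \code{networks} array of
#' \code{{name, regions}} entries. Every listed region is bilateral and is
#' expanded to a left and a right node, so a network over k regions has
#' n = 2k nodes and n(n-1)/2 within-network links.
#'
#' @param path path to the JSON document. Defaults to the packaged document
#'   defining the five cognitive networks (default mode, attention, verbal
#'   memory, memory, visuospatial working memory).
#' @param parcellation optional named integer vector overriding the
#'   document's node-to-label dictionary.
#' @return named list of \code{\linkS4class{NetworkDefinition}} objects.
#' @examples
#' nets <- loadNetworks()
#' nNodes(nets$dmn)       # 8
#' linkCount(nets$dmn)    # 28
#' @export
loadNetworks <- function(path = system.file("extdata", "networks.json",
                                            package = "cognet"),
                         parcellation = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(parcellation)) {
    parcellation <- unlist(doc$parcellation)
    if (is.null(parcellation))
      stop("document has no 'parcellation' dictionary and none was supplied")
  }
  entries <- doc$networks
  if (is.data.frame(entries))
    entries <- lapply(seq_len(nrow(entries)), function(i)
      list(name = entries$name[i], regions = entries$regions[[i]]))
  nets <- lapply(entries, function(e)
    networkDefinition(e$name, unlist(e$regions), parcellation))
  names(nets) <- vapply(nets, function(x) x@name, character(1))
  nets
}

#' The packaged five cognitive networks
#'
#' Convenience wrapper around \code{\link{loadNetworks}} returning the five
#' shipped network definitions.
#'
#' @return named list of \code{\linkS4class{NetworkDefinition}}: \code{dmn}
#'   (8 nodes), \code{attention} (12), \code{verbal_memory} (12),
#'   \code{memory} (12), \code{visuospatial_working_memory} (10).
#' @export
defaultNetworks <- function() loadNetworks()

#' Construct a network definition from bilateral region names
#'
#' @param name network identifier.
#' @param regions character vector of bilateral region names.
#' @param parcellation named integer vector mapping node names
#'   (\code{<region>_L}, \code{<region>_R}) to parcellation labels.
#' @return a \code{\linkS4class{NetworkDefinition}}.
#' @export
networkDefinition <- function(name, regions, parcellation) {
  if (length(regions) == 0L)
    stop("network '", name, "' has an empty region list")
  nodes <- data.frame(
    region = rep(regions, each = 2L),
    hemisphere = rep(c("L", "R"), length(regions)),
    stringsAsFactors = FALSE)
  nodes$node <- paste(nodes$region, nodes$hemisphere, sep = "_")
  missing <- setdiff(nodes$node, names(parcellation))
  if (length(missing))
    stop("network '", name, "': unresolved region names: ",
         paste(missing, collapse = ", "))
  nodes$label <- as.integer(parcellation[nodes$node])
  new("NetworkDefinition", name = name, regions = regions, nodes = nodes)
}

#' Enumerate the within-network links of a network
#'
#' Lists all unordered node pairs in canonical order (ascending node index,
#' i < j), the link set over which connectivity is analysed; its size is
#' n(n-1)/2 for n nodes.
#'
#' @param net a \code{\linkS4class{NetworkDefinition}}.
#' @return a \code{\linkS4class{LinkSet}}.
#' @examples
#' ls <- enumerateLinks(defaultNetworks()$dmn)
#' linkCount(ls)   # 28
#' @export
enumerateLinks <- function(net) {
  stopifnot(is(net, "NetworkDefinition"))
  n <- nrow(net@nodes)
  if (n < 2L)
    stop("network '", net@name, "' has fewer than 2 nodes; no links exist")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  links <- data.frame(i = as.integer(idx[, "row"]),
                      j = as.integer(idx[, "col"]))
  links <- links[order(links$i, links$j), , drop = FALSE]
  rownames(links) <- NULL
  links$node_i <- net@nodes$node[links$i]
  links$node_j <- net@nodes$node[links$j]
  new("LinkSet", networkName = net@name, nodeOrder = net@nodes$node,
      links = links)
}

# Canonical link identity string: order-insensitive in its two node names.
linkKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
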