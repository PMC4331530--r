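#' Construct an annotated network from an edge table
#'
#' Low-level constructor used by [loadEdgeList()] and the synthetic
#' generator.  Self-loops are removed and duplicate (unordered) edges
#' collapsed; isolated nodes may be supplied through `nodes`.
#'
#' @param edges two-column character matrix or data.frame of endpoints.
#' @param nodes optional full node vector (defaults to the endpoints in
#'   order of first appearance).
#' @param diseaseGenes,essentialGenes optional label sets.
#' @return an [AnnotatedNetwork-class].
#' @export
annotatedNetwork <- function(edges, nodes = NULL,
                             diseaseGenes = character(),
                             essentialGenes = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) >= 2) {
    storage.mode(edges) <- "character"
    keep <- edges[, 1] != edges[, 2]
    edges <- edges[keep, , drop = FALSE]
  }
  if (is.null(nodes)) {
    nodes <- unique(as.vector(t(edges[, 1:2, drop = FALSE])))
  }
  n <- length(nodes)
  if (n == 0L) {
    adj <- Matrix::Matrix(0, 0, 0, sparse = TRUE)
  } else {
    i <- match(edges[, 1], nodes)
    j <- match(edges[, 2], nodes)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint not in the node vector")
    adj <- Matrix::sparseMatrix(
      i = c(i, j), j = c(j, i), x = 1, dims = c(n, n),
      dimnames = list(nodes, nodes)
    )
    adj@x[] <- 1  # collapse duplicate edges back to 0/1
    adj <- Matrix::drop0(adj)
  }
  new("AnnotatedNetwork",
    nodes = nodes, adjacency = adj,
    diseaseGenes = unique(diseaseGenes),
    essentialGenes = unique(essentialGenes)
  )
}

#' Load an interaction network from an edge-list file
#'
#' Reads a whitespace- or tab-separated edge list with columns
#' `idA idB [score]`.  Lines starting with `#` are ignored.  When a
#' `scoreThreshold` is given (STRING-style confidence filtering), edges
#' with score below the threshold are dropped; the loaded graph is always
#' unweighted and undirected, with self-loops removed and duplicate edges
#' collapsed.
#'
#' @param path path to the edge-list file.
#' @param scoreThreshold optional numeric in \[0, 1\]; edges with
#'   `score < scoreThreshold` are dropped.  Requires a third column.
#' @param diseaseGenes,essentialGenes optional label sets attached to the
#'   returned network.
#' @return an [AnnotatedNetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb\t0.9", "b\tc\t0.3", "a\ta\t0.8"), f)
#' net <- loadEdgeList(f, scoreThreshold = 0.4)
#' edgeCount(net)  # 1: the low-confidence edge and the self-loop are gone
#' @export
loadEdgeList <- function(path, scoreThreshold = NULL,
                         diseaseGenes = character(),
                         essentialGenes = character()) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("malformed edge list at line ", lineNo[which(nf < 2)[1]],
         ": fewer than 2 columns")
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  score <- rep(NA_real_, length(fields))
  has3 <- nf >= 3
  if (any(has3)) {
    raw <- vapply(fields[has3], `[`, character(1), 3L)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- lineNo[has3][which(is.na(val))[1]]
      stop("malformed edge list at line ", bad, ": non-numeric score")
    }
    score[has3] <- val
  }
  if (!is.null(scoreThreshold)) {
    if (!all(has3)) {
      stop("scoreThreshold given but line ", lineNo[which(!has3)[1]],
           " has no score column")
    }
    sel <- score >= scoreThreshold
    a <- a[sel]; b <- b[sel]
  }
  annotatedNetwork(cbind(a, b),
    diseaseGenes = diseaseGenes, essentialGenes = essentialGenes
  )
}

#' Convert an annotated network to an igraph object
#'
#' @param net an [AnnotatedNetwork-class].
#' @return an undirected `igraph` graph with vertex names.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected")
}

#' Induced subgraph on a node subset
#'
#' @param net an [AnnotatedNetwork-class].
#' @param keep node identifiers to retain (network order is preserved).
#' @return an [AnnotatedNetwork-class].
#' @export
inducedSubnetwork <- function(net, keep) {
  keep <- net@nodes[net@nodes %in% keep]
  new("AnnotatedNetwork",
    nodes = keep,
    adjacency = net@adjacency[keep, keep, drop = FALSE],
    diseaseGenes = net@diseaseGenes,
    essentialGenes = net@essentialGenes
  )
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected node set.  Size
#' ties are broken in favour of the component containing the
#' lexicographically smallest identifier, so the result is deterministic.
#' An empty network is returned unchanged.
#'
#' @param net an [AnnotatedNetwork-class].
#' @return an [AnnotatedNetwork-class].
#' @export
largestComponent <- function(net) {
  if (length(net@nodes) == 0L) return(net)
  comp <- igraph::components(asIgraph(net))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # pick the tied component holding the lexicographically smallest node
    firsts <- vapply(best, function(k) {
      min(net@nodes[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)[1L]]
  }
  inducedSubnetwork(net, net@nodes[comp$membership == best])
}

#' Partition genes into disease/essential classes
#'
#' Splits the supplied disease set D and essential set E into the classes
#' used throughout: `E-` = E \\ D (essential, not disease), `D-` = D \\ E,
#' their intersection, and `O` = network nodes in neither.  Members of D or
#' E absent from the network are kept in their class and recorded in
#' `offNetwork`.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param diseaseIds,essentialIds identifier sets (default: the labels
#'   stored on the network).
#' @return a [GenePartition-class].
#' @export
partitionGenes <- function(net, diseaseIds = diseaseGenes(net),
                           essentialIds = essentialGenes(net)) {
  d <- unique(diseaseIds)
  e <- unique(essentialIds)
  onNet <- c(d, e)[c(d, e) %in% net@nodes]
  new("GenePartition",
    disease = d,
    essential = e,
    dMinus = setdiff(d, e),
    eMinus = setdiff(e, d),
    both = intersect(d, e),
    other = setdiff(net@nodes, c(d, e)),
    offNetwork = setdiff(union(d, e), onNet)
  )
}

#' Class membership restricted to the network
#'
#' @param net an [AnnotatedNetwork-class].
#' @param partition a [GenePartition-class].
#' @param class one of `"D"`, `"E"`, `"Dminus"`, `"Eminus"`, `"both"`,
#'   `"O"`.
#' @return character vector of on-network members of the class.
#' @export
classMembers <- function(net, partition, class) {
  ids <- switch(class,
    D = partition@disease,
    E = partition@essential,
    Dminus = partition@dMinus,
    Eminus = partition@eMinus,
    both = partition@both,
    O = partition@other,
    stop("unknown class '", class, "'")
  )
  ids[ids %in% net@nodes]
}

#' Per-class on-network counts
#'
#' Bookkeeping table of the partition restricted to the network, mirroring
#' the usual D/E/E&D/D-/E-/O summary.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param partition a [GenePartition-class].
#' @return named integer vector.
#' @export
partitionCounts <- function(net, partition) {
  cls <- c("D", "E", "both", "Dminus", "Eminus", "O")
  counts <- vapply(cls, function(k) {
    length(classMembers(net, partition, k))
  }, integer(1))
  names(counts) <- c("D", "E", "E&D", "D-", "E-", "O")
  counts
}
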