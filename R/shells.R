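#' Breadth-first shells of a node
#'
#' The n-neighbors of node i are the nodes whose shortest-path distance to
#' i is exactly n; shell 1 is the direct-neighbor set.  Shells partition
#' the nodes reachable from i (excluding i itself); unreachable nodes do
#' not appear.  The essential counts and proportions refer to the
#' non-disease essential class `E-` of the supplied partition.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param node a node identifier in the network.
#' @param partition optional [GenePartition-class]; defaults to the one
#'   derived from the network's own labels.
#' @return a [ShellProfile-class].
#' @export
computeShells <- function(net, node, partition = partitionGenes(net)) {
  if (!node %in% net@nodes) stop("node '", node, "' not in the network")
  d <- as.vector(igraph::distances(asIgraph(net), v = node))
  names(d) <- net@nodes
  d <- d[is.finite(d) & d > 0]
  eMinus <- classMembers(net, partition, "Eminus")
  maxN <- if (length(d)) max(d) else 0
  shells <- vector("list", maxN)
  sizes <- integer(maxN)
  ecount <- integer(maxN)
  for (n in seq_len(maxN)) {
    q <- names(d)[d == n]
    shells[[n]] <- q
    sizes[n] <- length(q)
    ecount[n] <- sum(q %in% eMinus)
  }
  props <- ifelse(sizes > 0, ecount / sizes, NA_real_)
  new("ShellProfile",
    node = node, shells = shells, shellSizes = sizes,
    essentialCounts = ecount, proportions = as.numeric(props)
  )
}

#' Shell proportions of non-disease essential genes over a class
#'
#' For every member i of a protein class, computes the proportion
#' `p_i^n = |Q_i^n intersect E-| / |Q_i^n|` of non-disease essential genes
#' among its n-neighbors.  Members whose shell n is empty contribute no
#' value (they are excluded, not counted as zero).
#'
#' @param net an [AnnotatedNetwork-class].
#' @param partition a [GenePartition-class].
#' @param nodeClass class name (see [classMembers()]) or an explicit
#'   identifier vector.
#' @param n shell index (>= 1), or a vector of indices.
#' @param distMatrix optional precomputed distance matrix (class members
#'   as rows, all nodes as columns) to amortize BFS over many calls.
#' @return for a single `n`, a named numeric vector of proportions; for
#'   several, a list indexed by `n`.
#' @export
shellProportions <- function(net, partition, nodeClass, n,
                             distMatrix = NULL) {
  stopifnot(all(n >= 1))
  members <- if (length(nodeClass) == 1L &&
                 nodeClass %in% c("D", "E", "Dminus", "Eminus", "both", "O")) {
    classMembers(net, partition, nodeClass)
  } else {
    intersect(nodeClass, net@nodes)
  }
  if (length(members) == 0L) {
    out <- lapply(n, function(.) stats::setNames(numeric(0), character(0)))
  } else {
    if (is.null(distMatrix)) {
      distMatrix <- igraph::distances(asIgraph(net), v = members)
      rownames(distMatrix) <- members
    }
    isE <- colnames(distMatrix) %in% classMembers(net, partition, "Eminus")
    out <- lapply(n, function(nn) {
      inShell <- distMatrix == nn
      q <- rowSums(inShell)
      qe <- rowSums(inShell & rep(isE, each = nrow(inShell)))
      p <- (qe / q)[q > 0]
      stats::setNames(as.numeric(p), rownames(distMatrix)[q > 0])
    })
  }
  if (length(n) == 1L) out[[1L]] else stats::setNames(out, n)
}

#' Exact permutation rank-sum p-value
#'
#' Two-sided p-value of the Wilcoxon rank-sum statistic by exhaustive
#' enumeration of all assignments of the pooled (mid-)ranks to group A.
#' Intended for small samples (combined size <= ~15).
#'
#' @param a,b numeric samples.
#' @return p-value in (0, 1].
#' @export
rankSumExact <- function(a, b) {
  nA <- length(a)
  pooled <- rank(c(a, b))  # midranks under ties
  wObs <- sum(pooled[seq_len(nA)])
  mu <- nA * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), nA)
  ws <- colSums(matrix(pooled[combos], nrow = nA))
  # two-sided: assignments at least as extreme about the mean rank sum
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

#' Normal-approximation rank-sum p-value
#'
#' Two-sided p-value from the tie-corrected normal approximation to the
#' rank-sum statistic, with a continuity correction of 1/2 so that
#' small-sample values track the exact permutation distribution.
#'
#' @param a,b numeric samples.
#' @return p-value in (0, 1].
#' @export
rankSumNormal <- function(a, b) {
  nA <- length(a)
  nB <- length(b)
  pooled <- rank(c(a, b))
  nTot <- nA + nB
  w <- sum(pooled[seq_len(nA)])
  mu <- nA * (nTot + 1) / 2
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties) / (nTot * (nTot - 1))
  sigma2 <- nA * nB / 12 * ((nTot + 1) - tieCorr)
  if (sigma2 <= 0) return(1)
  z <- max(0, abs(w - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-z))
}

#' Compare the shell proportions of two protein classes
#'
#' Reports the medians of the two collections of shell proportions and a
#' two-sided rank-sum p-value for their difference.  `method = "auto"`
#' uses exhaustive permutation enumeration when the combined sample size
#' is at most 12 and the tie-corrected normal approximation otherwise.
#'
#' @param pA,pB numeric collections of shell proportions (both nonempty).
#' @param classA,classB class names for reporting.
#' @param n shell index for reporting.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return a [ShellComparison-class].
#' @export
compareClasses <- function(pA, pB, classA = "A", classB = "B", n = NA,
                           method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(pA) == 0L) {
    stop("class '", classA, "' has no defined proportions at shell n=", n)
  }
  if (length(pB) == 0L) {
    stop("class '", classB, "' has no defined proportions at shell n=", n)
  }
  if (method == "auto") {
    method <- if (length(pA) + length(pB) <= 12L) "exact" else "normal"
  }
  p <- switch(method,
    exact = rankSumExact(pA, pB),
    normal = rankSumNormal(pA, pB)
  )
  new("ShellComparison",
    n = as.integer(n), classA = classA, classB = classB,
    medianA = stats::median(pA), medianB = stats::median(pB),
    nA = length(pA), nB = length(pB),
    pValue = p, method = method
  )
}

#' Shell-median comparison table for two classes
#'
#' Convenience wrapper reproducing the usual summary layout: for each
#' shell index n it reports the medians of the non-disease essential
#' proportions over both classes and the rank-sum p-value.  Shells where
#' either class has no defined proportion are dropped.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param partition a [GenePartition-class].
#' @param classA,classB class names (default the disease-not-essential
#'   class versus the unlabelled class).
#' @param maxN largest shell index to report.
#' @param method rank-sum method passed to [compareClasses()].
#' @return data.frame with columns `n`, `medianA`, `medianB`, `nA`, `nB`,
#'   `pValue`.
#' @export
shellMedianTable <- function(net, partition, classA = "Dminus",
                             classB = "O", maxN = 6L,
                             method = "auto") {
  g <- asIgraph(net)
  memA <- classMembers(net, partition, classA)
  memB <- classMembers(net, partition, classB)
  dA <- igraph::distances(g, v = memA); rownames(dA) <- memA
  dB <- igraph::distances(g, v = memB); rownames(dB) <- memB
  rows <- lapply(seq_len(maxN), function(nn) {
    pA <- shellProportions(net, partition, classA, nn, distMatrix = dA)
    pB <- shellProportions(net, partition, classB, nn, distMatrix = dB)
    if (length(pA) == 0L || length(pB) == 0L) return(NULL)
    cmp <- compareClasses(pA, pB, classA, classB, nn, method = method)
    data.frame(
      n = nn, medianA = cmp@medianA, medianB = cmp@medianB,
      nA = cmp@nA, nB = cmp@nB, pValue = cmp@pValue
    )
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
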