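# Brute-force oracles, kept deliberately independent of the package's
# implementation paths: plain loops and dense base-R linear algebra only.

# degree of every node by scanning the edge list
oracleDegrees <- function(edges, nodes) {
  deg <- stats::setNames(integer(length(nodes)), nodes)
  seen <- character()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a == b) next
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    deg[a] <- deg[a] + 1L
    deg[b] <- deg[b] + 1L
  }
  deg
}

# connected components by flood fill over an edge list
oracleComponents <- function(edges, nodes) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    k <- k + 1L
    frontier <- start
    comp[start] <- k
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
        nb <- nb[is.na(comp[nb])]
        comp[nb] <- k
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
  }
  comp
}

# all-pairs shortest paths, Floyd-Warshall on a dense matrix
oracleDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# dense closed-form steady state: alpha * (I - (1-alpha) W)^-1 Y
# with W assembled entry by entry from the stated normalization rules
oracleSteadyState <- function(adj, y, alpha, normalization) {
  n <- nrow(adj)
  k <- rowSums(adj)
  w <- matrix(0, n, n)
  for (x in seq_len(n)) {
    for (yy in seq_len(n)) {
      if (adj[x, yy] == 0) next
      w[x, yy] <- switch(normalization,
        pump = adj[yy, x] / k[yy],       # receives A(y,x)/k(y) from y
        average = adj[x, yy] / k[x],
        symmetric = adj[x, yy] / sqrt(k[x] * k[yy])
      )
    }
  }
  as.numeric(alpha * solve(diag(n) - (1 - alpha) * w, y))
}

# two-sided rank-sum p-value by full enumeration of group assignments
oracleRankSumP <- function(a, b) {
  nA <- length(a)
  r <- rank(c(a, b))
  n <- length(r)
  mu <- nA * (n + 1) / 2
  wObs <- sum(r[seq_len(nA)])
  sets <- utils::combn(n, nA)
  count <- 0L
  for (j in seq_len(ncol(sets))) {
    if (abs(sum(r[sets[, j]]) - mu) >= abs(wObs - mu) - 1e-12) {
      count <- count + 1L
    }
  }
  count / ncol(sets)
}

# Erdos-Renyi-ish random edge list over letter-ish node names
randomEdges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

# random connected graph: random spanning tree plus extra random edges
randomConnectedEdges <- function(n, extra, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  perm <- sample(nodes)
  tree <- cbind(perm[-1], vapply(2:n, function(i) {
    sample(perm[seq_len(i - 1)], 1)
  }, character(1)))
  pairs <- t(utils::combn(nodes, 2))
  more <- pairs[sample(nrow(pairs), min(extra, nrow(pairs))), , drop = FALSE]
  rbind(tree, more)
}

denseAdjacency <- function(net) {
  as.matrix(adjacencyMatrix(net))
}

writeTempLines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
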