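#' Create a propagation configuration
#'
#' @param alpha restart fraction in (0, 1]; balances prior information
#'   against network smoothing.  The default 0.5 weighs both equally; the
#'   method's published description leaves this parameter open, so runs
#'   should report the value used.
#' @param solver `"auto"` (direct sparse solve up to 20000 nodes, fixed
#'   point iteration above), `"iterative"`, or `"direct"`.
#' @param tolerance L1 convergence bound for the iterative solver.
#' @param maxIterations iteration cap for the iterative solver.
#' @param normalization `"pump"` (default; each node distributes its flow
#'   equally among its neighbors, conserving total flow), `"average"`, or
#'   `"symmetric"`.
#' @param priorMode `"normalized"` (each side of the prior sums to +1/-1)
#'   or `"unit"` (+1/-1 per gene).
#' @return a [PropagationConfig-class].
#' @export
propagationConfig <- function(alpha = 0.5, solver = "auto",
                              tolerance = 1e-8, maxIterations = 10000L,
                              normalization = "pump",
                              priorMode = "normalized") {
  new("PropagationConfig",
    alpha = alpha, solver = solver, tolerance = tolerance,
    maxIterations = as.integer(maxIterations),
    normalization = normalization, priorMode = priorMode
  )
}

#' Build the normalized propagation operator
#'
#' Returns the sparse operator W such that one propagation step is
#' `F <- (1 - alpha) * W %*% F + alpha * Y`.
#'
#' In `"pump"` mode a node x holding flow F(x) sends F(x)/k(x) to each of
#' its k(x) neighbors, so the new value at y is
#' \eqn{\sum_x F(x) A(x,y)/k(x)} and total flow is conserved.  In
#' `"average"` mode the new value at x is the mean of its neighbors'
#' values.  `"symmetric"` uses \eqn{A(x,y)/\sqrt{k(x)k(y)}}.  Degree-0
#' nodes have all-zero rows and columns in every mode: they neither send
#' nor receive flow.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param normalization `"pump"`, `"average"` or `"symmetric"`.
#' @return a sparse `Matrix`.
#' @export
buildOperator <- function(net, normalization = "pump") {
  if (length(net@nodes) == 0L) stop("cannot build an operator on an empty network")
  a <- net@adjacency
  k <- Matrix::rowSums(a)
  inv <- ifelse(k > 0, 1 / k, 0)
  switch(normalization,
    # row-normalize then transpose: column y of A/k collects A(x,y)/k(x)
    pump = Matrix::t(Matrix::Diagonal(x = inv) %*% a),
    average = Matrix::Diagonal(x = inv) %*% a,
    symmetric = {
      s <- Matrix::Diagonal(x = sqrt(inv))
      s %*% a %*% s
    },
    stop("unknown normalization '", normalization, "'")
  )
}

#' Build a signed prior vector
#'
#' Constructs the prior information Y for the three prioritization modes:
#' `"NP_D"` puts positive flow on the disease training genes only,
#' `"NP_E"` puts negative flow on the non-disease essential genes only,
#' and `"NP_DE"` (dual flow) uses both, so that candidates near the
#' training genes but away from the essential core score highest.
#'
#' With `priorMode = "normalized"` each on-network training gene receives
#' `+1/|T|` and each on-network non-disease essential gene `-1/|E-|`, so
#' positive and negative flow are balanced; `"unit"` assigns +1 and -1 per
#' gene.  Off-network members of either set are dropped with a warning.
#' Should the supplied sets overlap, the positive assignment wins (with a
#' warning); by construction `E-` excludes disease genes, so this only
#' arises with inconsistent user input.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param mode `"NP_D"`, `"NP_E"` or `"NP_DE"`.
#' @param trainingGenes disease training genes (positive side).
#' @param essentialMinus non-disease essential genes (negative side).
#' @param priorMode `"normalized"` or `"unit"`.
#' @return a [PriorVector-class].
#' @export
buildPrior <- function(net, mode = c("NP_DE", "NP_D", "NP_E"),
                       trainingGenes = character(),
                       essentialMinus = character(),
                       priorMode = "normalized") {
  mode <- match.arg(mode)
  pos <- if (mode %in% c("NP_D", "NP_DE")) unique(trainingGenes) else character()
  neg <- if (mode %in% c("NP_E", "NP_DE")) unique(essentialMinus) else character()
  off <- setdiff(c(pos, neg), net@nodes)
  if (length(off)) {
    warning(length(off), " prior gene(s) absent from the network; ignored")
  }
  pos <- intersect(pos, net@nodes)
  neg <- intersect(neg, net@nodes)
  overlap <- intersect(pos, neg)
  if (length(overlap)) {
    warning("genes in both prior sets keep their positive assignment: ",
            paste(overlap, collapse = ", "))
    neg <- setdiff(neg, overlap)
  }
  if (mode %in% c("NP_D", "NP_DE") && length(pos) == 0L) {
    stop("mode ", mode, " requires at least one on-network training gene")
  }
  if (mode %in% c("NP_E", "NP_DE") && length(neg) == 0L) {
    stop("mode ", mode, " requires at least one on-network essential gene")
  }
  y <- stats::setNames(numeric(length(net@nodes)), net@nodes)
  wPos <- if (priorMode == "normalized") 1 / length(pos) else 1
  wNeg <- if (priorMode == "normalized") 1 / length(neg) else 1
  y[pos] <- wPos
  y[neg] <- -wNeg
  new("PriorVector", values = y, positiveSet = pos, negativeSet = neg,
      mode = mode)
}

.asPriorValues <- function(net, y) {
  if (is(y, "PriorVector")) y <- y@values
  if (is.null(names(y))) {
    if (length(y) != length(net@nodes)) {
      stop("unnamed prior must have one entry per network node")
    }
    names(y) <- net@nodes
  } else {
    off <- setdiff(names(y)[y != 0], net@nodes)
    if (length(off)) {
      warning(length(off), " prior entr(ies) on off-network genes ignored")
    }
    full <- stats::setNames(numeric(length(net@nodes)), net@nodes)
    shared <- intersect(names(y), net@nodes)
    full[shared] <- y[shared]
    y <- full
  }
  y
}

#' Propagate a prior to its steady state
#'
#' Runs the flow propagation
#' \deqn{F^{t+1} = (1-\alpha) W F^t + \alpha Y, \quad F^1 = Y,}
#' either by fixed-point iteration to the configured L1 tolerance or by
#' solving the steady-state linear system
#' \deqn{F^\infty = \alpha (I - (1-\alpha) W)^{-1} Y}
#' directly.  For alpha in (0, 1] the system matrix is strictly
#' diagonally-dominant-safe (the spectral radius of `(1-alpha) W` is at
#' most `1-alpha < 1` for every supported normalization), so the solve
#' cannot be singular.  The two solvers agree entrywise up to solver
#' tolerance; propagation is linear in Y.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param prior a [PriorVector-class], or a (named) numeric vector over
#'   network nodes.
#' @param config a [PropagationConfig-class].
#' @param operator optional pre-built operator from [buildOperator()]
#'   (matching `config@normalization`), to amortize construction over many
#'   propagations.
#' @return a [PropagationResult-class].
#' @examples
#' net <- annotatedNetwork(cbind(c("a", "b"), c("b", "c")))
#' cfg <- propagationConfig(alpha = 0.5)
#' res <- propagateFlow(net, c(a = 1), cfg)
#' flowValues(res)
#' @export
propagateFlow <- function(net, prior, config = propagationConfig(),
                          operator = NULL) {
  validObject(config)
  y <- .asPriorValues(net, prior)
  n <- length(y)
  if (n == 0L) stop("empty network")
  w <- if (is.null(operator)) buildOperator(net, config@normalization) else operator
  alpha <- config@alpha
  solver <- config@solver
  if (solver == "auto") solver <- if (n <= 20000L) "direct" else "iterative"
  if (solver == "direct") {
    m <- Matrix::Diagonal(n) - (1 - alpha) * w
    f <- as.numeric(Matrix::solve(m, alpha * y))
    names(f) <- names(y)
    return(new("PropagationResult",
      flow = f, iterationsUsed = 0L, residual = 0,
      converged = TRUE, config = config
    ))
  }
  f <- y
  res <- Inf
  it <- 0L
  while (it < config@maxIterations) {
    it <- it + 1L
    fNew <- as.numeric((1 - alpha) * (w %*% f) + alpha * y)
    res <- sum(abs(fNew - f))
    f <- fNew
    if (res <= config@tolerance) break
  }
  if (res > config@tolerance) {
    stop(sprintf(
      "propagation did not converge in %d iterations (residual %.3g > %.3g)",
      config@maxIterations, res, config@tolerance
    ))
  }
  names(f) <- names(y)
  new("PropagationResult",
    flow = f, iterationsUsed = it, residual = res,
    converged = TRUE, config = config
  )
}

#' Steady-state similarity matrix
#'
#' Computes \eqn{S = \alpha (I - (1-\alpha) W)^{-1}}, whose entry S(x, y)
#' is the steady-state flow observed at x when one unit is injected at y;
#' column y equals the propagation of the indicator prior on y.  Dense:
#' intended for small networks and diagnostics.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param config a [PropagationConfig-class].
#' @return a dense base matrix with node dimnames.
#' @export
similarityMatrix <- function(net, config = propagationConfig()) {
  n <- length(net@nodes)
  if (n > 2000L) {
    warning("computing a dense ", n, " x ", n, " similarity matrix")
  }
  w <- buildOperator(net, config@normalization)
  m <- Matrix::Diagonal(n) - (1 - config@alpha) * w
  s <- config@alpha * as.matrix(Matrix::solve(m))
  dimnames(s) <- list(net@nodes, net@nodes)
  s
}

#' Propagate many priors against one factorization
#'
#' Solves the steady state for each column of `ys` with a single direct
#' solve, which is how the cross-validation harness amortizes its folds.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param ys numeric matrix, one prior per column, rows in network order.
#' @param config a [PropagationConfig-class].
#' @return numeric matrix of steady-state flows, same shape as `ys`.
#' @keywords internal
propagateMany <- function(net, ys, config = propagationConfig()) {
  n <- length(net@nodes)
  stopifnot(nrow(ys) == n)
  w <- buildOperator(net, config@normalization)
  m <- Matrix::Diagonal(n) - (1 - config@alpha) * w
  f <- as.matrix(Matrix::solve(m, config@alpha * ys))
  rownames(f) <- net@nodes
  f
}

#' Rank candidate genes by steady-state net flow
#'
#' Builds the prior for the requested mode, propagates it, and ranks the
#' candidate genes by descending flow.  Ranks are 1-based within the
#' candidate list; genes with exactly equal flow are all ranked last among
#' their tied group (pessimistic tie rule), and candidates absent from the
#' network rank behind every on-network candidate, sharing the worst rank.
#'
#' By linearity of the steady state, the dual-flow (`NP_DE`) score equals
#' the `NP_D` score under 1/|T| weighting plus the (negative) `NP_E` score
#' under 1/|E-| weighting.
#'
#' @param net an [AnnotatedNetwork-class].
#' @param mode `"NP_DE"`, `"NP_D"` or `"NP_E"`.
#' @param trainingGenes,essentialMinus prior gene sets, see [buildPrior()].
#' @param config a [PropagationConfig-class].
#' @param candidates candidate identifier vector (may include off-network
#'   genes); must be nonempty.
#' @return data.frame with columns `gene`, `score`, `rank`, `onNetwork`,
#'   ordered by rank.
#' @export
scoreCandidates <- function(net, mode, trainingGenes, essentialMinus,
                            config = propagationConfig(), candidates) {
  if (length(candidates) == 0L) stop("empty candidate list")
  prior <- buildPrior(net, mode, trainingGenes, essentialMinus,
                      priorMode = config@priorMode)
  flow <- flowValues(propagateFlow(net, prior, config))
  rankCandidates(flow, candidates)
}

#' Rank a candidate list against a flow vector
#'
#' @param flow named numeric vector of node scores.
#' @param candidates candidate identifiers.
#' @return data.frame `gene`, `score`, `rank`, `onNetwork` ordered by rank.
#' @keywords internal
rankCandidates <- function(flow, candidates) {
  onNet <- candidates %in% names(flow)
  score <- rep(-Inf, length(candidates))
  score[onNet] <- flow[candidates[onNet]]
  # ties share the worst (largest) rank of their group
  rk <- as.integer(rank(-score, ties.method = "max"))
  out <- data.frame(
    gene = candidates, score = score, rank = rk, onNetwork = onNet,
    stringsAsFactors = FALSE
  )
  out[order(out$rank, out$gene), , drop = FALSE]
}
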