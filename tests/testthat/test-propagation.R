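pathNet <- function() annotatedNetwork(rbind(c("a", "b"), c("b", "c")))

test_that("pump operator splits a node's flow equally among its neighbors", {
  net <- pathNet()
  w <- buildOperator(net, "pump")
  # one unit at b sends 1/2 to a and 1/2 to c
  y <- c(a = 0, b = 1, c = 0)
  out <- as.numeric(w %*% y)
  expect_equal(out, c(0.5, 0, 0.5))
  # columns of the pump operator sum to one (flow conservation per step)
  expect_equal(unname(Matrix::colSums(w)), c(1, 1, 1))
})

test_that("operator handles isolated nodes and rejects unknown modes", {
  solo <- annotatedNetwork(matrix(character(), ncol = 2), nodes = "x")
  for (mode in c("pump", "average", "symmetric")) {
    expect_equal(sum(abs(buildOperator(solo, mode))), 0)
  }
  expect_error(buildOperator(pathNet(), "bogus"), "unknown normalization")
})

test_that("operator action matches an entrywise brute-force double loop", {
  ed <- randomEdges(5, 0.6, 21)
  net <- annotatedNetwork(ed, nodes = sort(unique(as.vector(ed))))
  adj <- denseAdjacency(net)
  k <- rowSums(adj)
  set.seed(1)
  f <- rnorm(nrow(adj))
  for (mode in c("pump", "average", "symmetric")) {
    expected <- numeric(nrow(adj))
    for (x in seq_len(nrow(adj))) {
      for (y in seq_len(ncol(adj))) {
        if (adj[x, y] == 0) next
        expected[x] <- expected[x] + switch(mode,
          pump = f[y] * adj[y, x] / k[y],
          average = f[y] * adj[x, y] / k[x],
          symmetric = f[y] * adj[x, y] / sqrt(k[x] * k[y])
        )
      }
    }
    got <- as.numeric(buildOperator(net, mode) %*% f)
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("steady state solves the two-node system exactly", {
  net <- annotatedNetwork(cbind("a", "b"))
  # f_a = 0.5 f_b + 0.5, f_b = 0.5 f_a  =>  f_a = 2/3, f_b = 1/3
  f <- flowValues(propagateFlow(net, c(a = 1), propagationConfig(alpha = 0.5)))
  expect_equal(unname(f), c(2 / 3, 1 / 3), tolerance = 1e-10)
})

test_that("alpha = 1 returns the prior and a zero prior stays zero", {
  net <- annotatedNetwork(randomEdges(8, 0.4, 5))
  y <- stats::setNames(rnorm(length(networkNodes(net))), networkNodes(net))
  f1 <- flowValues(propagateFlow(net, y, propagationConfig(alpha = 1)))
  expect_equal(f1, y, tolerance = 1e-12)
  f0 <- flowValues(propagateFlow(net, 0 * y, propagationConfig(alpha = 0.3)))
  expect_equal(unname(f0), rep(0, length(y)))
})

test_that("iterative and direct solvers agree with the dense closed form", {
  for (seed in c(2, 7)) {
    ed <- randomConnectedEdges(12, 8, seed)
    net <- annotatedNetwork(ed, nodes = sort(unique(as.vector(ed))))
    adj <- denseAdjacency(net)
    set.seed(seed)
    y <- stats::setNames(rnorm(nrow(adj)), rownames(adj))
    for (mode in c("pump", "average", "symmetric")) {
      for (alpha in c(0.2, 0.8)) {
        oracle <- oracleSteadyState(adj, y, alpha, mode)
        it <- propagateFlow(net, y, propagationConfig(
          alpha = alpha, solver = "iterative", normalization = mode
        ))
        dir <- propagateFlow(net, y, propagationConfig(
          alpha = alpha, solver = "direct", normalization = mode
        ))
        expect_equal(unname(flowValues(it)), oracle, tolerance = 1e-7)
        expect_equal(unname(flowValues(dir)), oracle, tolerance = 1e-9)
        expect_lte(it@residual, 1e-8)
      }
    }
  }
})

test_that("iteration cap raises a convergence error that reports the residual", {
  net <- annotatedNetwork(randomConnectedEdges(10, 5, 3))
  y <- stats::setNames(rnorm(length(networkNodes(net))), networkNodes(net))
  expect_error(
    propagateFlow(net, y, propagationConfig(
      alpha = 0.01, solver = "iterative", maxIterations = 2L
    )),
    "did not converge"
  )
})

test_that("pump-mode steady state conserves total flow on connected graphs", {
  for (seed in 1:5) {
    ed <- randomConnectedEdges(15, 10, seed)
    net <- annotatedNetwork(ed, nodes = sort(unique(as.vector(ed))))
    set.seed(seed)
    y <- stats::setNames(rnorm(length(networkNodes(net))), networkNodes(net))
    f <- flowValues(propagateFlow(net, y, propagationConfig(alpha = 0.4)))
    expect_equal(sum(f), sum(y), tolerance = 1e-8)
  }
})

test_that("propagation is linear in the prior", {
  net <- annotatedNetwork(randomConnectedEdges(12, 8, 4))
  nodes <- networkNodes(net)
  set.seed(4)
  y1 <- stats::setNames(rnorm(length(nodes)), nodes)
  y2 <- stats::setNames(rnorm(length(nodes)), nodes)
  cfg <- propagationConfig(alpha = 0.6)
  f12 <- flowValues(propagateFlow(net, y1 + y2, cfg))
  f1 <- flowValues(propagateFlow(net, y1, cfg))
  f2 <- flowValues(propagateFlow(net, y2, cfg))
  expect_equal(f12, f1 + f2, tolerance = 1e-10)
})

test_that("automorphic nodes receive equal flow under a symmetric prior", {
  # a-b-c path: swapping a and c is an automorphism fixing b
  net <- pathNet()
  f <- flowValues(propagateFlow(net, c(b = 1), propagationConfig(alpha = 0.5)))
  expect_equal(unname(f["a"]), unname(f["c"]), tolerance = 1e-12)
})

test_that("the steady state approaches the prior as alpha approaches one", {
  net <- annotatedNetwork(randomConnectedEdges(10, 6, 8))
  nodes <- networkNodes(net)
  set.seed(8)
  y <- stats::setNames(rnorm(length(nodes)), nodes)
  gaps <- vapply(c(0.3, 0.6, 0.9, 0.99), function(a) {
    max(abs(flowValues(propagateFlow(net, y, propagationConfig(alpha = a))) - y))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 0.1 * gaps[1])
})

test_that("priors carry the stated weights and signs", {
  net <- annotatedNetwork(rbind(c("a","b"), c("b","e"), c("e","f"), c("f","g")))
  y <- buildPrior(net, "NP_DE", c("a", "b"), "e")
  v <- priorValues(y)
  expect_equal(unname(v[c("a", "b", "e")]), c(0.5, 0.5, -1))
  expect_equal(sum(v), 0)

  yd <- buildPrior(net, "NP_D", "a", character())
  expect_equal(unname(priorValues(yd)["a"]), 1)
  expect_equal(sum(priorValues(yd) != 0), 1)

  yu <- buildPrior(net, "NP_DE", c("a", "b"), c("e", "f", "g"),
                   priorMode = "unit")
  expect_equal(unname(priorValues(yu)[c("a", "b", "e", "f", "g")]),
               c(1, 1, -1, -1, -1))

  # normalized sides sum to +1 and -1
  yn <- buildPrior(net, "NP_DE", c("a", "b"), c("e", "f", "g"))
  expect_equal(sum(priorValues(yn)[priorValues(yn) > 0]), 1)
  expect_equal(sum(priorValues(yn)[priorValues(yn) < 0]), -1)
})

test_that("prior construction validates its gene sets", {
  net <- pathNet()
  expect_error(buildPrior(net, "NP_D", character(), "b"), "training gene")
  expect_error(buildPrior(net, "NP_E", "a", character()), "essential gene")
  expect_error(suppressWarnings(buildPrior(net, "NP_DE", "ghost", "b")),
               "training gene")
  expect_warning(buildPrior(net, "NP_D", c("a", "ghost"), character()),
                 "absent from the network")
  expect_warning(
    y <- buildPrior(net, "NP_DE", "a", c("a", "b")),
    "positive assignment"
  )
  expect_gt(priorValues(y)["a"], 0)
})

test_that("candidate ranking is 1-based, pessimistic on ties, worst for off-network", {
  flow <- c(a = 3, b = 2, c = 2, d = 2, e = 1)
  r <- dualflow:::rankCandidates(flow, c("a", "b", "c", "d", "e", "zz"))
  expect_equal(r$rank[r$gene == "a"], 1L)
  # b, c, d tie: all ranked last among the tied group
  expect_equal(r$rank[r$gene %in% c("b", "c", "d")], rep(4L, 3))
  expect_equal(r$rank[r$gene == "zz"], 6L)

  allOff <- dualflow:::rankCandidates(flow, c("x", "y", "z"))
  expect_equal(allOff$rank, rep(3L, 3))
  expect_error(scoreCandidates(pathNet(), "NP_D", "a", character(),
                               propagationConfig(), character()),
               "empty candidate list")
})

test_that("dual-flow scores decompose into weighted positive and negative parts", {
  toy <- decoyHubToy()
  net <- toy$network
  part <- partitionGenes(net)
  em <- classMembers(net, part, "Eminus")
  cfg <- propagationConfig(alpha = 0.5)
  cand <- networkNodes(net)
  de <- scoreCandidates(net, "NP_DE", toy$train, em, cfg, cand)
  d <- scoreCandidates(net, "NP_D", toy$train, em, cfg, cand)
  e <- scoreCandidates(net, "NP_E", toy$train, em, cfg, cand)
  m <- merge(merge(de[, c("gene", "score")], d[, c("gene", "score")],
                   by = "gene", suffixes = c("_de", "_d")),
             e[, c("gene", "score")], by = "gene")
  expect_equal(m$score_de, m$score_d + m$score, tolerance = 1e-10)
})
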