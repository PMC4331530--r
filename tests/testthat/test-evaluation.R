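posTable <- function() {
  data.frame(
    gene = sprintf("g%02d", 1:12),
    chromosome = c(rep("chr1", 8), rep("chr2", 4)),
    position = c(0, 10, 20, 35, 50, 70, 100, 140, 0, 5, 10, 15),
    stringsAsFactors = FALSE
  )
}

test_that("candidate lists pick the closest same-chromosome genes", {
  pos <- posTable()
  # short chromosome: everything is returned
  cl <- buildCandidateList("g09", pos, size = 100L)
  expect_setequal(cl@candidates, c("g09", "g10", "g11", "g12"))

  # nearest-by-distance selection matches a brute-force sort
  cl2 <- buildCandidateList("g03", pos, size = 4L)
  same <- pos[pos$chromosome == "chr1" & pos$gene != "g03", ]
  bf <- same$gene[order(abs(same$position - 20), same$gene)][1:3]
  expect_identical(cl2@candidates, c("g03", bf))

  # equidistant genes at the cutoff resolve by identifier order
  posT <- data.frame(
    gene = c("t", "left", "right", "far"),
    chromosome = "chr1",
    position = c(0, -10, 10, 99)
  )
  cl3 <- buildCandidateList("t", posT, size = 2L)
  expect_identical(cl3@candidates, c("t", "left"))

  expect_error(buildCandidateList("missing", pos), "absent from positions")
})

evalFixture <- function() {
  # two disease modules on a path-plus-hub graph, plus an off-network gene
  ed <- rbind(
    c("g01", "g02"), c("g02", "g03"), c("g01", "g03"),   # module 1 triangle
    c("g04", "g05"), c("g05", "g06"),                    # module 2
    c("g03", "g04"), c("g06", "g07"), c("g07", "g08"),
    c("g08", "g09"), c("g09", "g10"), c("g10", "g11"), c("g11", "g12")
  )
  net <- annotatedNetwork(ed, nodes = sprintf("g%02d", 1:12))
  assoc <- data.frame(
    disease = c("d1", "d1", "d1", "d2", "d2", "d2"),
    gene = c("g01", "g02", "g03", "g04", "g05", "offnet"),
    stringsAsFactors = FALSE
  )
  part <- partitionGenes(net, unique(assoc$gene), c("g11", "g12"))
  list(net = net, assoc = assoc, part = part)
}

test_that("leave-one-out scoring applies the enrichment rules", {
  fx <- evalFixture()
  # keep each test gene's chromosome free of its fellow training genes so
  # the top rank is attainable
  pos <- data.frame(
    gene = c("g01", sprintf("g%02d", 6:12), sprintf("g%02d", 2:5), "offnet"),
    chromosome = c(rep("chrA", 8), rep("chrB", 5)),
    position = c(seq(0, 70, 10), seq(0, 40, 10)),
    stringsAsFactors = FALSE
  )
  rep <- loocv(fx$assoc, fx$net, fx$part, propagationConfig(),
               positions = pos, mode = "NP_DE", candidateSize = 10L)
  tr <- trialResults(rep)
  expect_identical(nrow(tr), 6L)
  expect_equal(tr$enrichment, 50 / tr$rank)

  # the off-network test gene gets rank 100 and enrichment 0.5
  off <- tr[tr$gene == "offnet", ]
  expect_false(off$onNetwork)
  expect_identical(off$rank, 100L)
  expect_equal(off$enrichment, 0.5)

  # tightly linked module members rank their held-out gene first
  expect_identical(tr$rank[tr$gene == "g01"], 1L)
  expect_equal(tr$enrichment[tr$gene == "g01"], 50)

  # score 1 includes the off-network trial, score 2 excludes it
  pd <- rep@perDisease
  d2 <- tr[tr$disease == "d2", ]
  expect_equal(pd$score1[pd$disease == "d2"], mean(d2$enrichment))
  expect_equal(pd$score2[pd$disease == "d2"],
               mean(d2$enrichment[d2$onNetwork]))
  expect_equal(rep@score1, mean(pd$score1))
})

test_that("single-gene diseases are skipped with a warning", {
  fx <- evalFixture()
  assoc <- rbind(fx$assoc, data.frame(disease = "lonely", gene = "g07"))
  expect_warning(
    rep <- loocv(assoc, fx$net, fx$part, propagationConfig(),
                 positions = NULL, mode = "NP_D", candidateSize = 6L),
    "fewer than 2"
  )
  expect_false("lonely" %in% trialResults(rep)$disease)
})

test_that("a test gene tying other candidates is ranked last among them", {
  flow <- c(t = 1, a = 2, b = 1, c = 1, d = 1, e = 0.5)
  r <- dualflow:::rankCandidates(flow, names(flow))
  # t ties b, c, d at positions 2..5 -> all get rank 5
  expect_equal(r$rank[r$gene == "t"], 5L)
})

test_that("ROC analysis behaves at the boundaries and matches pairwise AUC", {
  mk <- function(ranks, csize = 100L) {
    data.frame(disease = "d", gene = seq_along(ranks), rank = ranks,
               enrichment = 50 / ranks, onNetwork = TRUE,
               candidateSize = csize)
  }
  perfect <- rocAuc(mk(rep(1L, 20)), 100L)
  expect_gte(perfect$auc, 0.99)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(perfect$roc$sensitivity[1], 0)
  expect_equal(utils::tail(perfect$roc$fpr, 1), 1)
  expect_equal(utils::tail(perfect$roc$sensitivity, 1), 1)

  worst <- rocAuc(mk(rep(100L, 20)), 100L)
  expect_lte(worst$auc, 0.02)

  set.seed(99)
  unif <- mk(sample(1:100, 500, replace = TRUE))
  ra <- rocAuc(unif, 100L)
  expect_equal(ra$auc, 0.5, tolerance = 0.03)
  # monotone curve
  expect_true(all(diff(ra$roc$fpr) >= 0))
  expect_true(all(diff(ra$roc$sensitivity) >= 0))
  # trapezoid vs pairwise comparison agreement
  expect_equal(ra$auc, pairwiseAuc(unif), tolerance = 0.01)

  offOnly <- mk(5L)
  offOnly$onNetwork <- FALSE
  expect_error(rocAuc(offOnly), "no on-network trial")
})

test_that("train/test splits score held-out genes against a fixed prior", {
  fx <- evalFixture()
  train <- data.frame(disease = c("d1", "d1"), gene = c("g01", "g02"))
  test <- data.frame(disease = "d1", gene = "g03")
  rep <- timeSplitEvaluate(train, test, fx$net, fx$part,
                           propagationConfig(), positions = NULL,
                           mode = "NP_DE", candidateSize = 8L)
  tr <- trialResults(rep)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$gene, "g03")
  # g03 closes the training triangle: it must beat the background
  expect_lte(tr$rank, 3L)

  overlap <- data.frame(disease = "d1", gene = "g01")
  expect_error(
    timeSplitEvaluate(train, overlap, fx$net, fx$part, propagationConfig()),
    "overlap"
  )
  orphan <- data.frame(disease = "dX", gene = "g07")
  expect_warning(
    expect_error(
      timeSplitEvaluate(train, orphan, fx$net, fx$part, propagationConfig(),
                        mode = "NP_DE"),
      "no disease"
    ),
    "no training genes"
  )
})

test_that("year-based splits partition the association table", {
  assoc <- data.frame(disease = "d", gene = c("a", "b", "c"),
                      year = c(2005, 2007, 2010))
  sp <- splitByYear(assoc, 2008)
  expect_setequal(sp$train$gene, c("a", "b"))
  expect_setequal(sp$test$gene, "c")
})
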