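test_that("discretization passes small domains through and bins large ones", {
  small <- c(0, 1, 2, 1, 0, 2)              # 3 distinct values
  r <- discretizeColumn(small)
  expect_true(r$spec$passThrough)
  expect_identical(r$values, small)
  # 13 distinct values -> floor(log2(13)) + 1 = 4 intervals
  x13 <- 0:12
  r13 <- discretizeColumn(x13)
  expect_false(r13$spec$passThrough)
  expect_equal(r13$spec$itvnum, 4)
  expect_equal(length(unique(r13$values)), 4)
  expect_equal(min(r13$values), 0)
  expect_equal(max(r13$values), 3)
  # 5 distinct values -> 3 intervals; zero maps to bin 0, max to the top
  x5 <- c(0, 1, 2, 3, 4)
  r5 <- discretizeColumn(x5)
  expect_equal(r5$spec$itvnum, 3)
  expect_equal(r5$values[1], 0)
  expect_equal(r5$values[5], 2)
  # the bin formula: min(floor(v * itvnum / max), itvnum - 1)
  expect_equal(r5$values, pmin(floor(x5 * 3 / 4), 2))
  # constant column is pass-through
  expect_true(discretizeColumn(rep(7, 10))$spec$passThrough)
})

test_that("BIC score is decomposable and penalizes spurious edges", {
  set.seed(3)
  d <- cbind(A = rbinom(500, 1, 0.5), B = rbinom(500, 1, 0.5))
  empty <- list(A = character(0), B = character(0))
  oneEdge <- list(A = character(0), B = "A")
  # independent data: the penalty dominates any likelihood gain
  expect_gt(bicScore(empty, d), bicScore(oneEdge, d))
  # decomposability: total = sum of per-family scores, checked by
  # computing each family against a single-variable/dependent split
  set.seed(4)
  d3 <- cbind(A = rbinom(300, 1, 0.4), B = rbinom(300, 2, 0.5),
              C = rbinom(300, 1, 0.6))
  dag <- list(A = character(0), B = "A", C = "B")
  total <- bicScore(dag, d3)
  parts <- bicScore(list(A = character(0), B = "A"), d3[, c("A", "B")]) +
    bicScore(list(B = character(0), C = "B"), d3[, c("B", "C")]) -
    bicScore(list(B = character(0)), d3[, "B", drop = FALSE])
  expect_equal(total, parts, tolerance = 1e-9)
  # duplicating the rows exactly doubles the likelihood term
  n <- nrow(d)
  dagScore <- function(dat) bicScore(oneEdge, dat)
  ll1 <- dagScore(d) + 0.5 * log(n) * 3          # strip the penalty
  ll2 <- dagScore(rbind(d, d)) + 0.5 * log(2 * n) * 3
  expect_equal(ll2, 2 * ll1, tolerance = 1e-8)
  expect_error(bicScore(list(A = "B", B = "A"), d), "acyclic")
})

test_that("structure search leaves independent variables unconnected", {
  set.seed(10)
  d <- cbind(A = rbinom(1000, 1, 0.5), B = rbinom(1000, 1, 0.5))
  dag <- greedyStructureSearch(d)
  expect_equal(sum(lengths(dag)), 0L)
  single <- greedyStructureSearch(cbind(A = rbinom(50, 1, 0.5)))
  expect_equal(sum(lengths(single)), 0L)
})

test_that("structure search recovers a strong chain's skeleton", {
  d <- sampleChainData(1000, seed = 21)
  dag <- greedyStructureSearch(d)
  expect_setequal(skeletonOf(dag), c("A-B", "B-C"))
})

test_that("maximum-likelihood CPTs are conditional frequencies", {
  d <- cbind(A = c(rep(1, 7), rep(0, 3)))
  bn <- fitCPTs(list(A = character(0)), d)
  expect_equal(unname(bn@cpts$A[1, ]), c(0.3, 0.7))
  # rows sum to one on a random learned net
  set.seed(12)
  d3 <- sampleChainData(200, seed = 12)
  bn3 <- fitCPTs(list(A = character(0), B = "A", C = "B"), d3)
  for (v in bn3@nodes)
    expect_equal(unname(rowSums(bn3@cpts[[v]])), rep(1, nrow(bn3@cpts[[v]])))
  # unseen parent configuration falls back to a uniform row
  d4 <- cbind(A = c(0, 0, 0, 1), B = c(0, 1, 1, 0), C = c(0, 1, 0, 1))
  bn4 <- fitCPTs(list(A = character(0), B = character(0), C = c("A", "B")),
                 d4)
  # parent config (A=1, B=1) never occurs
  expect_equal(unname(bn4@cpts$C[4, ]), c(0.5, 0.5))
})

test_that("joint probabilities factorize and normalize", {
  # hand-built chain A -> B with P(A=1)=0.6, P(B=1|A)=0.5 both ways
  bn <- new("DiscreteBayesNet", nodes = c("A", "B"),
            states = list(A = 0:1, B = 0:1),
            parents = list(A = character(0), B = "A"),
            cpts = list(A = matrix(c(0.4, 0.6), 1),
                        B = matrix(c(0.5, 0.5, 0.5, 0.5), 2)))
  expect_equal(jointProbability(bn, c(A = 1, B = 1)), 0.3)
  total <- sum(vapply(0:3, function(i)
    jointProbability(bn, c(A = i %% 2, B = i %/% 2)), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-9)
  # an edgeless net multiplies marginals
  bn2 <- new("DiscreteBayesNet", nodes = c("A", "B"),
             states = list(A = 0:1, B = 0:1),
             parents = list(A = character(0), B = character(0)),
             cpts = list(A = matrix(c(0.3, 0.7), 1),
                         B = matrix(c(0.8, 0.2), 1)))
  expect_equal(jointProbability(bn2, c(A = 1, B = 0)), 0.7 * 0.8)
  expect_error(jointProbability(bn, c(A = 1)), "every node")
  expect_error(jointProbability(bn, c(A = 5, B = 0)), "out of range")
  # normalization holds for any randomly parameterized net
  for (s in 1:3) {
    rbn <- randomBayesNet(4, seed = 100 + s)
    cards <- vapply(rbn@states, length, integer(1))
    grid <- expand.grid(lapply(cards, function(r) 0:(r - 1)))
    names(grid) <- rbn@nodes
    tot <- sum(apply(grid, 1, function(row)
      jointProbability(rbn, setNames(as.numeric(row), rbn@nodes))))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("variable elimination equals joint enumeration on random nets", {
  set.seed(5)
  for (s in 1:6) {
    nNodes <- sample(3:10, 1)
    bn <- randomBayesNet(nNodes, seed = 500 + s)
    nodes <- bn@nodes
    query <- sample(nodes, sample(1:2, 1))
    rest <- setdiff(nodes, query)
    evidence <- NULL
    if (length(rest) > 0 && runif(1) < 0.7) {
      ev <- sample(rest, 1)
      evidence <- setNames(sample(bn@states[[ev]], 1), ev)
    }
    got <- queryMarginal(bn, query, evidence)
    want <- enumerateMarginal(bn, query, evidence)
    expect_false(got$zeroEvidence)
    expect_equal(as.numeric(got$probabilities), as.numeric(want),
                 tolerance = 1e-9)
  }
})

test_that("marginal queries handle priors, full evidence and contradictions", {
  bn <- randomBayesNet(4, seed = 77)
  roots <- bn@nodes[lengths(bn@parents[bn@nodes]) == 0]
  r <- roots[1]
  # no evidence on a root: its prior CPT row
  got <- queryMarginal(bn, r)
  expect_equal(as.numeric(got$probabilities),
               as.numeric(bn@cpts[[r]][1, ]), tolerance = 1e-12)
  # evidence fixing everything but the query: still a distribution
  others <- setdiff(bn@nodes, r)
  ev <- vapply(others, function(v) bn@states[[v]][1], numeric(1))
  got2 <- queryMarginal(bn, r, ev)
  expect_equal(sum(got2$probabilities), 1, tolerance = 1e-9)
  # impossible evidence is flagged, not silently normalized
  bnDet <- new("DiscreteBayesNet", nodes = c("A", "B"),
               states = list(A = 0:1, B = 0:1),
               parents = list(A = character(0), B = "A"),
               cpts = list(A = matrix(c(0, 1), 1),
                           B = matrix(c(1, 0, 0, 1), 2)))
  bad <- queryMarginal(bnDet, "B", c(A = 0))
  expect_true(bad$zeroEvidence)
  expect_error(queryMarginal(bn, r, setNames(0, r)), "disjoint")
})

test_that("chain skeleton recovery is reliable across seeded replicates", {
  hits <- vapply(1:20, function(s) {
    d <- sampleChainData(1000, seed = 3000 + s)
    setequal(skeletonOf(greedyStructureSearch(d)), c("A-B", "B-C"))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("network export produces valid DOT and JSON artifacts", {
  d <- sampleChainData(300, seed = 9)
  bn <- fitCPTs(greedyStructureSearch(d), d)
  dot <- withr::local_tempfile(fileext = ".dot")
  js <- withr::local_tempfile(fileext = ".json")
  writeNetworkDOT(bn, dot)
  txt <- readLines(dot)
  expect_equal(txt[1], "digraph syndromes {")
  expect_true(any(grepl("->", txt)))
  writeNetworkJSON(bn, js)
  parsed <- jsonlite::read_json(js)
  expect_length(parsed, 3)
  expect_setequal(vapply(parsed, function(x) x$node, character(1)),
                  c("A", "B", "C"))
})
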