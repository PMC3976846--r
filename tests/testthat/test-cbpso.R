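# simple separable toy fitness over D bits with optimum `target`
toyFitness <- function(target, costPerBit = 0.05) {
  force(target)
  function(pos) {
    if (sum(pos) == 0) return(Inf)
    sum((pos - target)^2) + costPerBit * sum(pos)
  }
}

test_that("logistic series follows the map and stays in [0, 1]", {
  expect_equal(logisticSeries(0.3, 2), c(0.84, 0.5376))
  expect_error(logisticSeries(0.5, 3), "degenerate")
  expect_error(logisticSeries(0.25, 3), "degenerate")
  expect_error(logisticSeries(0, 3), "inside")
  expect_error(logisticSeries(1.2, 3), "inside")
  set.seed(31)
  for (i in 1:25) {
    q0 <- runif(1)
    if (q0 %in% c(0.25, 0.5, 0.75) || q0 <= 0 || q0 >= 1) next
    s <- logisticSeries(q0, 200)
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("binarization threshold maps 0.5 and above to 1", {
  expect_equal(SyndromeSelect:::binarize(c(0.49, 0.5, 0.51, 0, 1)),
               c(0, 1, 1, 0, 1))
})

test_that("inertia weight starts at ws and decays nonlinearly to its floor", {
  cfg <- swarmConfig(D = 5, N = 4, tMax = 100, k = 10)
  expect_equal(inertiaWeight(0, cfg), 1.2)
  expect_equal(inertiaWeight(100, cfg), 0.4 * 3^(1 / 11),
               tolerance = 1e-12)
  w <- vapply(0:100, inertiaWeight, numeric(1), config = cfg)
  expect_true(all(diff(w) <= 0))
})

test_that("sigmoid transfer is centred at 0.5 with saturating tails", {
  expect_equal(SyndromeSelect:::sigmoid(0), 0.5)
  expect_equal(SyndromeSelect:::sigmoid(6), 1 / (1 + exp(-6)))
  expect_equal(SyndromeSelect:::sigmoid(6), 0.99753, tolerance = 1e-5)
})

test_that("reinitialization schedule starts at zero and grows", {
  expect_equal(reinitProbability(1), 0)
  expect_equal(reinitProbability(3), 1 - 1 / (1 + log(3)))
  expect_equal(reinitProbability(3), 0.5235, tolerance = 1e-4)
  p <- reinitProbability(1:200)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
  expect_error(reinitProbability(0), ">= 1")
})

test_that("chaotic initialization is deterministic and keeps the N fittest", {
  fn <- toyFitness(c(1, 0, 1, 0))
  cfg <- swarmConfig(D = 4, N = 6, k = 40, tMax = 5, seed = 12)
  s1 <- withr::with_seed(12, chaoticInit(cfg, fn))
  s2 <- withr::with_seed(12, chaoticInit(cfg, fn))
  expect_identical(s1, s2)
  expect_equal(dim(s1$positions), c(6L, 4L))
  expect_true(all(s1$velocities >= -6 & s1$velocities <= 6))
  expect_identical(s1$pbestPositions, s1$positions)
  # kept particles are at least as fit as any discarded chaotic candidate
  all40 <- withr::with_seed(12, SyndromeSelect:::chaoticCandidates(4, 40, 4))
  fits <- apply(all40, 1, fn)
  expect_lte(max(s1$pbestFitness), sort(fits)[6] + 1e-12)
  # boundary k = N keeps every candidate
  cfgAll <- swarmConfig(D = 4, N = 5, k = 5, tMax = 5, seed = 3)
  sAll <- withr::with_seed(3, chaoticInit(cfgAll, fn))
  expect_equal(nrow(sAll$positions), 5L)
})

test_that("subset fitness adds the weighted mean-fr penalty to CV error", {
  set.seed(17)
  n <- 80
  planted <- sample(0:3, n, replace = TRUE)
  noise <- sample(0:3, n, replace = TRUE)
  X <- cbind(A = planted, B = noise)
  ps <- 2 * planted + rnorm(n, 0, 0.2)
  fr <- c(0.1, 0.9)
  fn0 <- makeFitness(X, ps, fr, p = 1e-9, sigma2 = 10, gamma = 100,
                     foldSeed = 4)
  fnP <- makeFitness(X, ps, fr, p = 0.4, sigma2 = 10, gamma = 100,
                     foldSeed = 4)
  # empty subset can never win
  expect_identical(fn0(c(0, 0)), Inf)
  # the planted feature beats the noise feature
  expect_lt(fnP(c(1, 0)), fnP(c(0, 1)))
  # the penalty term is p * mean(fr) of the selection
  expect_equal(fnP(c(1, 1)) - fn0(c(1, 1)), 0.4 * 0.5, tolerance = 1e-7)
  # deterministic across repeated calls (cache or not)
  expect_identical(fnP(c(1, 0)), fnP(c(1, 0)))
})

test_that("swarm search finds the exhaustive optimum on small problems", {
  for (D in 3:4) {
    target <- c(1, 0, 1, 1)[1:D]
    fn <- toyFitness(target)
    oracle <- bruteForceBestSubset(fn, D)
    cfg <- swarmConfig(D = D, N = 10, tMax = 25, k = 60, seed = 5)
    fit <- runCBPSO(fn, cfg)
    expect_equal(bestPosition(fit), oracle$position)
    expect_equal(bestFitness(fit), oracle$fitness)
  }
})

test_that("a seeded run is exactly reproducible and leaves user RNG intact", {
  fn <- toyFitness(c(0, 1, 1))
  cfg <- swarmConfig(D = 3, N = 6, tMax = 10, k = 20, seed = 99)
  set.seed(1234)
  r1 <- runCBPSO(fn, cfg)
  drawAfter <- runif(1)
  set.seed(1234)
  r2 <- runCBPSO(fn, cfg)
  expect_identical(fitnessTrace(r1), fitnessTrace(r2))
  expect_identical(bestPosition(r1), bestPosition(r2))
  # the engine restores the caller's RNG stream
  expect_identical(drawAfter, runif(1))
})

test_that("gbest trace never increases and velocities respect the bounds", {
  set.seed(2)
  for (rep in 1:3) {
    D <- sample(4:8, 1)
    fn <- toyFitness(as.numeric(runif(D) < 0.5))
    cfg <- swarmConfig(D = D, N = 8, tMax = 30, k = 40,
                       seed = sample.int(1000, 1))
    fit <- runCBPSO(fn, cfg)
    expect_true(all(diff(fitnessTrace(fit)) <= 0))
    expect_true(all(fit@swarm$velocities >= cfg$vMin &
                      fit@swarm$velocities <= cfg$vMax))
    expect_equal(bestFitness(fit), min(fit@swarm$pbestFitness))
  }
})

test_that("with every enhancement disabled the engine is a standard BPSO", {
  fn <- toyFitness(c(1, 1, 0, 1))
  cfg <- swarmConfig(D = 4, N = 7, tMax = 12, k = 50, seed = 42,
                     chaotic = FALSE, rk = 0, pm = 0, eliteFraction = 0)
  engine <- runCBPSO(fn, cfg)
  ref <- referencePlainBPSO(fn, cfg)
  expect_identical(fitnessTrace(engine), ref$trace)
  expect_identical(bestPosition(engine), ref$position)
  expect_identical(bestFitness(engine), ref$fitness)
})

test_that("reinitialization respects its gate and schedule", {
  fn <- toyFitness(c(1, 0))
  cfg <- swarmConfig(D = 2, N = 4, tMax = 5, k = 10, rk = 0.3, seed = 1)
  state <- withr::with_seed(1, chaoticInit(cfg, fn))
  state$gbestPosition <- state$pbestPositions[1, ]
  state$gbestFitness <- state$pbestFitness[1]
  # currun = 1: schedule is zero, nothing can happen
  res <- withr::with_seed(2, maybeReinitialize(state, cfg, fn, currun = 1))
  expect_equal(res$count, 0L)
  expect_identical(res$state$positions, state$positions)
  # rk = 0 turns the stage off entirely
  cfg0 <- swarmConfig(D = 2, N = 4, tMax = 5, k = 10, rk = 0, seed = 1)
  res0 <- withr::with_seed(2, maybeReinitialize(state, cfg0, fn,
                                                currun = 50))
  expect_equal(res0$count, 0L)
  # empirical per-particle rate ~ rk * p_c(3) = 0.3 * 0.5235 ~ 0.157
  single <- state
  single$positions <- state$positions[1, , drop = FALSE]
  single$velocities <- state$velocities[1, , drop = FALSE]
  single$pbestPositions <- state$pbestPositions[1, , drop = FALSE]
  single$pbestFitness <- state$pbestFitness[1]
  hits <- withr::with_seed(7, sum(vapply(1:10000, function(i)
    maybeReinitialize(single, cfg, fn, currun = 3)$count, integer(1))))
  expect_equal(hits / 10000, 0.3 * reinitProbability(3), tolerance = 0.01)
})

test_that("gbest mutation only ever improves the global best", {
  fn <- toyFitness(c(1, 0, 1))
  state <- list(positions = rbind(c(0, 0, 1)), velocities = rbind(rep(0, 3)),
                pbestPositions = rbind(c(0, 0, 1)),
                pbestFitness = fn(c(0, 0, 1)),
                gbestPosition = c(0, 0, 1), gbestFitness = fn(c(0, 0, 1)))
  # pm = 0: no flip possible, gbest unchanged
  cfg0 <- swarmConfig(D = 3, N = 2, k = 5, tMax = 5, pm = 0)
  res <- withr::with_seed(3, mutateGbest(state, cfg0, fn))
  expect_false(res$adopted)
  expect_identical(res$state$gbestPosition, c(0, 0, 1))
  # a worsening candidate is rejected: force every bit to flip from the
  # optimum, which can only hurt
  opt <- list(positions = rbind(c(1, 0, 1)), velocities = rbind(rep(0, 3)),
              pbestPositions = rbind(c(1, 0, 1)),
              pbestFitness = fn(c(1, 0, 1)),
              gbestPosition = c(1, 0, 1), gbestFitness = fn(c(1, 0, 1)))
  cfg1 <- swarmConfig(D = 3, N = 2, k = 5, tMax = 5, pm = 1)
  res1 <- withr::with_seed(3, mutateGbest(opt, cfg1, fn))
  expect_false(res1$adopted)
  expect_identical(res1$state$gbestFitness, fn(c(1, 0, 1)))
  # one bit from the optimum with pm = 1/D finds it within 100 attempts
  cur <- c(0, 0, 1)
  st <- list(positions = rbind(cur), velocities = rbind(rep(0, 3)),
             pbestPositions = rbind(cur), pbestFitness = fn(cur),
             gbestPosition = cur, gbestFitness = fn(cur))
  cfgD <- swarmConfig(D = 3, N = 2, k = 5, tMax = 5, pm = 1 / 3)
  found <- withr::with_seed(11, {
    hit <- FALSE
    for (i in 1:100) {
      r <- mutateGbest(st, cfgD, fn)
      st <- r$state
      if (identical(st$gbestPosition, c(1, 0, 1))) { hit <- TRUE; break }
    }
    hit
  })
  expect_true(found)
})

test_that("elitist refresh keeps the swarm size and never loses the gbest", {
  fn <- toyFitness(c(1, 0, 1, 0, 1))
  cfg <- swarmConfig(D = 5, N = 10, k = 30, tMax = 5, eliteFraction = 0.3,
                     seed = 8)
  state <- withr::with_seed(8, chaoticInit(cfg, fn))
  i0 <- which.min(state$pbestFitness)
  state$gbestPosition <- state$pbestPositions[i0, ]
  state$gbestFitness <- state$pbestFitness[i0]
  before <- state$gbestFitness
  res <- withr::with_seed(9, elitistRefresh(state, cfg, fn))
  expect_equal(nrow(res$positions), 10L)
  expect_lte(res$gbestFitness, before)
  # the pbest record holding the gbest is untouched
  expect_equal(min(res$pbestFitness), res$gbestFitness)
  # eliteFraction = 0 is a no-op
  cfg0 <- swarmConfig(D = 5, N = 10, k = 30, tMax = 5, eliteFraction = 0,
                      seed = 8)
  res0 <- withr::with_seed(9, elitistRefresh(state, cfg0, fn))
  expect_identical(res0$positions, state$positions)
})

test_that("solution decoding maps bits to names", {
  nm <- c("a", "b", "c")
  expect_equal(decodeSolution(c(1, 0, 1), nm), c("a", "c"))
  expect_equal(decodeSolution("101", nm), c("a", "c"))
  expect_length(decodeSolution(c(0, 0, 0), nm), 0)
  expect_equal(decodeSolution(c(1, 1, 1), nm), nm)
  expect_error(decodeSolution(c(1, 0), nm), "match")
})
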