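#' @include AllClasses.R AllGenerics.R lssvr.R
NULL

#' Swarm configuration for chaotic binary PSO
#'
#' All tunables of the search engine. Defaults follow the method's
#' published settings where stated (velocity bounds \eqn{\pm 6}, inertia
#' 1.2 to 0.4 with shape constant \eqn{c_3 = 10}, reinitialization gate
#' `rk = 0.3`, chaotic series length `k = 500` with logistic control
#' \eqn{\mu = 4}, global-best mutation after 10 stagnant iterations) and
#' standard PSO practice elsewhere (`c1 = c2 = 2`).
#'
#' @param D number of dimensions (candidate features).
#' @param N swarm size (must not exceed `k`).
#' @param tMax number of generations.
#' @param c1,c2 cognitive / social acceleration constants.
#' @param c3 inertia decay shape constant.
#' @param vMin,vMax velocity clamp bounds.
#' @param ws,wl initial / final inertia weight (`ws > wl`).
#' @param rk reinitialization gate probability in `[0, 1]`.
#' @param p fitness weight of the mean-fr relevance term, in `(0, 1)`.
#' @param k chaotic series length for initialization.
#' @param mu logistic-map control parameter (4 = fully chaotic regime).
#' @param stagnationMutate stagnant iterations before global-best mutation.
#' @param stagnationElite stagnant iterations before elitist refresh.
#' @param eliteFraction share of the swarm replaced by an elitist refresh.
#' @param pm per-bit mutation probability for the global best; `NULL`
#'   means `1/D`.
#' @param chaotic use chaotic initialization (`FALSE` gives plain random
#'   initialization, the standard-BPSO baseline).
#' @param seed integer seed controlling every stochastic draw of the run.
#' @return list of class `swarmConfig`.
#' @export
swarmConfig <- function(D, N = 100L, tMax = 100L, c1 = 2, c2 = 2, c3 = 10,
                        vMin = -6, vMax = 6, ws = 1.2, wl = 0.4, rk = 0.3,
                        p = 0.2, k = 500L, mu = 4,
                        stagnationMutate = 10L, stagnationElite = 20L,
                        eliteFraction = 0.2, pm = NULL, chaotic = TRUE,
                        seed = 1L) {
  stopifnot(ws > wl, vMin < vMax, p > 0, p < 1, N >= 2, D >= 1,
            rk >= 0, rk <= 1, eliteFraction >= 0, eliteFraction <= 1)
  if (chaotic && N > k)
    stop("swarm size N must not exceed the chaotic series length k")
  structure(list(D = as.integer(D), N = as.integer(N),
                 tMax = as.integer(tMax), c1 = c1, c2 = c2, c3 = c3,
                 vMin = vMin, vMax = vMax, ws = ws, wl = wl, rk = rk,
                 p = p, k = as.integer(k), mu = mu,
                 stagnationMutate = as.integer(stagnationMutate),
                 stagnationElite = as.integer(stagnationElite),
                 eliteFraction = eliteFraction,
                 pm = pm %||% 1 / D, chaotic = chaotic,
                 seed = as.integer(seed)),
            class = "swarmConfig")
}

#' Logistic-map chaotic series
#'
#' Iterates \eqn{q_{k+1} = \mu q_k (1 - q_k)} from a starting value in
#' `(0, 1)`. At \eqn{\mu = 4} the map is fully chaotic; the fixed/periodic
#' seeds 0.25, 0.5 and 0.75 collapse the orbit and are rejected.
#'
#' @param q0 starting value in `(0, 1)`, not one of 0.25, 0.5, 0.75.
#' @param k number of iterates to produce.
#' @param mu control parameter.
#' @return numeric vector of `k` iterates, all in `[0, 1]`.
#' @examples
#' logisticSeries(0.3, 2)  # 0.84, 0.5376
#' @export
logisticSeries <- function(q0, k, mu = 4) {
  if (q0 <= 0 || q0 >= 1) stop("q0 must lie strictly inside (0, 1)")
  if (q0 %in% c(0.25, 0.5, 0.75))
    stop("degenerate logistic seed (0.25, 0.5, 0.75)")
  out <- numeric(k)
  q <- q0
  for (i in seq_len(k)) {
    q <- mu * q * (1 - q)
    out[i] <- q
  }
  out
}

# draw a vector of admissible logistic seeds (resampling degenerate values)
drawChaoticSeeds <- function(D) {
  q0 <- stats::runif(D)
  bad <- q0 %in% c(0.25, 0.5, 0.75) | q0 <= 0 | q0 >= 1
  while (any(bad)) {
    q0[bad] <- stats::runif(sum(bad))
    bad <- q0 %in% c(0.25, 0.5, 0.75) | q0 <= 0 | q0 >= 1
  }
  q0
}

# k x D matrix of candidate binary vectors from D chaotic trajectories
chaoticCandidates <- function(D, k, mu) {
  q0 <- drawChaoticSeeds(D)
  traj <- vapply(q0, logisticSeries, numeric(k), k = k, mu = mu)
  matrix(binarize(traj), k, D)
}

#' Nonlinearly decaying inertia weight
#'
#' \eqn{w(t) = w_l (w_s / w_l)^{1 / (1 + c_3 t / t_{max})}}: equals `ws`
#' at `t = 0` and decays towards `wl`, supporting global search early and
#' local search late.
#'
#' @param t current iteration, `0 <= t <= tMax`.
#' @param config a [swarmConfig()].
#' @return the inertia weight.
#' @export
inertiaWeight <- function(t, config) {
  config$wl * (config$ws / config$wl)^(1 / (1 + config$c3 * t / config$tMax))
}

#' Reinitialization schedule probability
#'
#' \eqn{p_c = 1 - 1 / (1 + \ln(\mathrm{currun}))}: zero at the first
#' iteration and increasing towards 1, so swarm reinitialization becomes
#' more likely the longer the run, counteracting premature convergence.
#'
#' @param currun current iteration number (>= 1).
#' @return probability in `[0, 1)`.
#' @export
reinitProbability <- function(currun) {
  if (any(currun < 1)) stop("currun must be >= 1")
  1 - 1 / (1 + log(currun))
}

#' Build the subset-fitness function for syndrome selection
#'
#' Fitness of a candidate subset (binary position) is the seeded 5-fold
#' cross-validated LS-SVR MSE on the selected syndrome columns plus `p`
#' times the mean fr relevance score of the selected features:
#' \deqn{\mathrm{fit}(X_i) = \mathrm{pdterror}(X_i) + p \cdot
#'       \mathrm{mfr}(X_i).}
#' The empty subset receives `+Inf` so it can never become the global
#' best. Per-feature squared-distance slices and a position cache make
#' repeated evaluations cheap; the fold assignment is fixed once so every
#' evaluation within a run is comparable and deterministic.
#'
#' @param syndromes numeric matrix, samples x features.
#' @param ps positive-score target vector.
#' @param fr per-feature relevance scores (see [frScores()]).
#' @param p weight of the relevance term.
#' @param sigma2,gamma frozen LS-SVR hyperparameters.
#' @param folds number of CV folds (default 5).
#' @param foldSeed seed for the fold assignment.
#' @return function mapping a binary position vector to its fitness.
#' @export
makeFitness <- function(syndromes, ps, fr, p, sigma2, gamma, folds = 5L,
                        foldSeed = 1L) {
  syndromes <- as.matrix(syndromes)
  D <- ncol(syndromes)
  stopifnot(length(fr) == D, length(ps) == nrow(syndromes))
  foldIdx0 <- lapply(makeFolds(length(ps), folds, foldSeed),
                     function(te) as.integer(te) - 1L)
  ps <- as.numeric(ps)
  cache <- new.env(parent = emptyenv())
  function(position) {
    sel <- which(position == 1)
    if (length(sel) == 0L) return(Inf)
    key <- bitKey(position)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- cvMSESubsetCpp(syndromes[, sel, drop = FALSE], ps, sigma2,
                          gamma, foldIdx0) + p * mean(fr[sel])
    cache[[key]] <- val
    val
  }
}

# one full swarm-state audit helper: gbest = min over pbest
refreshGbest <- function(state) {
  i <- which.min(state$pbestFitness)
  if (state$pbestFitness[i] < state$gbestFitness) {
    state$gbestFitness <- state$pbestFitness[i]
    state$gbestPosition <- state$pbestPositions[i, ]
    state$improved <- TRUE
  }
  state
}

#' Chaotic initialization of the particle swarm
#'
#' Runs `D` independent logistic-map trajectories of length `k`; candidate
#' binary vector `j` thresholds the `j`-th iterate of every trajectory at
#' 0.5 (iterates >= 0.5 become 1). The `N` candidates with the smallest
#' fitness become the initial swarm; velocities are initialized uniformly
#' within the velocity bounds and each particle's personal best is its
#' initial position.
#'
#' @param config a [swarmConfig()].
#' @param fitnessFn function from binary position to fitness.
#' @return list with `positions`, `velocities`, `pbestPositions` (N x D
#'   matrices) and `pbestFitness` (length N). Draws from the current RNG
#'   stream; seed externally (or via [runCBPSO()]) for reproducibility.
#' @export
chaoticInit <- function(config, fitnessFn) {
  N <- config$N; D <- config$D; k <- config$k
  cand <- chaoticCandidates(D, k, config$mu)
  fit <- apply(cand, 1, fitnessFn)
  keep <- order(fit, seq_along(fit))[seq_len(N)]   # ties: first candidate
  positions <- cand[keep, , drop = FALSE]
  velocities <- matrix(stats::runif(N * D, config$vMin, config$vMax), N, D)
  list(positions = positions, velocities = velocities,
       pbestPositions = positions, pbestFitness = fit[keep])
}

randomInit <- function(config, fitnessFn) {
  N <- config$N; D <- config$D
  positions <- matrix(binarize(stats::runif(N * D)), N, D)
  velocities <- matrix(stats::runif(N * D, config$vMin, config$vMax), N, D)
  fit <- apply(positions, 1, fitnessFn)
  list(positions = positions, velocities = velocities,
       pbestPositions = positions, pbestFitness = fit)
}

#' Run the chaotic binary particle swarm search
#'
#' Executes chaotic (or plain random) initialization followed by `tMax`
#' generations of: sigmoid-transfer velocity/position update with
#' nonlinearly decaying inertia, fitness evaluation, personal/global best
#' update, probabilistic swarm reinitialization (gate `rk` times the
#' schedule [reinitProbability()]), global-best bit mutation after
#' `stagnationMutate` stagnant iterations (improvement-only acceptance)
#' and an elitist refresh of the worst particles after `stagnationElite`
#' stagnant iterations. The global-best fitness trace is non-increasing.
#'
#' Setting `chaotic = FALSE`, `rk = 0`, `pm = 0` and `eliteFraction = 0`
#' disables every enhancement and leaves a standard binary PSO — the
#' plain-wrapper baseline.
#'
#' @param fitnessFn function from binary position (length `D`) to fitness
#'   (smaller is better); see [makeFitness()].
#' @param config a [swarmConfig()].
#' @return A [SwarmFit-class].
#' @export
runCBPSO <- function(fitnessFn, config) {
  withSeed(config$seed, {
    N <- config$N; D <- config$D
    state <- if (config$chaotic) chaoticInit(config, fitnessFn)
             else randomInit(config, fitnessFn)
    i0 <- which.min(state$pbestFitness)
    state$gbestPosition <- state$pbestPositions[i0, ]
    state$gbestFitness <- state$pbestFitness[i0]
    stagnation <- 0L
    trace <- numeric(config$tMax)
    events <- list()
    log_event <- function(t, type, detail = NULL)
      events[[length(events) + 1L]] <<- list(iteration = t, type = type,
                                             detail = detail)
    for (t in seq_len(config$tMax)) {
      w <- inertiaWeight(t, config)
      state$improved <- FALSE
      for (i in seq_len(N)) {
        r1 <- stats::runif(D); r2 <- stats::runif(D)
        v <- w * state$velocities[i, ] +
          config$c1 * r1 * (state$pbestPositions[i, ] -
                              state$positions[i, ]) +
          config$c2 * r2 * (state$gbestPosition - state$positions[i, ])
        v <- clamp(v, config$vMin, config$vMax)
        u <- stats::runif(D)
        x <- as.numeric(u < sigmoid(v))
        state$velocities[i, ] <- v
        state$positions[i, ] <- x
        f <- fitnessFn(x)
        if (f < state$pbestFitness[i]) {
          state$pbestFitness[i] <- f
          state$pbestPositions[i, ] <- x
        }
      }
      state <- refreshGbest(state)
      if (config$rk > 0 && t > 1) {
        res <- maybeReinitialize(state, config, fitnessFn, currun = t)
        if (res$count > 0) log_event(t, "reinit", res$count)
        state <- res$state
      }
      stagnation <- if (state$improved) 0L else stagnation + 1L
      if (config$pm > 0 && stagnation >= config$stagnationMutate) {
        res <- mutateGbest(state, config, fitnessFn)
        if (res$adopted) {
          log_event(t, "gbest_mutation")
          stagnation <- 0L
        }
        state <- res$state
      }
      if (config$eliteFraction > 0 &&
          stagnation >= config$stagnationElite) {
        state <- elitistRefresh(state, config, fitnessFn)
        log_event(t, "elitist_refresh")
        stagnation <- 0L
      }
      trace[t] <- state$gbestFitness
    }
    new("SwarmFit", position = state$gbestPosition,
        fitness = state$gbestFitness, trace = trace,
        swarm = state[c("positions", "velocities", "pbestPositions",
                        "pbestFitness")],
        events = events, config = unclass(config))
  })
}

#' Probabilistic swarm reinitialization
#'
#' Each particle is independently reinitialized (fresh random binary
#' position and velocity) with probability `rk * reinitProbability(currun)`.
#' Personal bests are kept and updated only when the fresh position
#' improves on them, so neither pbest nor gbest can worsen.
#'
#' @param state swarm state list (`positions`, `velocities`,
#'   `pbestPositions`, `pbestFitness`, `gbestPosition`, `gbestFitness`).
#' @param config a [swarmConfig()].
#' @param fitnessFn fitness function.
#' @param currun current iteration (>= 1).
#' @return list with updated `state` and `count` of reinitialized
#'   particles.
#' @export
maybeReinitialize <- function(state, config, fitnessFn, currun) {
  pr <- config$rk * reinitProbability(currun)
  count <- 0L
  for (i in seq_len(nrow(state$positions))) {
    if (stats::runif(1) < pr) {
      count <- count + 1L
      x <- binarize(stats::runif(config$D))
      state$positions[i, ] <- x
      state$velocities[i, ] <- stats::runif(config$D, config$vMin,
                                            config$vMax)
      f <- fitnessFn(x)
      if (f < state$pbestFitness[i]) {
        state$pbestFitness[i] <- f
        state$pbestPositions[i, ] <- x
      }
    }
  }
  if (count > 0) state <- refreshGbest(state)
  list(state = state, count = count)
}

#' Mutate the global best position
#'
#' Builds a candidate by flipping each global-best bit independently with
#' probability `pm` and adopts it only if its fitness strictly improves on
#' the current global best (so the global best never worsens).
#'
#' @inheritParams maybeReinitialize
#' @return list with updated `state` and logical `adopted`.
#' @export
mutateGbest <- function(state, config, fitnessFn) {
  flips <- stats::runif(config$D) < config$pm
  adopted <- FALSE
  if (any(flips)) {
    cand <- state$gbestPosition
    cand[flips] <- 1 - cand[flips]
    f <- fitnessFn(cand)
    if (f < state$gbestFitness) {
      state$gbestPosition <- cand
      state$gbestFitness <- f
      adopted <- TRUE
    }
  }
  list(state = state, adopted = adopted)
}

#' Elitist refresh of the worst particles
#'
#' Replaces the worst `ceiling(eliteFraction * N)` particles (by personal
#' best fitness) with chaotic-initialized newcomers to restore swarm
#' diversity; the particle holding the global best is never replaced and
#' the global best itself is unchanged or improved.
#'
#' @inheritParams maybeReinitialize
#' @return updated state.
#' @export
elitistRefresh <- function(state, config, fitnessFn) {
  N <- nrow(state$positions)
  r <- ceiling(config$eliteFraction * N)
  if (r == 0L) return(state)
  best <- which.min(state$pbestFitness)
  worst <- setdiff(order(state$pbestFitness, decreasing = TRUE), best)
  worst <- worst[seq_len(min(r, length(worst)))]
  cand <- chaoticCandidates(config$D, length(worst), config$mu)
  for (j in seq_along(worst)) {
    i <- worst[j]
    x <- cand[j, ]
    state$positions[i, ] <- x
    state$velocities[i, ] <- stats::runif(config$D, config$vMin,
                                          config$vMax)
    f <- fitnessFn(x)
    if (f < state$pbestFitness[i]) {
      state$pbestFitness[i] <- f
      state$pbestPositions[i, ] <- x
    }
  }
  refreshGbest(state)
}

#' Decode a binary position into feature names
#'
#' @param position binary vector, or a bitstring such as `"00110"`.
#' @param featureNames character vector, one name per dimension.
#' @return names of the selected (1) features, in order.
#' @examples
#' decodeSolution("101", c("a", "b", "c"))  # "a" "c"
#' @export
decodeSolution <- function(position, featureNames) {
  if (is.character(position) && length(position) == 1L)
    position <- as.integer(strsplit(position, "")[[1]])
  if (length(position) != length(featureNames))
    stop("position length must match the number of feature names")
  featureNames[position == 1]
}

#' @rdname accessors
#' @export
setMethod("bestPosition", "SwarmFit", function(x) x@position)

#' @rdname accessors
#' @export
setMethod("bestFitness", "SwarmFit", function(x) x@fitness)

#' @rdname accessors
#' @export
setMethod("fitnessTrace", "SwarmFit", function(x) x@trace)

setMethod("show", "SwarmFit", function(object) {
  cat("SwarmFit:", sum(object@position), "of", length(object@position),
      "features selected\n")
  cat("  gbest fitness:", format(object@fitness, digits = 6),
      " generations:", length(object@trace),
      " events:", length(object@events), "\n")
})

#' End-to-end syndrome selection on a hierarchy
#'
#' Convenience wrapper chaining the study protocol: one hyperparameter
#' grid search on the full syndrome set (10-fold CV) whose
#' \eqn{(\sigma^2, \gamma)} are then frozen for all fitness evaluations,
#' syndrome ranking for the fr relevance term, and the chaotic binary PSO
#' search with 5-fold CV fitness.
#'
#' @param hierarchy a [SyndromeHierarchy-class].
#' @param config a [swarmConfig()]; its `D` must equal the number of
#'   syndromes.
#' @param lssvr an [lssvrConfig()] for the grid search.
#' @param ranking optional precomputed ranking (from [rankSyndromes()])
#'   to reuse; computed when `NULL`.
#' @return list with `fit` (a [SwarmFit-class]), `selected` (character),
#'   `ranking` (data.frame) and `lssvr` (the frozen config).
#' @export
selectSyndromes <- function(hierarchy, config, lssvr = lssvrConfig(),
                            ranking = NULL) {
  X <- syndromeValues(hierarchy)
  ps <- positiveScore(hierarchy)
  stopifnot(config$D == ncol(X))
  tuned <- if (is.null(lssvr$sigma2) || is.null(lssvr$gamma))
    gridSearchLSSVR(X, ps, lssvr) else lssvr
  if (is.null(ranking)) {
    peCfg <- tuned
    peCfg$folds <- 5L
    ranking <- rankSyndromes(X, peCfg, ps = ps)
  }
  fitnessFn <- makeFitness(X, ps, ranking$fr, p = config$p,
                           sigma2 = tuned$sigma2, gamma = tuned$gamma,
                           folds = 5L, foldSeed = config$seed)
  fit <- runCBPSO(fitnessFn, config)
  list(fit = fit, selected = decodeSolution(fit@position, colnames(X)),
       ranking = ranking, lssvr = tuned)
}
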