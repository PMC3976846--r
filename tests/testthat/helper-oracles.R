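# Independent oracles and fixture builders used across the suite.

# Direct dense solve of the full (n+1) x (n+1) bordered LS-SVM system
# [[0, 1'], [1, K + I/gamma]] [b; alpha] = [0; y], with the kernel built
# entry-by-entry from rbfKernel. Independent of the package's
# Cholesky/Schur solver path.
referenceLSSVRSolve <- function(X, y, sigma2, gamma) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- rbfKernel(X[i, ], X[j, ], sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  sol <- solve(A, c(0, y))
  list(bias = sol[1], alpha = sol[-1], K = K)
}

referenceLSSVRPredict <- function(ref, Xtrain, Xnew, sigma2) {
  vapply(seq_len(nrow(Xnew)), function(q) {
    k <- vapply(seq_len(nrow(Xtrain)), function(i)
      rbfKernel(Xtrain[i, ], Xnew[q, ], sigma2), numeric(1))
    sum(ref$alpha * k) + ref$bias
  }, numeric(1))
}

# Independent re-implementation of the seeded fold loop (fold definition
# mirrors the documented contract: shuffled round-robin assignment).
referenceCvMSE <- function(X, y, sigma2, gamma, folds, seed) {
  n <- length(y)
  perm <- local({ set.seed(seed); sample.int(n) })
  assign <- split(perm, rep_len(seq_len(folds), n))
  errs <- vapply(assign, function(te) {
    tr <- setdiff(seq_len(n), te)
    ref <- referenceLSSVRSolve(X[tr, , drop = FALSE], y[tr], sigma2, gamma)
    pred <- referenceLSSVRPredict(ref, X[tr, , drop = FALSE],
                                  X[te, , drop = FALSE], sigma2)
    mean((y[te] - pred)^2)
  }, numeric(1))
  mean(errs)
}

# Exhaustive search over all non-empty subsets of D features.
bruteForceBestSubset <- function(fitnessFn, D) {
  best <- NULL
  for (m in 1:(2^D - 1)) {
    pos <- as.numeric(bitwAnd(m, 2^(seq_len(D) - 1)) > 0)
    f <- fitnessFn(pos)
    if (is.null(best) || f < best$fitness)
      best <- list(position = pos, fitness = f)
  }
  best
}

# A small hand-checkable symptom table: 6 samples, 3 groups
# (exclusive size 2, concurrent size 3, concurrent size 1).
tinySymptomData <- function() {
  values <- cbind(
    lipA = c(1, 0, 0, 1, 0, 1),
    lipB = c(0, 1, 0, 0, 0, 0),
    emo1 = c(2, 0, 1, 0, 3, 1),
    emo2 = c(0, 1, 1, 0, 2, 0),
    emo3 = c(1, 1, 0, 0, 0, 2),
    odor = c(0, 2, 1, 1, 0, 0))
  ps <- c(5, 4, 2, 3, 6, 7)
  list(table = SymptomTable(values, ps),
       grouping = SyndromeGrouping(
         names = c("lip", "emotion", "odor"),
         members = list(c("lipA", "lipB"), c("emo1", "emo2", "emo3"),
                        "odor"),
         exclusive = c(TRUE, FALSE, FALSE)),
       # lipA positive in rows 1,4,6 (3 samples), lipB in row 2 (1 sample)
       # -> codes lipA = 2, lipB = 1
       expectedSyndromes = cbind(
         lip = c(2, 1, 0, 2, 0, 2),
         emotion = c(3, 2, 2, 0, 5, 3),
         odor = c(0, 2, 1, 1, 0, 0)))
}

# Random discrete Bayesian network with given node count; states 0..card-1.
randomBayesNet <- function(nNodes, seed, maxCard = 3, edgeProb = 0.35) {
  set.seed(seed)
  nodes <- paste0("X", seq_len(nNodes))
  ord <- sample(nodes)                 # topological order
  parents <- setNames(rep(list(character(0)), nNodes), nodes)
  for (i in seq_len(nNodes)) for (j in seq_len(nNodes)) {
    if (i < j && runif(1) < edgeProb)
      parents[[ord[j]]] <- c(parents[[ord[j]]], ord[i])
  }
  cards <- setNames(sample(2:maxCard, nNodes, replace = TRUE), nodes)
  states <- lapply(cards, function(r) 0:(r - 1))
  cpts <- lapply(nodes, function(v) {
    np <- prod(c(1, cards[parents[[v]]]))
    m <- matrix(runif(np * cards[[v]], 0.05, 1), np, cards[[v]])
    m / rowSums(m)
  })
  names(cpts) <- nodes
  new("DiscreteBayesNet", nodes = nodes, states = states,
      parents = parents, cpts = cpts)
}

# Brute-force posterior by full joint enumeration, reading CPT entries
# directly (independent of both jointProbability and variable elimination).
enumerateMarginal <- function(bn, query, evidence = NULL) {
  nodes <- bn@nodes
  cards <- vapply(bn@states, length, integer(1))[nodes]
  grid <- expand.grid(lapply(cards, function(r) 0:(r - 1)))
  names(grid) <- nodes
  probs <- apply(grid, 1, function(row) {
    p <- 1
    for (v in nodes) {
      pa <- bn@parents[[v]]
      ri <- 1
      if (length(pa) > 0) {
        mult <- cumprod(c(1, cards[pa]))[seq_along(pa)]
        ri <- sum(row[pa] * mult) + 1
      }
      p <- p * bn@cpts[[v]][ri, row[[v]] + 1]
    }
    p
  })
  if (!is.null(evidence)) {
    for (e in names(evidence)) {
      k <- match(evidence[[e]], bn@states[[e]]) - 1
      probs[grid[[e]] != k] <- 0
    }
  }
  z <- sum(probs)
  if (z == 0) return(NULL)
  qCards <- cards[query]
  out <- array(0, dim = qCards)
  for (r in seq_len(nrow(grid))) {
    idx <- matrix(unlist(grid[r, query]) + 1, 1)
    out[idx] <- out[idx] + probs[r]
  }
  out / z
}

# Sample n rows from a 3-node chain A -> B -> C with strong dependencies.
sampleChainData <- function(n, seed) {
  set.seed(seed)
  A <- rbinom(n, 1, 0.5)
  B <- ifelse(A == 1, rbinom(n, 1, 0.9), rbinom(n, 1, 0.1))
  C <- ifelse(B == 1, rbinom(n, 1, 0.85), rbinom(n, 1, 0.15))
  cbind(A = A, B = B, C = C)
}

# Undirected skeleton of a parents-list DAG as a sorted "a-b" edge set.
skeletonOf <- function(parents) {
  edges <- character(0)
  for (v in names(parents)) for (p in parents[[v]])
    edges <- c(edges, paste(sort(c(v, p)), collapse = "-"))
  sort(unique(edges))
}

# Reference standard binary PSO (no chaos, no reinit, no mutation, no
# elitism), mirroring the engine's documented draw order so a seeded run
# must match the full engine with those stages disabled.
referencePlainBPSO <- function(fitnessFn, config) {
  set.seed(config$seed)
  N <- config$N; D <- config$D
  pos <- matrix(as.numeric(runif(N * D) >= 0.5), N, D)
  vel <- matrix(runif(N * D, config$vMin, config$vMax), N, D)
  pfit <- apply(pos, 1, fitnessFn)
  ppos <- pos
  gi <- which.min(pfit)
  gpos <- ppos[gi, ]; gfit <- pfit[gi]
  trace <- numeric(config$tMax)
  for (t in seq_len(config$tMax)) {
    w <- config$wl * (config$ws / config$wl)^(1 / (1 + config$c3 * t /
                                                     config$tMax))
    for (i in seq_len(N)) {
      r1 <- runif(D); r2 <- runif(D)
      v <- w * vel[i, ] + config$c1 * r1 * (ppos[i, ] - pos[i, ]) +
        config$c2 * r2 * (gpos - pos[i, ])
      v <- pmin(pmax(v, config$vMin), config$vMax)
      u <- runif(D)
      x <- as.numeric(u < 1 / (1 + exp(-v)))
      vel[i, ] <- v; pos[i, ] <- x
      f <- fitnessFn(x)
      if (f < pfit[i]) { pfit[i] <- f; ppos[i, ] <- x }
    }
    mi <- which.min(pfit)
    if (pfit[mi] < gfit) { gfit <- pfit[mi]; gpos <- ppos[mi, ] }
    trace[t] <- gfit
  }
  list(position = gpos, fitness = gfit, trace = trace)
}
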