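#' @include AllClasses.R
NULL

#' Discretize a syndrome column for network learning
#'
#' Columns with at most four distinct values pass through unchanged.
#' Otherwise the number of intervals is
#' \eqn{itvnum = \lfloor \log_2(u) \rfloor + 1} for \eqn{u} distinct
#' values, and each value maps to the bin index
#' \eqn{\min(\lfloor v \cdot itvnum / \max(v) \rfloor, itvnum - 1)}, so
#' exactly `itvnum` labels (0-based) are producible and zero maps to
#' bin 0. A constant column is treated as pass-through.
#'
#' @param column numeric vector of non-negative values.
#' @return list with `values` (the discretized column) and `spec` (list
#'   with `passThrough`, `itvnum`, `maxValue`).
#' @export
discretizeColumn <- function(column) {
  if (any(column < 0)) stop("values must be non-negative")
  u <- length(unique(column))
  if (u <= 4L) {
    return(list(values = column,
                spec = list(passThrough = TRUE, itvnum = u,
                            maxValue = max(column))))
  }
  itvnum <- floor(log2(u)) + 1
  mx <- max(column)
  bins <- pmin(floor(column * itvnum / mx), itvnum - 1)
  list(values = bins,
       spec = list(passThrough = FALSE, itvnum = itvnum, maxValue = mx))
}

#' Discretize a full table of syndrome columns
#'
#' @param X numeric matrix, samples x variables.
#' @return list with `data` (matrix of discretized columns) and `specs`
#'   (per-column discretization specs, see [discretizeColumn()]).
#' @export
discretizeTable <- function(X) {
  X <- as.matrix(X)
  out <- lapply(seq_len(ncol(X)), function(j) discretizeColumn(X[, j]))
  data <- vapply(out, function(o) o$values, numeric(nrow(X)))
  data <- matrix(data, nrow(X), ncol(X), dimnames = dimnames(X))
  specs <- lapply(out, function(o) o$spec)
  names(specs) <- colnames(X)
  list(data = data, specs = specs)
}

#' Persist a discretization specification as JSON
#' @param specs the `specs` element returned by [discretizeTable()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeDiscretizationSpec <- function(specs, path) {
  jsonlite::write_json(specs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# map data columns to 0-based state indices; states = sorted unique values
dataToStates <- function(data) {
  data <- as.matrix(data)
  states <- lapply(seq_len(ncol(data)), function(j) sort(unique(data[, j])))
  names(states) <- colnames(data)
  idx <- vapply(seq_len(ncol(data)), function(j)
    match(data[, j], states[[j]]) - 1L, integer(nrow(data)))
  idx <- matrix(idx, nrow(data), ncol(data), dimnames = dimnames(data))
  list(idx = idx, states = states)
}

# counts of (parent configuration, child state) for one family; parents'
# mixed-radix index has the FIRST parent varying fastest
familyCounts <- function(idx, cards, child, parents) {
  n <- nrow(idx)
  rc <- cards[[child]]
  if (length(parents) == 0L) {
    pconf <- rep(0L, n)
    np <- 1L
  } else {
    np <- prod(unlist(cards[parents]))
    mult <- cumprod(c(1, unlist(cards[parents])))[seq_along(parents)]
    pconf <- as.integer(idx[, parents, drop = FALSE] %*% mult)
  }
  counts <- matrix(0, np, rc)
  tab <- tabulate(pconf * rc + idx[, child] + 1L, nbins = np * rc)
  # tabulate index: child state varies fastest within a parent config
  matrix(tab, np, rc, byrow = TRUE)
}

# BIC family score: log-likelihood minus 0.5 log(n) * free parameters
familyBIC <- function(idx, cards, child, parents, n) {
  counts <- familyCounts(idx, cards, child, parents)
  rowTot <- rowSums(counts)
  pos <- counts > 0
  ll <- sum(counts[pos] * log(counts[pos] /
                                rowTot[row(counts)[pos]]))
  nparams <- (cards[[child]] - 1) * nrow(counts)
  ll - 0.5 * log(n) * nparams
}

#' BIC score of a DAG on discrete data
#'
#' Decomposable score: the sum over nodes of the family log-likelihood at
#' the maximum-likelihood CPT minus the penalty
#' \eqn{\frac{1}{2}\log(n)} times the number of free parameters of the
#' family. Used as the objective of [greedyStructureSearch()].
#'
#' @param parents named list mapping each variable to its parent names
#'   (empty character vector for roots).
#' @param data matrix or data.frame of discrete values, columns named.
#' @return the total BIC score (larger is better).
#' @export
bicScore <- function(parents, data) {
  ds <- dataToStates(data)
  nodes <- colnames(ds$idx)
  if (!setequal(names(parents), nodes))
    stop("parents must be keyed by every data column")
  if (!isAcyclic(parents, nodes)) stop("graph must be acyclic")
  cards <- lapply(ds$states, length)
  n <- nrow(ds$idx)
  sum(vapply(nodes, function(j)
    familyBIC(ds$idx, cards, j, parents[[j]], n), numeric(1)))
}

# is there a directed path from `from` to `to`?
hasPath <- function(parents, from, to) {
  children <- function(v) names(parents)[vapply(parents, function(p)
    v %in% p, logical(1))]
  seen <- character(0)
  stack <- from
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    if (v == to) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, children(v))
  }
  FALSE
}

#' Greedy two-phase score-based structure search
#'
#' A forward phase repeatedly applies the single edge addition that most
#' improves the BIC score (respecting acyclicity and the parent limit)
#' until no addition improves it; a backward phase then repeatedly applies
#' the best score-improving edge deletion. Candidate edges are scanned in
#' lexicographic (from, to) order and only strictly better improvements
#' displace the incumbent, so ties break deterministically.
#'
#' @param data matrix or data.frame of discrete values, columns named.
#' @param maxParents parent limit per node (bounds CPT size).
#' @return named list of parent sets (the learned DAG).
#' @export
greedyStructureSearch <- function(data, maxParents = 4L) {
  data <- as.matrix(data)
  nodes <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  colnames(data) <- nodes
  ds <- dataToStates(data)
  cards <- lapply(ds$states, length)
  n <- nrow(ds$idx)
  nodes <- sort(nodes)                      # lexicographic scan order
  parents <- setNames(rep(list(character(0)), length(nodes)), nodes)
  scoreCache <- new.env(parent = emptyenv())
  fam <- function(child, pa) {
    key <- paste(child, paste(sort(pa), collapse = ","), sep = "|")
    v <- scoreCache[[key]]
    if (is.null(v)) {
      v <- familyBIC(ds$idx, cards, child, pa, n)
      scoreCache[[key]] <- v
    }
    v
  }
  if (length(nodes) < 2L) return(parents)
  eps <- 1e-9
  repeat {                                  # forward: additions
    best <- NULL
    for (from in nodes) for (to in nodes) {
      if (from == to || from %in% parents[[to]]) next
      if (length(parents[[to]]) >= maxParents) next
      if (hasPath(parents, from = to, to = from)) next  # would cycle
      delta <- fam(to, c(parents[[to]], from)) - fam(to, parents[[to]])
      if (delta > eps && (is.null(best) || delta > best$delta))
        best <- list(from = from, to = to, delta = delta)
    }
    if (is.null(best)) break
    parents[[best$to]] <- c(parents[[best$to]], best$from)
  }
  repeat {                                  # backward: deletions
    best <- NULL
    for (to in nodes) for (from in parents[[to]]) {
      delta <- fam(to, setdiff(parents[[to]], from)) -
        fam(to, parents[[to]])
      if (delta > eps && (is.null(best) || delta > best$delta))
        best <- list(from = from, to = to, delta = delta)
    }
    if (is.null(best)) break
    parents[[best$to]] <- setdiff(parents[[best$to]], best$from)
  }
  parents
}

#' Fit conditional probability tables by maximum likelihood
#'
#' Each CPT entry is the empirical conditional frequency
#' `count(child, parent config) / count(parent config)`; a parent
#' configuration never observed in the data receives a uniform row.
#'
#' @param parents named list of parent sets (a DAG, e.g. from
#'   [greedyStructureSearch()]).
#' @param data matrix or data.frame of discrete values, columns named.
#' @return A [DiscreteBayesNet-class].
#' @export
fitCPTs <- function(parents, data) {
  data <- as.matrix(data)
  ds <- dataToStates(data)
  nodes <- colnames(ds$idx)
  cards <- lapply(ds$states, length)
  cpts <- lapply(nodes, function(j) {
    counts <- familyCounts(ds$idx, cards, j, parents[[j]])
    tot <- rowSums(counts)
    cpt <- counts / ifelse(tot == 0, 1, tot)
    cpt[tot == 0, ] <- 1 / ncol(cpt)       # unseen parent configuration
    colnames(cpt) <- as.character(ds$states[[j]])
    cpt
  })
  names(cpts) <- nodes
  new("DiscreteBayesNet", nodes = nodes, states = ds$states,
      parents = parents[nodes], cpts = cpts)
}

setMethod("show", "DiscreteBayesNet", function(object) {
  ne <- sum(lengths(object@parents))
  cat("DiscreteBayesNet:", length(object@nodes), "nodes,", ne, "edges\n")
  cards <- vapply(object@states, length, integer(1))
  cat("  cardinalities:", paste(cards, collapse = " "), "\n")
})

# CPT row index (1-based) of a parent configuration given 0-based state
# indices of the parents; first parent varies fastest
cptRowIndex <- function(bn, node, stateIdx) {
  pa <- bn@parents[[node]]
  if (length(pa) == 0L) return(1L)
  cards <- vapply(bn@states[pa], length, integer(1))
  mult <- cumprod(c(1, cards))[seq_along(pa)]
  as.integer(sum(stateIdx[pa] * mult)) + 1L
}

#' Joint probability of a full assignment
#'
#' Product of the CPT entries along the network factorization:
#' \eqn{P(x) = \prod_j P(x_j \mid pa(x_j))}.
#'
#' @param bn a [DiscreteBayesNet-class].
#' @param assignment named vector covering every node, values on each
#'   node's state scale.
#' @return the joint probability.
#' @export
jointProbability <- function(bn, assignment) {
  if (!setequal(names(assignment), bn@nodes))
    stop("assignment must cover every node exactly once")
  stateIdx <- vapply(bn@nodes, function(j) {
    k <- match(assignment[[j]], bn@states[[j]])
    if (is.na(k)) stop("value out of range for node '", j, "'")
    k - 1L
  }, integer(1))
  prod(vapply(bn@nodes, function(j)
    bn@cpts[[j]][cptRowIndex(bn, j, stateIdx), stateIdx[[j]] + 1L],
    numeric(1)))
}

# ---- factor algebra for variable elimination -------------------------------
# a factor is list(vars, cards (named), val) with the FIRST var fastest

cptToFactor <- function(bn, node) {
  vars <- c(node, bn@parents[[node]])
  cards <- vapply(bn@states[vars], length, integer(1))
  # cpt rows: parent configs (first parent fastest); cols: child states.
  # target layout: child fastest, then parents in order -> transpose.
  val <- as.numeric(t(bn@cpts[[node]]))
  list(vars = vars, cards = cards, val = val)
}

factorReduce <- function(f, var, stateIdx) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  dims <- f$cards
  arr <- array(f$val, dim = dims)
  arr <- do.call(`[`, c(list(arr), lapply(seq_along(dims), function(d)
    if (d == pos) stateIdx + 1L else seq_len(dims[d])), list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), pos)
  list(vars = f$vars[keep], cards = f$cards[keep], val = as.numeric(arr))
}

factorProduct <- function(f, g) {
  vars <- union(f$vars, g$vars)
  cards <- setNames(integer(length(vars)), vars)
  cards[f$vars] <- f$cards
  cards[g$vars] <- g$cards
  expand <- function(h) {
    if (length(h$vars) == 0L) return(array(h$val, dim = pmax(cards, 1L)))
    perm <- c(match(h$vars, vars), setdiff(seq_along(vars),
                                           match(h$vars, vars)))
    arr <- array(h$val, dim = c(h$cards,
                                cards[setdiff(vars, h$vars)]))
    aperm(arr, order(perm))
  }
  if (length(vars) == 0L)
    return(list(vars = vars, cards = cards, val = f$val * g$val))
  val <- as.numeric(expand(f) * expand(g))
  list(vars = vars, cards = cards, val = val)
}

factorMarginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  if (length(f$vars) == 1L)
    return(list(vars = character(0), cards = setNames(integer(0),
                                                      character(0)),
                val = sum(f$val)))
  arr <- array(f$val, dim = f$cards)
  keep <- setdiff(seq_along(f$vars), pos)
  out <- apply(arr, keep, sum)
  list(vars = f$vars[keep], cards = f$cards[keep], val = as.numeric(out))
}

#' Exact posterior marginal by variable elimination
#'
#' Reduces every CPT factor by the evidence, eliminates the remaining
#' non-query variables in min-degree order, multiplies what is left and
#' normalizes. Answers are exact; on small networks they equal full joint
#' enumeration.
#'
#' @param bn a [DiscreteBayesNet-class].
#' @param query character vector of query variable names.
#' @param evidence named vector of observed values (state scale); must be
#'   disjoint from the query.
#' @return list with `probabilities` (array over the query variables,
#'   dimnames = state labels) and `zeroEvidence` (`TRUE` when the evidence
#'   has probability zero, in which case the distribution is `NA`).
#' @export
queryMarginal <- function(bn, query, evidence = NULL) {
  evNames <- names(evidence) %||% character(0)
  if (length(intersect(query, evNames)) > 0)
    stop("query and evidence must be disjoint")
  stopifnot(all(query %in% bn@nodes), all(evNames %in% bn@nodes))
  factors <- lapply(bn@nodes, function(j) cptToFactor(bn, j))
  for (e in evNames) {
    k <- match(evidence[[e]], bn@states[[e]])
    if (is.na(k)) stop("evidence value out of range for node '", e, "'")
    factors <- lapply(factors, factorReduce, var = e, stateIdx = k - 1L)
  }
  toEliminate <- setdiff(bn@nodes, c(query, evNames))
  while (length(toEliminate) > 0) {
    # min-degree: eliminate the variable appearing with fewest neighbours
    degree <- vapply(toEliminate, function(v) {
      nb <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      length(setdiff(nb, v))
    }, integer(1))
    v <- toEliminate[order(degree, toEliminate)][1]
    inv <- vapply(factors, function(f) v %in% f$vars, logical(1))
    merged <- Reduce(factorProduct, factors[inv])
    factors <- c(factors[!inv], list(factorMarginalize(merged, v)))
    toEliminate <- setdiff(toEliminate, v)
  }
  joint <- Reduce(factorProduct, factors)
  # reorder to the query order
  if (length(joint$vars) > 0) {
    perm <- match(query, joint$vars)
    arr <- array(joint$val, dim = joint$cards)
    arr <- aperm(arr, perm)
  } else {
    arr <- array(joint$val, dim = 1L)
  }
  z <- sum(arr)
  if (z <= 0) {
    arr[] <- NA_real_
    return(list(probabilities = arr, zeroEvidence = TRUE))
  }
  arr <- arr / z
  dimnames(arr) <- lapply(bn@states[query], as.character)
  list(probabilities = arr, zeroEvidence = FALSE)
}

#' Export a network structure as DOT
#'
#' @param bn a [DiscreteBayesNet-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeNetworkDOT <- function(bn, path) {
  lines <- c("digraph syndromes {")
  for (j in bn@nodes)
    lines <- c(lines, paste0("  \"", j, "\";"))
  for (j in bn@nodes) for (p in bn@parents[[j]])
    lines <- c(lines, paste0("  \"", p, "\" -> \"", j, "\";"))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export a network (cardinalities and CPTs) as JSON
#'
#' @inheritParams writeNetworkDOT
#' @return `path`, invisibly.
#' @export
writeNetworkJSON <- function(bn, path) {
  out <- lapply(bn@nodes, function(j) list(
    node = j,
    states = bn@states[[j]],
    parents = bn@parents[[j]],
    cpt = lapply(seq_len(nrow(bn@cpts[[j]])), function(r)
      as.numeric(bn@cpts[[j]][r, ]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
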