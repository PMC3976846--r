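#' @import methods
NULL

#' SymptomTable: samples by symptoms with a per-sample positive score
#'
#' Container for a clinical observation table. Rows are patient samples,
#' columns are symptom features quantified as non-negative integers (binary
#' occurrence or small ordinal positivity levels), and each sample carries a
#' non-negative real "positive score" summarizing its total positivity; the
#' score is the regression target throughout the package.
#'
#' @slot values integer-valued matrix, samples x symptoms, non-negative.
#' @slot positiveScore numeric vector of non-negative scores, one per sample.
#'
#' @seealso [SymptomTable()], [readSymptomTable()], [buildHierarchy()]
#' @exportClass SymptomTable
setClass("SymptomTable",
  representation(values = "matrix", positiveScore = "numeric"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("'values' must be a numeric matrix")
    if (any(v < 0)) return("symptom values must be non-negative")
    if (any(v != floor(v))) return("symptom values must be integers")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      return("symptom columns must carry unique names")
    if (length(object@positiveScore) != nrow(v))
      return("positiveScore length must equal the number of samples")
    if (any(object@positiveScore < 0))
      return("positive scores must be non-negative")
    TRUE
  }
)

#' SyndromeGrouping: assignment of symptom columns to syndrome groups
#'
#' Each group carries a name, an ordered member list (symptom column names),
#' an exclusivity flag, and -- for exclusive groups, once learned or supplied
#' -- a code map assigning each member a positive integer code. Groups must
#' partition the symptom columns of the table they are applied to.
#'
#' @slot groups list of group descriptors; each is a list with elements
#'   `name` (character), `members` (character vector), `exclusive` (logical
#'   flag) and `codeMap` (named integer vector or `NULL`).
#'
#' @seealso [SyndromeGrouping()], [readGrouping()], [writeGrouping()]
#' @exportClass SyndromeGrouping
setClass("SyndromeGrouping",
  representation(groups = "list"),
  validity = function(object) {
    gs <- object@groups
    if (length(gs) == 0L) return("at least one group is required")
    nm <- vapply(gs, function(g) g$name, character(1))
    if (anyDuplicated(nm)) return("group names must be unique")
    for (g in gs) {
      if (!is.character(g$members) || length(g$members) == 0L)
        return(paste0("group '", g$name, "' has no members"))
      if (!is.logical(g$exclusive) || length(g$exclusive) != 1L)
        return(paste0("group '", g$name, "' needs a single exclusive flag"))
      if (!is.null(g$codeMap)) {
        cm <- g$codeMap
        if (!setequal(names(cm), g$members) ||
            !setequal(as.integer(cm), seq_along(g$members)))
          return(paste0("group '", g$name,
                        "': codeMap must be a bijection members -> 1..m"))
      }
    }
    members <- unlist(lapply(gs, function(g) g$members))
    if (anyDuplicated(members))
      return("a symptom may belong to exactly one group")
    TRUE
  }
)

#' SyndromeHierarchy: the three-layer feature representation
#'
#' Ties together a [SymptomTable-class] (leaf layer), a
#' [SyndromeGrouping-class] (middle layer definition) and the computed
#' syndrome value matrix, one integer column per group. The root of the
#' conceptual tree is the positive score carried by the table.
#'
#' @slot table the underlying [SymptomTable-class].
#' @slot grouping the [SyndromeGrouping-class], with learned code maps
#'   filled in for exclusive groups.
#' @slot syndromeValues integer matrix, samples x groups.
#'
#' @seealso [buildHierarchy()], [syndromeValues()]
#' @exportClass SyndromeHierarchy
setClass("SyndromeHierarchy",
  representation(table = "SymptomTable", grouping = "SyndromeGrouping",
                 syndromeValues = "matrix"),
  validity = function(object) {
    if (ncol(object@syndromeValues) != length(object@grouping@groups))
      return("one syndrome column per group is required")
    if (nrow(object@syndromeValues) != nrow(object@table@values))
      return("syndrome rows must match table samples")
    if (any(object@syndromeValues < 0))
      return("syndrome values must be non-negative")
    TRUE
  }
)

#' LSSVRModel: fitted least-squares support vector regression model
#'
#' Dual solution of the LS-SVM regression problem with Gaussian RBF kernel:
#' one dual coefficient per training sample plus a bias, with the equality
#' constraint that the dual coefficients sum to zero.
#'
#' @slot trainingInputs numeric matrix of training inputs (samples x features).
#' @slot alpha numeric vector of dual coefficients, one per training sample.
#' @slot bias numeric scalar intercept.
#' @slot sigma2 positive RBF width parameter (direct divisor convention,
#'   \eqn{k(x,z) = \exp(-\|x-z\|^2/\sigma^2)}).
#' @slot gamma positive regularization parameter.
#'
#' @seealso [fitLSSVR()], [predict,LSSVRModel-method]
#' @exportClass LSSVRModel
setClass("LSSVRModel",
  representation(trainingInputs = "matrix", alpha = "numeric",
                 bias = "numeric", sigma2 = "numeric", gamma = "numeric"),
  validity = function(object) {
    if (length(object@alpha) != nrow(object@trainingInputs))
      return("one dual coefficient per training sample is required")
    tol <- 1e-6 * (1 + sum(abs(object@alpha)))
    if (abs(sum(object@alpha)) > tol)
      return("dual coefficients must sum to zero (equality constraint)")
    if (object@sigma2 <= 0 || object@gamma <= 0)
      return("sigma2 and gamma must be positive")
    TRUE
  }
)

#' SwarmFit: result of a binary particle swarm search
#'
#' Holds the global best subset found, its fitness, the per-generation
#' global-best fitness trace (non-increasing by construction), the final
#' swarm state and the event log (reinitializations, global-best mutations,
#' elitist refreshes).
#'
#' @slot position binary numeric vector, the selected-subset indicator.
#' @slot fitness numeric, fitness of `position`.
#' @slot trace numeric vector of per-generation global best fitness.
#' @slot swarm list with final `positions`, `velocities`, `pbestPositions`
#'   matrices and `pbestFitness` vector.
#' @slot events list of event records (iteration, type, detail).
#' @slot config the swarm configuration list used.
#'
#' @seealso [runCBPSO()], [selectSyndromes()], [decodeSolution()]
#' @exportClass SwarmFit
setClass("SwarmFit",
  representation(position = "numeric", fitness = "numeric",
                 trace = "numeric", swarm = "list", events = "list",
                 config = "list"),
  validity = function(object) {
    if (!all(object@position %in% c(0, 1)))
      return("position must be a binary vector")
    if (is.unsorted(rev(object@trace)) && any(diff(object@trace) > 1e-12))
      return("global best trace must be non-increasing")
    TRUE
  }
)

#' DiscreteBayesNet: a discrete Bayesian network with CPTs
#'
#' Directed acyclic graph over discrete variables together with one
#' conditional probability table per node. CPTs are stored as matrices with
#' one row per parent configuration (lexicographic over parent states, first
#' parent varying fastest) and one column per child state; every row sums
#' to one.
#'
#' @slot nodes character vector of variable names (topologically unordered).
#' @slot states named list; per node, the vector of its observable states.
#' @slot parents named list; per node, character vector of parent names.
#' @slot cpts named list; per node, the conditional probability matrix.
#'
#' @seealso [fitCPTs()], [greedyStructureSearch()], [queryMarginal()]
#' @exportClass DiscreteBayesNet
setClass("DiscreteBayesNet",
  representation(nodes = "character", states = "list", parents = "list",
                 cpts = "list"),
  validity = function(object) {
    nd <- object@nodes
    if (!setequal(names(object@parents), nd) ||
        !setequal(names(object@states), nd) ||
        !setequal(names(object@cpts), nd))
      return("states, parents and cpts must be keyed by node name")
    for (j in nd) {
      if (!all(object@parents[[j]] %in% nd))
        return(paste0("unknown parent of node '", j, "'"))
      cpt <- object@cpts[[j]]
      if (ncol(cpt) != length(object@states[[j]]))
        return(paste0("CPT of '", j, "' must have one column per state"))
      if (any(abs(rowSums(cpt) - 1) > 1e-9))
        return(paste0("CPT rows of '", j, "' must sum to 1"))
    }
    if (!isAcyclic(object@parents, nd)) return("graph must be acyclic")
    TRUE
  }
)

# DFS acyclicity check on a parents-list representation
isAcyclic <- function(parents, nodes) {
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(FALSE)
    if (state[[v]] == 2L) return(TRUE)
    state[[v]] <<- 1L
    for (p in parents[[v]]) if (!visit(p)) return(FALSE)
    state[[v]] <<- 2L
    TRUE
  }
  all(vapply(nodes, visit, logical(1)))
}
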