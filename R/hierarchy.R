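#' @include AllClasses.R AllGenerics.R
NULL

#' Aggregate a mutually-exclusive symptom group into one syndrome code
#'
#' For a group of symptoms that cannot co-occur (e.g. the four possible lip
#' colors), the syndrome takes integer values `0..m`: 0 when no member is
#' positive, otherwise the code of the single positive member. Codes
#' `1..m` are assigned so that the symptom positive in more patients
#' receives the larger code; ties are broken by the larger mean positive
#' score among that symptom's positive patients, then by column order
#' (earlier column, larger code).
#'
#' @param columns numeric matrix, samples x group members, binary 0/1 with
#'   column names.
#' @param positiveScore per-sample positive score (used for tie-breaks).
#' @param codeMap optional previously learned code map (named integer
#'   vector member -> code); when supplied it is applied as-is.
#' @return list with `values` (integer syndrome column) and `codeMap`.
#' @examples
#' m <- cbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 0))
#' extractExclusiveSyndrome(m, c(3, 2, 1, 0))
#' @export
extractExclusiveSyndrome <- function(columns, positiveScore, codeMap = NULL) {
  columns <- as.matrix(columns)
  if (is.null(colnames(columns)))
    stop("member columns must be named")
  if (any(columns < 0)) stop("symptom values must be non-negative")
  if (!all(columns %in% c(0, 1)))
    stop("exclusive group members must be binary (0/1)")
  bad <- which(rowSums(columns) > 1)
  if (length(bad) > 0)
    stop("exclusivity violated: more than one positive member in row ",
         bad[1])
  m <- ncol(columns)
  if (is.null(codeMap)) {
    counts <- colSums(columns > 0)
    meanPS <- vapply(seq_len(m), function(j) {
      pos <- columns[, j] > 0
      if (any(pos)) mean(positiveScore[pos]) else -Inf
    }, numeric(1))
    # descending by count, then mean score, then original column order
    ord <- order(-counts, -meanPS, seq_len(m))
    codeMap <- setNames(integer(m), colnames(columns))
    codeMap[ord] <- seq(m, 1L)
  } else {
    if (!setequal(names(codeMap), colnames(columns)) ||
        !setequal(as.integer(codeMap), seq_len(m)))
      stop("codeMap must be a bijection from members onto 1..m")
    codeMap <- setNames(as.integer(codeMap[colnames(columns)]),
                        colnames(columns))
  }
  values <- as.integer(columns %*% codeMap)
  list(values = values, codeMap = codeMap)
}

#' Aggregate a concurrent symptom group into one syndrome value
#'
#' Symptoms that may co-occur (e.g. irritability, depression and sigh under
#' "emotion") are summarized by cumulative summation: the syndrome value of
#' a sample is the row sum of its member columns, a total positive strength.
#'
#' @param columns numeric matrix of non-negative integers, samples x
#'   group members.
#' @return integer vector of row sums.
#' @examples
#' extractConcurrentSyndrome(rbind(c(2, 0, 1)))  # 3
#' @export
extractConcurrentSyndrome <- function(columns) {
  columns <- as.matrix(columns)
  if (any(columns < 0)) stop("symptom values must be non-negative")
  as.integer(rowSums(columns))
}

#' Build the three-layer feature hierarchy
#'
#' Computes one syndrome column per group (frequency-coded for exclusive
#' groups, row sums for concurrent ones) and returns the assembled
#' [SyndromeHierarchy-class]. The groups must partition the symptom columns
#' of the table: every symptom in exactly one group. Learned code maps are
#' stored back into the returned grouping so that serializing it with
#' [writeGrouping()] and rebuilding reproduces identical syndrome values.
#'
#' @param table a [SymptomTable-class].
#' @param grouping a [SyndromeGrouping-class].
#' @return A [SyndromeHierarchy-class].
#' @export
buildHierarchy <- function(table, grouping) {
  stopifnot(is(table, "SymptomTable"), is(grouping, "SyndromeGrouping"))
  cols <- colnames(table@values)
  members <- unlist(lapply(grouping@groups, function(g) g$members))
  missing <- setdiff(members, cols)
  if (length(missing) > 0)
    stop("grouping refers to unknown symptom column(s): ",
         paste(missing, collapse = ", "))
  unassigned <- setdiff(cols, members)
  if (length(unassigned) > 0)
    stop("symptom column(s) not assigned to any group: ",
         paste(unassigned, collapse = ", "))
  # duplicates across groups are rejected by the SyndromeGrouping validity
  groups <- grouping@groups
  syn <- matrix(0L, nrow(table@values), length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    sub <- table@values[, g$members, drop = FALSE]
    if (g$exclusive) {
      res <- extractExclusiveSyndrome(sub, table@positiveScore, g$codeMap)
      syn[, k] <- res$values
      groups[[k]]$codeMap <- res$codeMap
    } else {
      syn[, k] <- extractConcurrentSyndrome(sub)
    }
  }
  colnames(syn) <- vapply(groups, function(g) g$name, character(1))
  new("SyndromeHierarchy", table = table,
      grouping = new("SyndromeGrouping", groups = groups),
      syndromeValues = syn)
}

#' @rdname accessors
#' @export
setMethod("syndromeValues", "SyndromeHierarchy",
          function(x) x@syndromeValues)

#' @rdname accessors
#' @export
setMethod("positiveScore", "SyndromeHierarchy",
          function(x) x@table@positiveScore)

#' @rdname accessors
#' @export
setMethod("symptomValues", "SyndromeHierarchy", function(x) x@table@values)

#' @describeIn SyndromeHierarchy-class the grouping with learned code maps.
#' @param x,object a `SyndromeHierarchy`.
#' @export
setMethod("groupNames", "SyndromeHierarchy",
          function(x) groupNames(x@grouping))

setMethod("show", "SyndromeHierarchy", function(object) {
  cat("SyndromeHierarchy:", nrow(object@syndromeValues), "samples,",
      ncol(object@table@values), "symptoms ->",
      ncol(object@syndromeValues), "syndromes\n")
})

#' Extract the grouping (with learned code maps) from a hierarchy
#' @param x a [SyndromeHierarchy-class].
#' @return The [SyndromeGrouping-class] stored in the hierarchy.
#' @export
hierarchyGrouping <- function(x) {
  stopifnot(is(x, "SyndromeHierarchy"))
  x@grouping
}
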