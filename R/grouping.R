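#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SyndromeGrouping
#'
#' @param names character vector of group names.
#' @param members list of character vectors: symptom column names per group.
#' @param exclusive logical vector: `TRUE` for mutually-exclusive groups
#'   (at most one member positive per sample), `FALSE` for concurrent ones.
#' @param codeMaps optional list of named integer vectors (exclusive groups
#'   only), mapping each member symptom to its positive integer code.
#' @return A [SyndromeGrouping-class] object.
#' @examples
#' SyndromeGrouping(c("lip", "emotion"),
#'                  list(c("pale", "red"), c("irritability", "sigh")),
#'                  exclusive = c(TRUE, FALSE))
#' @export
SyndromeGrouping <- function(names, members, exclusive,
                             codeMaps = vector("list", length(names))) {
  stopifnot(length(names) == length(members),
            length(names) == length(exclusive))
  groups <- mapply(function(n, m, e, cm) {
    list(name = n, members = as.character(m), exclusive = as.logical(e),
         codeMap = if (is.null(cm)) NULL else
           setNames(as.integer(cm), base::names(cm)))
  }, names, members, exclusive, codeMaps, SIMPLIFY = FALSE)
  new("SyndromeGrouping", groups = unname(groups))
}

#' @rdname accessors
#' @export
setMethod("groupNames", "SyndromeGrouping",
          function(x) vapply(x@groups, function(g) g$name, character(1)))

#' @rdname accessors
#' @export
setMethod("groupSizes", "SyndromeGrouping",
          function(x) vapply(x@groups, function(g) length(g$members),
                             integer(1)))

#' @describeIn SyndromeGrouping-class number of groups.
#' @param x,object a `SyndromeGrouping`.
#' @export
setMethod("length", "SyndromeGrouping", function(x) length(x@groups))

setMethod("show", "SyndromeGrouping", function(object) {
  sz <- groupSizes(object)
  cat("SyndromeGrouping:", length(sz), "groups over", sum(sz),
      "symptoms\n")
  excl <- sum(vapply(object@groups, function(g) g$exclusive, logical(1)))
  cat("  exclusive:", excl, " concurrent:", length(sz) - excl, "\n")
})

#' Read / write a grouping specification as JSON
#'
#' The JSON form is an array of objects with fields `group_name`, `members`,
#' `exclusive` and optionally `code_map`; `writeGrouping()` persists learned
#' code maps so a rebuilt hierarchy reproduces identical syndrome values.
#'
#' @param path file path.
#' @param x a [SyndromeGrouping-class] (for writing).
#' @return `readGrouping()` returns a [SyndromeGrouping-class];
#'   `writeGrouping()` returns `path` invisibly.
#' @export
readGrouping <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  SyndromeGrouping(
    names = vapply(raw, function(g) g$group_name, character(1)),
    members = lapply(raw, function(g) unlist(g$members)),
    exclusive = vapply(raw, function(g) isTRUE(g$exclusive), logical(1)),
    codeMaps = lapply(raw, function(g) {
      if (is.null(g$code_map)) NULL else unlist(g$code_map)
    })
  )
}

#' @rdname readGrouping
#' @export
writeGrouping <- function(x, path) {
  stopifnot(is(x, "SyndromeGrouping"))
  out <- lapply(x@groups, function(g) {
    rec <- list(group_name = g$name, members = as.list(g$members),
                exclusive = g$exclusive)
    if (!is.null(g$codeMap)) rec$code_map <- as.list(g$codeMap)
    rec
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
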