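#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SymptomTable
#'
#' @param values numeric matrix of non-negative integers, samples x
#'   symptoms, with unique column names.
#' @param positiveScore numeric vector of non-negative per-sample scores.
#' @return A [SymptomTable-class] object.
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
#' tab <- SymptomTable(m, c(1.5, 2))
#' symptomValues(tab)
#' @export
SymptomTable <- function(values, positiveScore) {
  storage.mode(values) <- "double"
  new("SymptomTable", values = values,
      positiveScore = as.numeric(positiveScore))
}

#' @rdname accessors
#' @export
setMethod("symptomValues", "SymptomTable", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("positiveScore", "SymptomTable", function(x) x@positiveScore)

#' @describeIn SymptomTable-class number of samples and symptoms.
#' @param object,x a `SymptomTable`.
#' @export
setMethod("dim", "SymptomTable", function(x) dim(x@values))

setMethod("show", "SymptomTable", function(object) {
  cat("SymptomTable:", nrow(object@values), "samples x",
      ncol(object@values), "symptoms\n")
  cat("  positive score: range [",
      format(min(object@positiveScore), digits = 4), ", ",
      format(max(object@positiveScore), digits = 4), "]\n", sep = "")
})

#' Read / write a symptom table as CSV
#'
#' The on-disk format is a plain CSV with one header row: symptom columns
#' first (non-negative integers) and a final column named `positive_score`
#' (non-negative real).
#'
#' @param path file path.
#' @param x a [SymptomTable-class] (for writing).
#' @return `readSymptomTable()` returns a [SymptomTable-class];
#'   `writeSymptomTable()` returns `path` invisibly.
#' @export
readSymptomTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"positive_score" %in% names(df))
    stop("CSV must contain a 'positive_score' column (last)")
  ps <- df[["positive_score"]]
  df[["positive_score"]] <- NULL
  SymptomTable(as.matrix(df), ps)
}

#' @rdname readSymptomTable
#' @export
writeSymptomTable <- function(x, path) {
  stopifnot(is(x, "SymptomTable"))
  df <- as.data.frame(x@values, check.names = FALSE)
  df[["positive_score"]] <- x@positiveScore
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
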