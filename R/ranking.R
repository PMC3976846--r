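#' @include lssvr.R
NULL

#' Correlation-derived relevance of one feature to the positive score
#'
#' Returns \eqn{1 - |r|} where \eqn{r} is the Pearson correlation between
#' the feature and the target; smaller values indicate a more predictive
#' feature. A zero-variance feature has no defined correlation and scores
#' the worst possible value 1 (with a warning).
#'
#' @param feature numeric vector.
#' @param ps numeric target (positive score), same length.
#' @return value in `[0, 1]`.
#' @export
mccScore <- function(feature, ps) {
  if (length(feature) != length(ps))
    stop("feature and ps must have equal length")
  if (stats::sd(feature) == 0) {
    warning("zero-variance feature: mcc set to 1")
    return(1)
  }
  1 - abs(stats::cor(feature, ps))
}

#' Leave-one-feature-out predicting error
#'
#' Cross-validated MSE of an LS-SVR model trained on all feature columns
#' except `featureIndex`. A clearly increased error after removing a
#' feature marks that feature as highly predictive.
#'
#' @param X numeric matrix, samples x features (at least 2 columns).
#' @param ps numeric target vector.
#' @param featureIndex column to leave out.
#' @param config an [lssvrConfig()] with `sigma2`/`gamma` set; its `folds`
#'   and `seed` drive the (deterministic) fold assignment.
#' @return cross-validated MSE without the feature.
#' @export
peScore <- function(X, ps, featureIndex, config) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("cannot remove the sole feature column")
  cvMSE(X[, -featureIndex, drop = FALSE], ps, config)
}

#' Combined feature-ranking score
#'
#' Combines the correlation relevance `mcc` (smaller = better) and the
#' leave-one-feature-out error `pe` (larger = better, i.e. the model
#' suffers more without the feature) into
#' \deqn{fr_i = \frac{mcc_i + (1 - pe_i / \max_j pe_j)}{2},}
#' a score in `[0, 1]` where smaller means more predictive.
#'
#' @param mcc numeric vector of correlation relevance scores.
#' @param pe numeric vector of leave-one-feature-out errors, same length.
#' @return numeric vector of fr scores.
#' @export
frScores <- function(mcc, pe) {
  if (length(mcc) != length(pe)) stop("mcc and pe must have equal length")
  mx <- max(pe)
  if (mx <= 0) stop("max(pe) must be positive")
  (mcc + (1 - pe / mx)) / 2
}

#' Rank features by ascending fr score
#'
#' @param records data.frame with at least columns `feature` and `fr`.
#' @return the data.frame with a `rank` column added: rank 1 is the
#'   smallest fr; ties keep input order.
#' @export
rankFeatures <- function(records) {
  stopifnot(is.data.frame(records), all(c("feature", "fr") %in%
                                        names(records)))
  records$rank <- rank(records$fr, ties.method = "first")
  records
}

#' Threshold subset of ranked features
#'
#' @param records ranked data.frame (see [rankFeatures()]).
#' @param theta threshold; features with `fr` strictly below it are kept.
#' @return character vector of feature names.
#' @export
thresholdSubset <- function(records, theta) {
  as.character(records$feature[records$fr < theta])
}

#' Rank all syndromes of a hierarchy
#'
#' Computes `mcc`, `pe`, `fr` and ranks for every syndrome column against
#' the positive score. The LS-SVR hyperparameters for the `pe` evaluations
#' must be fixed in `config` (typically by one [gridSearchLSSVR()] on the
#' full syndrome set).
#'
#' @param hierarchy a [SyndromeHierarchy-class] (or a plain numeric matrix
#'   of syndrome values, in which case `ps` must be given).
#' @param config an [lssvrConfig()] with `sigma2`/`gamma` set.
#' @param ps positive-score vector; taken from the hierarchy when omitted.
#' @return data.frame with columns `feature`, `mcc`, `pe`, `fr`, `rank`.
#' @export
rankSyndromes <- function(hierarchy, config, ps = NULL) {
  if (is(hierarchy, "SyndromeHierarchy")) {
    X <- syndromeValues(hierarchy)
    ps <- positiveScore(hierarchy)
  } else {
    X <- as.matrix(hierarchy)
    if (is.null(ps)) stop("ps is required for a plain matrix input")
  }
  mcc <- vapply(seq_len(ncol(X)), function(j)
    suppressWarnings(mccScore(X[, j], ps)), numeric(1))
  pe <- vapply(seq_len(ncol(X)), function(j)
    peScore(X, ps, j, config), numeric(1))
  rankFeatures(data.frame(
    feature = colnames(X) %||% paste0("f", seq_len(ncol(X))),
    mcc = mcc, pe = pe, fr = frScores(mcc, pe),
    stringsAsFactors = FALSE))
}

#' Correlation-based filter baseline (top fraction of symptoms)
#'
#' Ranks the raw symptom columns by absolute Pearson correlation with the
#' positive score and keeps the top `ceiling(topFraction * D)` columns.
#' Zero-variance columns count as correlation 0.
#'
#' @param table a [SymptomTable-class].
#' @param topFraction fraction in `(0, 1]` of columns to keep.
#' @return character vector of selected symptom names, strongest first.
#' @export
cfmBaseline <- function(table, topFraction) {
  stopifnot(is(table, "SymptomTable"),
            topFraction > 0, topFraction <= 1)
  X <- table@values
  r <- suppressWarnings(
    abs(stats::cor(X, table@positiveScore))[, 1])
  r[is.na(r)] <- 0
  k <- ceiling(topFraction * ncol(X))
  colnames(X)[order(-r, seq_along(r))][seq_len(k)]
}

#' Reference ranking of the 27-syndrome hepatocellular-carcinoma panel
#'
#' Published feature-ranking summary for a Traditional Chinese Medicine
#' observation panel of 147 symptoms aggregated into 27 syndrome groups,
#' collected from hepatocellular-carcinoma patients: per syndrome, its
#' group size, exclusivity convention, correlation relevance `mcc`,
#' leave-one-feature-out error `pe`, the reported combined score `fr` and
#' the reported rank. The `mcc`/`pe` columns serve as inputs for
#' recomputing `fr` and the threshold subsets; the reported `fr`/`rank`
#' columns serve as the expected output.
#'
#' @return data.frame with columns `index`, `name`, `abbreviation`,
#'   `size`, `exclusive`, `mcc`, `pe`, `fr`, `rank`.
#' @export
hccSyndromePanel <- function() {
  path <- system.file("extdata", "hcc_syndrome_panel.csv",
                      package = "SyndromeSelect", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$exclusive <- as.logical(df$exclusive)
  df
}
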