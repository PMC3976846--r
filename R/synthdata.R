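#' @include AllClasses.R hierarchy.R
NULL

#' Specification for a synthetic clinical symptom dataset
#'
#' Defines the shape and signal structure of a generated dataset: group
#' sizes and exclusivity flags, which syndrome groups carry true signal
#' (the "planted" set), their linear weights on the positive score, the
#' Gaussian noise level and the per-symptom positivity parameters. All
#' stochastic choices are driven by `seed`.
#'
#' @param nSamples number of patient samples.
#' @param groupSizes integer vector of group sizes.
#' @param exclusiveFlags logical vector, `TRUE` for mutually-exclusive
#'   groups.
#' @param plantedRelevant integer indices of the groups whose syndrome
#'   values drive the positive score.
#' @param weights positive weights, one per planted group.
#' @param noiseSd standard deviation of the Gaussian noise on the score.
#' @param noneProb probability of the all-zero state in exclusive groups.
#' @param seed integer seed.
#' @return list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(nSamples, groupSizes, exclusiveFlags,
                          plantedRelevant, weights = rep(1,
                            length(plantedRelevant)),
                          noiseSd = 0.5, noneProb = 0.4, seed = 1L) {
  stopifnot(length(groupSizes) == length(exclusiveFlags),
            all(plantedRelevant %in% seq_along(groupSizes)),
            length(weights) == length(plantedRelevant),
            noiseSd >= 0)
  structure(list(nSamples = as.integer(nSamples),
                 groupSizes = as.integer(groupSizes),
                 exclusiveFlags = as.logical(exclusiveFlags),
                 plantedRelevant = as.integer(plantedRelevant),
                 weights = as.numeric(weights), noiseSd = noiseSd,
                 noneProb = noneProb, seed = as.integer(seed)),
            class = "syntheticSpec")
}

#' The standard 27-group panel specification
#'
#' A synthetic dataset shaped like the hepatocellular-carcinoma
#' observation panel: 300 samples, 147 symptoms in 27 groups with the
#' published group sizes, the three color-coding groups (lip color, tongue
#' color, coated tongue color) mutually exclusive, and by default five
#' planted relevant syndromes — the five groups reported as most
#' predictive in the reference ranking (facial features, sternocostal and
#' abdominal pain, diet, defecate and urine, skin of the limbs).
#'
#' @param seed integer seed.
#' @param nSamples number of samples (default 300).
#' @param plantedRelevant planted group indices (default
#'   `c(15, 17, 18, 19, 22)`).
#' @param noiseSd noise level (default 0.5).
#' @return a [syntheticSpec()].
#' @export
standardPanelSpec <- function(seed = 1L, nSamples = 300L,
                              plantedRelevant = c(15L, 17L, 18L, 19L, 22L),
                              noiseSd = 0.5) {
  panel <- hccSyndromePanel()
  syntheticSpec(nSamples = nSamples, groupSizes = panel$size,
                exclusiveFlags = panel$exclusive,
                plantedRelevant = plantedRelevant,
                weights = seq(2, 1, length.out = length(plantedRelevant)),
                noiseSd = noiseSd, seed = seed)
}

#' Generate a synthetic symptom dataset with known ground truth
#'
#' Exclusive groups draw, per sample, either the all-zero "none" state
#' (probability `noneProb`) or a single positive member chosen with
#' seeded per-member probabilities; concurrent groups draw each member
#' independently as a small ordinal (binomial with per-symptom level cap
#' 1-3 and positivity rate). The positive score is the weighted sum of
#' the planted groups' syndrome values plus Gaussian noise (clamped at
#' zero, scores being non-negative by definition).
#'
#' @param spec a [syntheticSpec()].
#' @return list with `table` (a [SymptomTable-class]), `grouping` (a
#'   [SyndromeGrouping-class]) and `truth` (list: planted indices, planted
#'   group names, weights, noiseSd, seed).
#' @export
generateSymptomData <- function(spec) {
  withSeed(spec$seed, {
    G <- length(spec$groupSizes)
    n <- spec$nSamples
    panelNames <- if (G == 27L) hccSyndromePanel()$name
                  else paste0("group", seq_len(G))
    groupNames <- make.unique(panelNames)
    cols <- list()
    memberNames <- list()
    synValues <- matrix(0, n, G)
    for (g in seq_len(G)) {
      m <- spec$groupSizes[g]
      nm <- if (m == 1L) gsub(" ", "_", tolower(groupNames[g])) else
        paste0(gsub(" ", "_", tolower(groupNames[g])), "_", seq_len(m))
      memberNames[[g]] <- nm
      if (spec$exclusiveFlags[g]) {
        # categorical: none (prob noneProb) or exactly one member
        pMember <- stats::runif(m, 0.5, 1.5)
        pMember <- (1 - spec$noneProb) * pMember / sum(pMember)
        draw <- sample.int(m + 1L, n, replace = TRUE,
                           prob = c(spec$noneProb, pMember)) - 1L
        sub <- matrix(0L, n, m)
        pos <- draw > 0
        sub[cbind(which(pos), draw[pos])] <- 1L
      } else {
        # independent small ordinals per member symptom
        lvl <- sample(1:3, m, replace = TRUE)
        rate <- stats::runif(m, 0.15, 0.5)
        sub <- vapply(seq_len(m), function(j)
          stats::rbinom(n, lvl[j], rate[j]), integer(n))
        sub <- matrix(sub, n, m)
      }
      colnames(sub) <- nm
      cols[[g]] <- sub
      synValues[, g] <- if (spec$exclusiveFlags[g]) 0 else rowSums(sub)
    }
    values <- do.call(cbind, cols)
    # planted signal: weighted syndrome values of the planted groups.
    # exclusive groups contribute their (frequency-coded) syndrome value;
    # computed after coding below if planted. Default planted groups are
    # concurrent, whose syndrome is the row sum available already.
    signal <- rep(0, n)
    for (i in seq_along(spec$plantedRelevant)) {
      g <- spec$plantedRelevant[i]
      sv <- if (spec$exclusiveFlags[g]) {
        # provisional frequency coding with a zero score (score not yet
        # defined); ties fall back to column order
        extractExclusiveSyndrome(cols[[g]], rep(0, n))$values
      } else synValues[, g]
      signal <- signal + spec$weights[i] * sv
    }
    ps <- signal + if (spec$noiseSd > 0)
      stats::rnorm(n, 0, spec$noiseSd) else 0
    ps <- pmax(ps, 0)
    table <- SymptomTable(values, ps)
    grouping <- SyndromeGrouping(groupNames, memberNames,
                                 spec$exclusiveFlags)
    list(table = table, grouping = grouping,
         truth = list(planted = spec$plantedRelevant,
                      plantedNames = groupNames[spec$plantedRelevant],
                      weights = spec$weights, noiseSd = spec$noiseSd,
                      seed = spec$seed))
  })
}
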