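#' ROC area under the curve
#'
#' AUC computed as the Mann--Whitney U statistic divided by n1*n2, with
#' ties counted 0.5 (midranks) -- identical to the trapezoidal area under
#' the ROC curve over all thresholds.
#'
#' @param positives Scores of the positive class.
#' @param negatives Scores of the negative class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(positives, negatives) {
  if (!length(positives) || !length(negatives)) stop("empty class")
  r <- rank(c(positives, negatives), ties.method = "average")
  n1 <- length(positives); n2 <- length(negatives)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' Mann--Whitney rank test
#'
#' Returns the U statistic (midrank tie handling) and a two-sided p-value:
#' exact when n1*n2 <= `exact_max` and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections (via
#' `stats::wilcox.test`).
#'
#' @param a,b Numeric score vectors.
#' @param exact_max Exact-enumeration cutoff on n1*n2 (default 400).
#' @return List with `U` (for `a` relative to `b`), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max = 400L) {
  if (!length(a) || !length(b)) stop("empty input")
  n1 <- length(a); n2 <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (n1 * n2 <= exact_max) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  r <- rank(c(a, b), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  list(U = u, p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Bivariate (p_DD, entropy) discrimination
#'
#' Fits a two-feature logistic classifier on per-residue (p_DD, S) pairs
#' and reports the AUC of its fitted probabilities -- the combined use of
#' bound-state disorder and binding-mode diversity to separate two residue
#' classes (e.g. context-dependent vs single-mode regions).
#'
#' @param p_dd Numeric vector.
#' @param entropy Numeric vector (bits).
#' @param labels Binary labels (1 = positive class).
#' @return List with the fitted `model` (class `binding_model` machinery
#'   reused on two features) and `auc`.
#' @export
bivariate_discrimination <- function(p_dd, entropy, labels) {
  stopifnot(length(p_dd) == length(entropy),
            length(p_dd) == length(labels))
  dat <- data.frame(label = as.numeric(labels), p_dd = p_dd,
                    entropy = entropy)
  fit <- fit_binding_model(label ~ p_dd + entropy, data = dat,
                           min_per_class = 2L,
                           feature_config = list(features =
                                                   c("p_dd", "entropy")))
  p <- fit$fitted
  list(model = fit, auc = roc_auc(p[dat$label == 1], p[dat$label == 0]))
}

#' Benchmark harness: class-wise discrimination statistics
#'
#' Given per-residue scores and region-class labels (e.g. DOR / CDR / DDR /
#' DBR), computes, for each requested pair of classes, the AUC and
#' Mann--Whitney p-value of the entropy, of p_DD, and of the bivariate
#' logistic combination. Residues are pooled across proteins. This is the
#' evaluation machinery for externally curated datasets; published
#' benchmark figures additionally require the original curated regions and
#' an external NMR-trained disorder predictor, so no reference values are
#' asserted here.
#'
#' @param profile A `binding_profile` (or data.frame with `p_dd`,
#'   `entropy_bits`).
#' @param classes Character vector, one class label per profile row (`NA`
#'   rows are dropped).
#' @param pairs List of length-2 character vectors; default: all class
#'   pairs present.
#' @return data.frame with one row per (pair, statistic).
#' @export
benchmark_binding_modes <- function(profile, classes, pairs = NULL) {
  stopifnot(nrow(profile) == length(classes))
  keep <- !is.na(classes) & !is.na(profile$p_dd)
  prof <- profile[keep, , drop = FALSE]
  cls <- classes[keep]
  if (is.null(pairs)) {
    u <- sort(unique(cls))
    pairs <- utils::combn(u, 2, simplify = FALSE)
  }
  rows <- list()
  for (pr in pairs) {
    i1 <- cls == pr[1]; i2 <- cls == pr[2]
    for (stat in c("entropy_bits", "p_dd", "bivariate")) {
      if (stat == "bivariate") {
        sub <- i1 | i2
        bd <- bivariate_discrimination(prof$p_dd[sub],
                                       prof$entropy_bits[sub],
                                       as.numeric(i1[sub]))
        auc <- bd$auc; pv <- NA_real_
      } else {
        s1 <- prof[[stat]][i1]; s2 <- prof[[stat]][i2]
        auc <- roc_auc(s1, s2)
        pv <- mann_whitney(s1, s2)$p_value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(class1 = pr[1], class2 = pr[2], statistic = stat,
                   n1 = sum(i1), n2 = sum(i2), auc = auc, p_value = pv)
    }
  }
  do.call(rbind, rows)
}
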