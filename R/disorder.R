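#' Built-in fallback disorder predictor
#'
#' A charge/hydropathy unfoldability score so the pipeline can run without
#' any external disorder predictor. On a centred sliding window the
#' unfoldability u = 2.785 <H> - |<q>| - 1.151 is computed, where <H> is the
#' mean Kyte--Doolittle hydropathy rescaled to \[0, 1\] ((KD + 4.5)/9) and
#' <q> is the mean formal charge; the per-residue disorder score is
#' 0.5 - u clipped to \[0, 1\]. Hydrophobic, uncharged stretches therefore
#' score near 0 (ordered), charged hydrophilic stretches near 1
#' (disordered). Positions with unknown residues (`X`) take the scale means.
#'
#' Any external per-residue score in \[0, 1\] (e.g. from an NMR-trained
#' predictor) can be used instead via [read_score_table()]; results are
#' sensitive to that choice and trained model parameters record their score
#' source.
#'
#' @param seq A [protein_sequence()].
#' @param window Odd integer >= 3, smoothing window length (default 21). If
#'   it exceeds the sequence length the whole-sequence mean is used and a
#'   warning is emitted.
#' @return A `disorder_profile`.
#' @export
builtin_disorder <- function(seq, window = 21L) {
  stopifnot(inherits(seq, "protein_sequence"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("smoothing window must be odd and >= 3")
  chars <- seq_chars(seq)
  kd <- kyte_doolittle(); qv <- residue_charge()
  h <- (unname(kd[chars]) + 4.5) / 9
  q <- unname(qv[chars])
  h[is.na(h)] <- mean((kd + 4.5) / 9)  # X residues
  q[is.na(q)] <- 0
  n <- seq$n
  if (window > n) {
    warning("smoothing window (", window, ") exceeds sequence length (", n,
            "); using whole-sequence means")
    mh <- rep(mean(h), n); mq <- rep(mean(q), n)
  } else {
    half <- (window - 1L) %/% 2L
    mh <- numeric(n); mq <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      mh[i] <- mean(h[lo:hi]); mq[i] <- mean(q[lo:hi])
    }
  }
  u <- 2.785 * mh - abs(mq) - 1.151
  disorder_profile(pmin(1, pmax(0, 0.5 - u)), id = seq$id, residues = chars)
}

#' Validate a sequence / disorder-profile pair
#'
#' Checks that the profile has one score per residue and that identifiers
#' match (unless `override_id = TRUE`, which accepts mismatched ids with a
#' warning). Returns the validated pair used by all feature computations.
#'
#' @param seq A [protein_sequence()].
#' @param profile A [disorder_profile()].
#' @param override_id Accept mismatched identifiers.
#' @return List with elements `seq` and `profile`.
#' @export
attach_scores <- function(seq, profile, override_id = FALSE) {
  stopifnot(inherits(seq, "protein_sequence"),
            inherits(profile, "disorder_profile"))
  if (length(profile$scores) != seq$n)
    stop("profile length (", length(profile$scores),
         ") != sequence length (", seq$n, ") for '", seq$id, "'")
  if (!identical(seq$id, profile$id)) {
    if (!override_id)
      stop("id mismatch: sequence '", seq$id, "' vs profile '", profile$id,
           "' (set override_id = TRUE to accept)")
    warning("id mismatch accepted by override: '", seq$id, "' vs '",
            profile$id, "'")
  }
  if (!is.null(profile$residues)) {
    sc <- seq_chars(seq)
    cmp <- profile$residues != "X" & sc != "X" & profile$residues != sc
    if (any(cmp))
      stop("residue mismatch between sequence and profile at position ",
           which(cmp)[1])
  }
  list(seq = seq, profile = profile)
}
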