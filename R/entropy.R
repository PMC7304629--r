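#' Bin window probabilities into binding-mode frequencies
#'
#' The window-level disorder-to-order probabilities of a residue are binned
#' into 10 intervals of width 0.1 on \[0, 1\]. Bins are half-open
#' \[0, 0.1), ..., \[0.8, 0.9) with the final bin \[0.9, 1.0\] closed, so a
#' value of exactly 0.1 falls in bin 2 and exactly 1.0 in bin 10.
#'
#' @param window_pdos Numeric vector of probabilities in \[0, 1\].
#' @param n_bins Number of bins (default 10).
#' @return List of class `mode_distribution`: `counts` (integer, length
#'   `n_bins`), `frequencies` (counts / N), `n` (N), `breaks`.
#' @export
bin_frequencies <- function(window_pdos, n_bins = 10L) {
  p <- as.numeric(window_pdos)
  if (!length(p)) stop("empty probability set")
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("probabilities must lie in [0,1]")
  idx <- pmin(floor(p * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, n_bins)
  structure(list(counts = counts, frequencies = counts / length(p),
                 n = length(p),
                 breaks = seq(0, 1, length.out = n_bins + 1L)),
            class = "mode_distribution")
}

#' Shannon entropy of a binding-mode distribution
#'
#' -sum f log2 f over occupied bins (0 log 0 = 0), in bits. With 10 bins
#' the entropy lies in \[0, log2 10 ~ 3.32\]; low values mean one dominant
#' binding mode, high values a context-dependent spread over modes.
#'
#' @param dist A `mode_distribution` from [bin_frequencies()], or a raw
#'   frequency vector summing to 1.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(dist) {
  f <- if (inherits(dist, "mode_distribution")) dist$frequencies else
    as.numeric(dist)
  f <- f[f > 0]
  h <- -sum(f * log2(f))
  if (h == 0) 0 else h  # avoid IEEE negative zero for degenerate input
}

#' Default landscape classification thresholds
#'
#' The box boundaries on the (p_DD, S) plane. `do_*` / `dd_*` delimit the
#' low-entropy corners (single preferred binding mode), the `cd_entropy`
#' line opens the context-dependent (fuzzy) top band split at
#' `poly_pdd_max`, `condfold_pdd_max`, `dbr_pdd_max`. Anything outside all
#' five boxes is part of the continuum between modes.
#'
#' @return Named list of thresholds.
#' @export
landscape_thresholds <- function() {
  list(do_pdd_max = 0.25, dd_pdd_min = 0.65, uniform_entropy_max = 1.8,
       cd_entropy_min = 2.25, poly_pdd_max = 0.25,
       condfold_pdd_max = 0.45, dbr_pdd_max = 0.75)
}

#' Classify a residue on the binding-mode landscape
#'
#' Maps (p_DD, entropy) to one of six classes:
#' \describe{
#'   \item{disorder-to-order}{p_DD < 0.25 and S < 1.8: folds into a stable
#'     structure upon binding}
#'   \item{disorder-to-disorder}{p_DD > 0.65 and S < 1.8: remains
#'     disordered in the bound state}
#'   \item{polymorphic}{p_DD <= 0.25 and S > 2.25: folds, but into
#'     alternative structures with different partners}
#'   \item{conditional-folding}{0.25 < p_DD <= 0.45 and S > 2.25: folding
#'     inducible by specific partners or modifications}
#'   \item{disordered-binding}{0.45 < p_DD <= 0.75 and S > 2.25:
#'     conformational exchange persists in the complex}
#'   \item{continuum}{anything outside the five boxes}
#' }
#' Every point of \[0,1\] x \[0, log2 10\] receives exactly one label.
#'
#' @param p_dd Disorder-to-disorder probability (vector ok).
#' @param entropy Binding-mode Shannon entropy in bits (vector ok).
#' @param thresholds See [landscape_thresholds()].
#' @return Character vector of class labels.
#' @export
classify_landscape <- function(p_dd, entropy,
                               thresholds = landscape_thresholds()) {
  t <- thresholds
  stopifnot(length(p_dd) == length(entropy))
  out <- rep("continuum", length(p_dd))
  low <- entropy < t$uniform_entropy_max
  high <- entropy > t$cd_entropy_min
  out[low & p_dd < t$do_pdd_max] <- "disorder-to-order"
  out[low & p_dd > t$dd_pdd_min] <- "disorder-to-disorder"
  out[high & p_dd <= t$poly_pdd_max] <- "polymorphic"
  out[high & p_dd > t$poly_pdd_max & p_dd <= t$condfold_pdd_max] <-
    "conditional-folding"
  out[high & p_dd > t$condfold_pdd_max & p_dd <= t$dbr_pdd_max] <-
    "disordered-binding"
  out[is.na(p_dd) | is.na(entropy)] <- NA_character_
  out
}
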