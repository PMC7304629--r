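#' Window-level disorder-to-order probabilities for one residue
#'
#' Enumerates every 5--9-residue window containing position `i`, computes
#' its bias features against the 20-residue flanks, scores it with the
#' model and returns the logistic probabilities, in window-enumeration
#' order (by length, then start). Windows whose features cannot be computed
#' (excluded `X` residues, no flanks) are silently dropped; the caller sees
#' the survivor count.
#'
#' @param seq A [protein_sequence()].
#' @param i Residue position.
#' @param profile A [disorder_profile()] attached to `seq`.
#' @param model A `binding_model` or `binding_params`.
#' @param flank_len,min_len,max_len,composition_stat Feature configuration;
#'   defaults come from the model's recorded `feature_config`.
#' @return Numeric vector of p_DO(R_i) values (possibly length 0).
#' @export
window_pdo_set <- function(seq, i, profile, model,
                           flank_len = NULL, min_len = NULL, max_len = NULL,
                           composition_stat = NULL) {
  fc <- feature_config_of(model)
  if (is.null(flank_len)) flank_len <- fc$flank_len
  if (is.null(min_len)) min_len <- fc$min_len
  if (is.null(max_len)) max_len <- fc$max_len
  if (is.null(composition_stat)) composition_stat <- fc$composition_stat
  wins <- enumerate_windows(i, seq$n, min_len, max_len)
  if (!nrow(wins)) return(numeric())
  feats <- lapply(seq_len(nrow(wins)), function(k)
    bias_features(wins$start[k], wins$end[k], seq, profile,
                  flank_len = flank_len, composition_stat = composition_stat,
                  strict = FALSE))
  keep <- !vapply(feats, is.null, logical(1))
  if (!any(keep)) return(numeric())
  F <- do.call(rbind, feats[keep])
  pdo_from_score(score_region(F, model))
}

feature_config_of <- function(model) {
  fc <- if (!is.null(model$feature_config)) model$feature_config else list()
  defaults <- default_feature_config()
  for (nm in names(defaults)) if (is.null(fc[[nm]])) fc[[nm]] <- defaults[[nm]]
  fc
}

#' Median binding-mode probability of a residue
#'
#' The per-residue disorder-to-order probability is the sample median of
#' the window-level set; for even counts, the midpoint of the two central
#' order statistics. p_DD = 1 - p_DO.
#'
#' @param window_pdos Non-empty numeric vector of window probabilities.
#' @return Named vector `c(p_do, p_dd)`.
#' @export
residue_pdo <- function(window_pdos) {
  if (!length(window_pdos)) stop("empty window-probability set")
  m <- stats::median(window_pdos)
  c(p_do = m, p_dd = 1 - m)
}

#' Per-residue binding-mode profile of a sequence
#'
#' The main prediction routine: for every residue it collects the window
#' probability set, takes the median p_DO (and p_DD = 1 - p_DO), bins the
#' set into 10 binding-mode frequency bins, computes the Shannon entropy in
#' bits, and assigns the landscape class. Residues with no computable
#' window are emitted with `NA` values.
#'
#' @param seq A [protein_sequence()], or character string.
#' @param model A `binding_model` or `binding_params` (default:
#'   [default_model()]).
#' @param profile Optional [disorder_profile()]; if `NULL`, scores come
#'   from [builtin_disorder()].
#' @param thresholds Landscape thresholds, see [landscape_thresholds()].
#' @param ... Passed to [window_pdo_set()] (feature-configuration
#'   overrides).
#' @return A data.frame of class `binding_profile` with columns `id`,
#'   `position`, `residue`, `n_windows`, `p_do`, `p_dd`, `entropy_bits`,
#'   `landscape_class`.
#' @examples
#' seq <- protein_sequence(strrep("MEEPQSDPSV", 6), id = "demo")
#' prof <- predict_binding_modes(seq)
#' head(prof)
#' @export
predict_binding_modes <- function(seq, model = default_model(),
                                  profile = NULL,
                                  thresholds = landscape_thresholds(), ...) {
  if (is.character(seq)) seq <- protein_sequence(seq)
  stopifnot(inherits(seq, "protein_sequence"))
  if (is.null(profile)) profile <- builtin_disorder(seq)
  suppressWarnings(attach_scores(seq, profile, override_id = TRUE))
  chars <- seq_chars(seq)
  n <- seq$n
  p_do <- p_dd <- ent <- rep(NA_real_, n)
  nw <- integer(n)
  for (i in seq_len(n)) {
    pd <- window_pdo_set(seq, i, profile, model, ...)
    nw[i] <- length(pd)
    if (!length(pd)) next
    m <- residue_pdo(pd)
    p_do[i] <- m["p_do"]; p_dd[i] <- m["p_dd"]
    ent[i] <- shannon_entropy(bin_frequencies(pd))
  }
  out <- data.frame(id = seq$id, position = seq_len(n), residue = chars,
                    n_windows = nw, p_do = p_do, p_dd = p_dd,
                    entropy_bits = ent,
                    landscape_class = classify_landscape(p_dd, ent,
                                                         thresholds),
                    stringsAsFactors = FALSE)
  class(out) <- c("binding_profile", "data.frame")
  out
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("<binding_profile> ", x$id[1], ": ", nrow(x), " residues\n", sep = "")
  ok <- !is.na(x$p_do)
  if (any(ok)) {
    cat(sprintf("  median p_DO %.3f | median S %.2f bits\n",
                stats::median(x$p_do[ok]), stats::median(x$entropy_bits[ok])))
    tab <- table(x$landscape_class[ok])
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  NextMethod()
}

#' @export
summary.binding_profile <- function(object, ...) {
  ok <- !is.na(object$p_do)
  list(n = nrow(object),
       p_do = summary(object$p_do[ok]),
       entropy_bits = summary(object$entropy_bits[ok]),
       classes = table(object$landscape_class[ok]))
}

#' Plot a binding-mode profile
#'
#' `which = "tracks"` draws p_DD and entropy along the sequence;
#' `which = "landscape"` the (p_DD, S) scatter with the classification
#' boxes.
#'
#' @param x A `binding_profile`.
#' @param which `"tracks"` or `"landscape"`.
#' @param ... Further graphical parameters.
#' @export
plot.binding_profile <- function(x, which = c("tracks", "landscape"), ...) {
  which <- match.arg(which)
  ok <- !is.na(x$p_do)
  if (which == "tracks") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(x$position, x$p_dd, type = "l", ylim = c(0, 1),
                   xlab = "", ylab = expression(p[DD]), ...)
    graphics::abline(h = c(0.25, 0.65), lty = 3, col = "grey50")
    graphics::plot(x$position, x$entropy_bits, type = "l",
                   ylim = c(0, log2(10)), xlab = "position",
                   ylab = expression(S[A[i]] ~ "(bits)"), ...)
    graphics::abline(h = c(1.8, 2.25), lty = 3, col = "grey50")
  } else {
    t <- landscape_thresholds()
    graphics::plot(x$p_dd[ok], x$entropy_bits[ok], xlim = c(0, 1),
                   ylim = c(0, log2(10)), xlab = expression(p[DD]),
                   ylab = expression(S[A[i]] ~ "(bits)"), pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.6), ...)
    graphics::rect(0, 0, t$do_pdd_max, t$uniform_entropy_max, border = "blue")
    graphics::rect(t$dd_pdd_min, 0, 1, t$uniform_entropy_max,
                   border = "darkorange")
    graphics::rect(0, t$cd_entropy_min, t$poly_pdd_max, log2(10),
                   border = "skyblue")
    graphics::rect(t$poly_pdd_max, t$cd_entropy_min, t$condfold_pdd_max,
                   log2(10), border = "darkgreen")
    graphics::rect(t$condfold_pdd_max, t$cd_entropy_min, t$dbr_pdd_max,
                   log2(10), border = "orange")
  }
  invisible(x)
}
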