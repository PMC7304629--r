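#' Enumerate candidate binding windows containing a residue
#'
#' All windows of length 5--9 (by default) that contain position `i` and lie
#' entirely within the sequence. Away from the termini (i and n-i+1 both
#' >= 9, n >= 17) this gives the full set of 5+6+7+8+9 = 35 windows; the
#' terminal residues get exactly 5 (one placement per length).
#'
#' @param i 1-based residue position.
#' @param n Sequence length.
#' @param min_len,max_len Window length range (defaults 5 and 9).
#' @return data.frame with columns `start`, `length`, `end`, sorted by
#'   (length, start).
#' @export
enumerate_windows <- function(i, n, min_len = 5L, max_len = 9L) {
  i <- as.integer(i); n <- as.integer(n)
  if (i < 1L || i > n) stop("position ", i, " outside [1, ", n, "]")
  out <- list()
  for (L in seq.int(min_len, max_len)) {
    lo <- max(1L, i - L + 1L)
    hi <- min(i, n - L + 1L)
    if (hi >= lo) {
      st <- seq.int(lo, hi)
      out[[length(out) + 1L]] <- data.frame(start = st, length = L,
                                            end = st + L - 1L)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), length = integer(), end = integer()))
  do.call(rbind, out)
}

#' Flanking context of a binding window
#'
#' The up-to-20-residue stretches immediately preceding and following a
#' window, truncated at the termini. A window is rejected only when both
#' flanks would be empty (it spans the whole sequence).
#'
#' @param start,end 1-based window bounds (inclusive).
#' @param n Sequence length.
#' @param flank_len Maximum flank length (default 20).
#' @return List with integer vectors `left` and `right` (possibly empty).
#' @export
flank_of <- function(start, end, n, flank_len = 20L) {
  stopifnot(start >= 1L, end <= n, start <= end)
  left <- if (start > 1L) seq.int(max(1L, start - flank_len), start - 1L) else integer()
  right <- if (end < n) seq.int(end + 1L, min(n, end + flank_len)) else integer()
  if (!length(left) && !length(right))
    stop("window [", start, ",", end, "] spans the whole sequence: no flanks")
  list(left = left, right = right)
}

#' Region-vs-flank local bias features
#'
#' The three predictors of the binding-mode scoring function for a window
#' (candidate binding region) against its pooled flanks:
#' \describe{
#'   \item{delta_id}{mean disorder score of the window minus mean over the
#'     union of flank residues}
#'   \item{delta_a}{composition bias; by default the difference in mean
#'     TOP-IDP disorder propensity, or the L1 distance between the two
#'     length-20 composition frequency vectors when
#'     `composition_stat = "l1"`}
#'   \item{delta_h}{difference in mean Kyte--Doolittle hydropathy}
#' }
#' Left and right flank residues are pooled into a single mean so truncated
#' flanks weigh by their actual residue counts. Windows or flanks touching
#' an `X` residue are rejected (`NULL` is returned when `strict = FALSE`).
#'
#' @param start,end Window bounds.
#' @param seq A [protein_sequence()].
#' @param profile A [disorder_profile()] attached to `seq`.
#' @param flank_len Maximum flank length (default 20).
#' @param composition_stat `"topidp"` (default) or `"l1"`.
#' @param strict Error (`TRUE`, default) or return `NULL` (`FALSE`) on
#'   excluded residues / missing flanks.
#' @return Named numeric vector `c(delta_id, delta_a, delta_h)`, or `NULL`.
#' @export
bias_features <- function(start, end, seq, profile, flank_len = 20L,
                          composition_stat = c("topidp", "l1"),
                          strict = TRUE) {
  composition_stat <- match.arg(composition_stat)
  chars <- seq_chars(seq)
  fl <- tryCatch(flank_of(start, end, seq$n, flank_len), error = function(e) e)
  if (inherits(fl, "error")) {
    if (strict) stop(conditionMessage(fl)) else return(NULL)
  }
  win <- seq.int(start, end)
  flank <- c(fl$left, fl$right)
  if (any(chars[c(win, flank)] == "X")) {
    if (strict) stop("window [", start, ",", end,
                     "] or its flanks contain excluded (X) residues")
    return(NULL)
  }
  kd <- kyte_doolittle()
  delta_id <- mean(profile$scores[win]) - mean(profile$scores[flank])
  delta_h <- mean(kd[chars[win]]) - mean(kd[chars[flank]])
  delta_a <- if (composition_stat == "topidp") {
    ti <- top_idp()
    mean(ti[chars[win]]) - mean(ti[chars[flank]])
  } else {
    aa <- aa_alphabet()
    fw <- tabulate(match(chars[win], aa), 20L) / length(win)
    ff <- tabulate(match(chars[flank], aa), 20L) / length(flank)
    sum(abs(fw - ff))
  }
  c(delta_id = unname(delta_id), delta_a = unname(delta_a),
    delta_h = unname(delta_h))
}

#' Compute bias features for a table of labelled regions
#'
#' Turns curated regions (or any interval table) into the feature rows used
#' to train the scoring function: one example per region, features computed
#' for the whole annotated interval against its 20-residue flanks.
#'
#' @param regions data.frame with columns `id`, `start`, `end` and
#'   optionally `label`.
#' @param seqs Named list of [protein_sequence()] objects.
#' @param profiles Named list of [disorder_profile()] objects (same names).
#' @param flank_len,composition_stat Passed to [bias_features()].
#' @return data.frame with `id`, `start`, `end`, `delta_id`, `delta_a`,
#'   `delta_h` and `label` if present; regions whose features cannot be
#'   computed are dropped with a warning.
#' @export
featurize_regions <- function(regions, seqs, profiles, flank_len = 20L,
                              composition_stat = "topidp") {
  stopifnot(all(c("id", "start", "end") %in% names(regions)))
  rows <- vector("list", nrow(regions))
  for (k in seq_len(nrow(regions))) {
    id <- as.character(regions$id[k])
    if (is.null(seqs[[id]])) stop("no sequence for region id '", id, "'")
    f <- bias_features(regions$start[k], regions$end[k], seqs[[id]],
                       profiles[[id]], flank_len = flank_len,
                       composition_stat = composition_stat, strict = FALSE)
    if (is.null(f)) next
    row <- data.frame(id = id, start = regions$start[k], end = regions$end[k],
                      delta_id = f["delta_id"], delta_a = f["delta_a"],
                      delta_h = f["delta_h"], row.names = NULL)
    if ("label" %in% names(regions)) row$label <- regions$label[k]
    rows[[k]] <- row
  }
  kept <- !vapply(rows, is.null, logical(1))
  if (any(!kept))
    warning(sum(!kept), " region(s) dropped (excluded residues or no flanks)")
  do.call(rbind, rows[kept])
}
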