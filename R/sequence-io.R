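#' Construct a protein sequence object
#'
#' A `protein_sequence` is an identifier plus an ordered string over the 20
#' standard amino-acid one-letter codes, with 1-based contiguous positions.
#' Nonstandard letters (B, J, Z, U, O, and any other non-alphabet character)
#' are handled according to `nonstandard`: `"map"` (default) replaces them
#' with `"X"` -- downstream feature computation excludes any window or flank
#' touching an `X` -- while `"reject"` raises an error naming the offending
#' positions.
#'
#' @param residues Character scalar, the amino-acid sequence (case
#'   insensitive).
#' @param id Character scalar identifier.
#' @param nonstandard One of `"map"`, `"reject"`.
#' @return An object of class `protein_sequence`: a list with elements `id`,
#'   `residues` (upper-case string), `n` (length).
#' @export
protein_sequence <- function(residues, id = "seq", nonstandard = c("map", "reject")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- toupper(gsub("[[:space:]*]", "", residues))
  if (nchar(res) < 1L)
    stop("sequence '", id, "' is empty")
  chars <- strsplit(res, "")[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad)) {
    if (nonstandard == "reject")
      stop("sequence '", id, "' contains nonstandard residue(s) ",
           paste0(chars[bad], "@", bad, collapse = ", "))
    chars[bad] <- "X"
    res <- paste(chars, collapse = "")
  }
  structure(list(id = id, residues = res, n = nchar(res)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", x$n, " aa)\n", sep = "")
  shown <- if (x$n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat("  ", shown, "\n", sep = "")
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param nonstandard Policy for letters outside the 20-letter alphabet, see
#'   [protein_sequence()].
#' @return List of `protein_sequence` objects, input order preserved.
#' @export
read_fasta <- function(path, nonstandard = c("map", "reject")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  out <- lapply(seq_along(set), function(k)
    protein_sequence(as.character(set[[k]]), id = ids[k], nonstandard = nonstandard))
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A `protein_sequence` or list of them.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    cat(">", s$id, "\n", sep = "", file = con)
    starts <- seq(1L, s$n, by = width)
    for (st in starts)
      cat(substr(s$residues, st, min(st + width - 1L, s$n)), "\n",
          sep = "", file = con)
  }
  invisible(path)
}

#' Read a per-residue disorder-score table
#'
#' Expects a TSV with a header line and columns `position`, `residue`,
#' `score` (1-based positions, scores in \[0, 1\]). This is the carrier
#' format for scores produced by any external per-residue disorder
#' predictor, or by [builtin_disorder()].
#'
#' @param path Path to the TSV file.
#' @param id Sequence identifier to attach; defaults to the file stem.
#' @param seq Optional `protein_sequence` for residue-letter cross-checking.
#' @return A `disorder_profile`: list with `id`, `scores` (numeric vector),
#'   `residues` (character vector).
#' @export
read_score_table <- function(path, id = NULL, seq = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "residue", "score")
  if (!all(need %in% names(tab)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  pos <- as.integer(tab$position)
  if (any(pos != seq_along(pos)))
    stop("positions must be contiguous 1..n; first violation at row ",
         which(pos != seq_along(pos))[1])
  sc <- as.numeric(tab$score)
  bad <- which(!is.finite(sc) | sc < 0 | sc > 1)
  if (length(bad))
    stop("score outside [0,1] at position ", pos[bad[1]], " (", sc[bad[1]], ")")
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  prof <- disorder_profile(sc, id = id, residues = toupper(tab$residue))
  if (!is.null(seq)) attach_scores(seq, prof)  # validates
  prof
}

#' Construct a disorder profile
#'
#' @param scores Numeric vector of per-residue disorder scores in \[0, 1\].
#' @param id Sequence identifier.
#' @param residues Optional character vector of residue letters.
#' @return Object of class `disorder_profile`.
#' @export
disorder_profile <- function(scores, id = "seq", residues = NULL) {
  scores <- as.numeric(scores)
  if (!length(scores)) stop("empty score vector")
  if (any(!is.finite(scores) | scores < 0 | scores > 1))
    stop("disorder scores must lie in [0,1]")
  if (!is.null(residues) && length(residues) != length(scores))
    stop("residue letters and scores differ in length")
  structure(list(id = id, scores = scores, residues = residues),
            class = "disorder_profile")
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat("<disorder_profile> ", x$id, " (", length(x$scores),
      " residues, mean ", sprintf("%.3f", mean(x$scores)), ")\n", sep = "")
  invisible(x)
}

#' Write per-residue binding-mode profiles to a TSV file
#'
#' One row per residue with columns `id`, `position`, `residue`,
#' `n_windows`, `p_do`, `p_dd`, `entropy_bits`, `landscape_class`.
#' Numeric columns are written at fixed 6-decimal precision so that
#' re-writing identical profiles yields a byte-identical file.
#'
#' @param profiles A `binding_profile` data.frame (from
#'   [predict_binding_modes()]) or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, as.data.frame))
  rows <- rows[order(match(rows$id, unique(rows$id)), rows$position), ]
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  out <- data.frame(id = rows$id, position = rows$position,
                    residue = rows$residue, n_windows = rows$n_windows,
                    p_do = fmt(rows$p_do), p_dd = fmt(rows$p_dd),
                    entropy_bits = fmt(rows$entropy_bits),
                    landscape_class = rows$landscape_class,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a profile table written by [write_profile_table()]
#'
#' @param path Path to the TSV.
#' @return data.frame with the profile columns, numerics parsed.
#' @export
read_profile_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("p_do", "p_dd", "entropy_bits"))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  tab
}
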