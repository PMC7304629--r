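#' Per-residue observed/missing states from a coordinate file
#'
#' Reads a PDB or mmCIF file (dispatch on extension) and assigns each
#' position of a declared full-length sequence the state `O` (any
#' non-hydrogen atom modelled) or `M` (missing coordinates). Mapping is by
#' author residue numbering against positions 1..n of the declared
#' sequence. Terminal M-runs are flagged separately from internal ones
#' (construct-truncation screening). When `max_resolution` is set,
#' structures whose recorded crystallographic resolution is worse are
#' rejected.
#'
#' @param path Coordinate file (.pdb / .ent or .cif).
#' @param chain Chain identifier.
#' @param declared_length Length of the reference (full) sequence.
#' @param max_resolution Reject structures with resolution (Angstrom) above
#'   this value; `NULL` (default) disables the filter.
#' @return List of class `residue_observation`: `states` (character vector
#'   of "O"/"M"), `terminal` (logical: position in a terminal M-run),
#'   `nonstandard` (positions with modelled non-standard residues),
#'   `resolution`, `path`, `chain`.
#' @export
residue_order_states <- function(path, chain, declared_length,
                                 max_resolution = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  res <- structure_resolution(path)
  if (!is.null(max_resolution) && is.finite(res) && res > max_resolution)
    stop("structure ", basename(path), " rejected: resolution ", res,
         " A worse than ", max_resolution, " A")
  pdb <- read_structure(path)
  if (!any(pdb$atom$chain == chain))
    stop("chain '", chain, "' not found in ", basename(path))
  atoms <- heavy_atoms(pdb)
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  resno <- unique(atoms$resno)
  resno <- resno[resno >= 1 & resno <= declared_length]
  states <- rep("M", declared_length)
  states[resno] <- "O"
  std3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")
  ns <- unique(atoms$resno[!atoms$resid %in% std3])
  ns <- ns[ns >= 1 & ns <= declared_length]
  terminal <- rep(FALSE, declared_length)
  r <- rle(states)
  if (r$values[1] == "M") terminal[seq_len(r$lengths[1])] <- TRUE
  if (r$values[length(r$values)] == "M")
    terminal[(declared_length - r$lengths[length(r$lengths)] + 1L):
               declared_length] <- TRUE
  structure(list(states = states, terminal = terminal, nonstandard = ns,
                 resolution = res, path = path, chain = chain),
            class = "residue_observation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop hydrogens by element symbol when present, else by atom-name prefix
heavy_atoms <- function(pdb) {
  at <- pdb$atom
  h <- if (!is.null(at$elesy) && !all(is.na(at$elesy)))
    toupper(trimws(at$elesy)) == "H"
  else grepl("^[0-9]*H", trimws(at$elety))
  at[!h | is.na(h), , drop = FALSE]
}

read_structure <- function(path) {
  if (grepl("\\.cif$", path, ignore.case = TRUE))
    suppressWarnings(bio3d::read.cif(path)) else bio3d::read.pdb(path)
}

# crystallographic resolution from REMARK 2 (PDB) or refine/reflns (mmCIF)
structure_resolution <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(hit)) {
    v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s+([0-9.]+).*",
                                         "\\1", hit[1])))
    return(if (is.na(v)) NA_real_ else v)
  }
  hit <- grep("_refine\\.ls_d_res_high|_reflns\\.d_resolution_high", lines,
              value = TRUE)
  if (length(hit)) {
    v <- suppressWarnings(as.numeric(sub(".*?([0-9.]+)\\s*$", "\\1", hit[1])))
    return(if (is.na(v)) NA_real_ else v)
  }
  NA_real_
}

#' Disordered segments of an observation vector
#'
#' Maximal runs of missing (`M`) residues of at least `min_len` residues,
#' in position order. Terminal runs can be excluded (truncation-artefact
#' screening).
#'
#' @param obs A `residue_observation` or character vector of "O"/"M".
#' @param min_len Minimum segment length (default 5).
#' @param drop_terminal Exclude M-runs touching either terminus.
#' @return data.frame with columns `start`, `end`, `length`, `terminal`.
#' @export
disordered_segments <- function(obs, min_len = 5L, drop_terminal = FALSE) {
  states <- if (inherits(obs, "residue_observation")) obs$states else obs
  r <- rle(states == "M")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  out$terminal <- out$start == 1L | out$end == length(states)
  if (drop_terminal) out <- out[!out$terminal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface residues of a chain in a complex
#'
#' Positions of `chain` with any non-hydrogen atom within `cutoff` (default
#' 4.5 Angstrom) of any non-hydrogen atom of a different chain. Homotypic
#' contacts (identical sequences, e.g. dimerisation) count: only the chain
#' identifier must differ.
#'
#' @param path Coordinate file with at least two chains.
#' @param chain Chain whose interface residues are sought.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return Integer vector of author residue numbers.
#' @export
interface_residues <- function(path, chain, cutoff = 4.5) {
  pdb <- read_structure(path)
  at <- heavy_atoms(pdb)
  chains <- unique(at$chain)
  if (length(chains) < 2L)
    stop("structure ", basename(path), " has a single chain; ",
         "interface detection needs a complex")
  a <- at[at$chain == chain, , drop = FALSE]
  b <- at[at$chain != chain, , drop = FALSE]
  if (!nrow(a)) stop("chain '", chain, "' not found")
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  close <- rowSums(d2 <= cutoff^2 + 1e-9) > 0
  sort(unique(a$resno[close]))
}

#' Classify a disordered region by its binding modes across complexes
#'
#' Implements the structural dataset-assignment rules. The region must be
#' disordered (missing) in the monomer. Then, over all complex structures:
#' \describe{
#'   \item{DOR}{at least 5 consecutive region residues observed in every
#'     complex, and at least one region residue mediating an
#'     inter-molecular contact (interface)}
#'   \item{DDR}{region missing in the monomer and in every complex}
#'   \item{CDR}{at least 5 consecutive residues observed (with an interface
#'     contact in an ordered form) in some complex and missing in another}
#'   \item{unclassified}{anything else; evidence is retained}
#' }
#'
#' @param region Integer vector of positions, or `c(start, end)` via
#'   `start`/`end` arguments.
#' @param monomer_obs `residue_observation` of the monomeric structure.
#' @param complex_obs_list List of `residue_observation`s, one per complex.
#' @param interface_sets List (parallel to `complex_obs_list`) of integer
#'   vectors of interface positions, e.g. from [interface_residues()].
#' @param min_run Consecutive-residue requirement (default 5).
#' @return List of class `region_annotation`: `label`, `start`, `end`,
#'   `evidence` (per-complex summary data.frame).
#' @export
classify_region <- function(region, monomer_obs, complex_obs_list,
                            interface_sets, min_run = 5L) {
  if (length(region) == 2L && region[2] > region[1] + 1L)
    region <- seq.int(region[1], region[2])
  if (!length(complex_obs_list)) stop("no complex observations supplied")
  if (length(interface_sets) != length(complex_obs_list))
    stop("interface_sets must parallel complex_obs_list")
  mono <- states_of(monomer_obs)[region]
  if (any(mono != "M"))
    stop("region is not disordered (missing) in the monomer")

  longest_run <- function(x) if (any(x)) max(rle(x)$lengths[rle(x)$values]) else 0L
  ev <- data.frame(complex = seq_along(complex_obs_list),
                   ordered_run = NA_integer_, missing_run = NA_integer_,
                   interface = NA)
  for (k in seq_along(complex_obs_list)) {
    st <- states_of(complex_obs_list[[k]])[region]
    ev$ordered_run[k] <- longest_run(st == "O")
    ev$missing_run[k] <- longest_run(st == "M")
    ev$interface[k] <- length(intersect(region, interface_sets[[k]])) > 0
  }
  all_missing <- all(ev$ordered_run == 0L & ev$missing_run == length(region))
  ordered_everywhere <- all(ev$ordered_run >= min_run)
  ordered_with_iface <- ev$ordered_run >= min_run & ev$interface
  missing_somewhere <- ev$missing_run >= min_run

  label <- if (all_missing) "DDR"
  else if (ordered_everywhere && any(ev$interface)) "DOR"
  else if (any(ordered_with_iface) && any(missing_somewhere)) "CDR"
  else "unclassified"

  structure(list(label = label, start = min(region), end = max(region),
                 evidence = ev),
            class = "region_annotation")
}

states_of <- function(x) if (inherits(x, "residue_observation")) x$states else x

#' @export
print.region_annotation <- function(x, ...) {
  cat("<region_annotation> [", x$start, "-", x$end, "] ", x$label, "\n",
      sep = "")
  print(x$evidence)
  invisible(x)
}
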