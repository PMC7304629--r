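#' Simulate labelled training regions from a known logistic model
#'
#' Feature triples (delta_id, delta_a, delta_h) are drawn from independent
#' normals (optionally correlated via `chol_corr`), and each region's label
#' is Bernoulli with probability given by the logistic model at the true
#' parameters -- the generative counterpart of [fit_binding_model()], used
#' for parameter-recovery and coverage checks.
#'
#' @param n Number of regions.
#' @param lambda True length-3 coefficient vector.
#' @param gamma True intercept.
#' @param mean,sd Length-3 feature means and standard deviations. Defaults
#'   (mean 0; sd 0.2, 0.3, 1.5) reflect the magnitudes the three biases
#'   take on real sequences: disorder and propensity differences live on
#'   sub-unit scales, hydropathy differences on the Kyte--Doolittle scale.
#' @param chol_corr Optional 3x3 upper Cholesky factor of a feature
#'   correlation matrix.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return data.frame with `delta_id`, `delta_a`, `delta_h`, `p_true`,
#'   `label`.
#' @export
simulate_training_set <- function(n, lambda = c(2, -1, 0.5), gamma = -0.3,
                                  mean = c(0, 0, 0), sd = c(0.2, 0.3, 1.5),
                                  chol_corr = NULL, seed = NULL) {
  stopifnot(n >= 1, length(lambda) == 3, all(sd > 0))
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(3 * n), ncol = 3)
  if (!is.null(chol_corr)) Z <- Z %*% chol_corr
  F <- sweep(sweep(Z, 2, sd, "*"), 2, mean, "+")
  colnames(F) <- c("delta_id", "delta_a", "delta_h")
  p <- pdo_from_score(score_region(F, list(lambda = lambda, gamma = gamma)))
  data.frame(F, p_true = p, label = stats::rbinom(n, 1L, p))
}

#' Generate a sequence with engineered binding-region biases
#'
#' Background residues are drawn from a flat composition over the 20
#' standard amino acids; each designed region is resampled (exponentially
#' tilted by the Kyte--Doolittle and TOP-IDP scales, then
#' rejection-checked) until its realised mean hydropathy and
#' disorder-propensity shifts against the background are within `tol_h` /
#' `tol_a` of the targets. The disorder profile is flat at
#' `base_disorder` with seeded jitter, then each region's scores are
#' recentred to realise the requested region-vs-background mean shift
#' exactly (then clipped to \[0, 1\]).
#'
#' @param length Total sequence length.
#' @param regions data.frame with columns `start`, `end` and any of
#'   `delta_h` (target mean hydropathy shift), `delta_a` (target mean
#'   TOP-IDP shift), `delta_id` (target mean disorder-score shift);
#'   absent/NA targets default to 0. Regions must be disjoint, length >= 5,
#'   within bounds.
#' @param base_disorder Background mean disorder score (default 0.5).
#' @param jitter SD of the seeded disorder-score jitter (default 0.02).
#' @param tol_h,tol_a Realisation tolerances (defaults 0.2 and 0.15).
#' @param seed RNG seed (mandatory).
#' @param id Sequence identifier.
#' @return List with `seq` ([protein_sequence()]), `profile`
#'   ([disorder_profile()]), and `truth` (the region table with realised
#'   shifts appended).
#' @export
synth_sequence <- function(length, regions, base_disorder = 0.5,
                           jitter = 0.02, tol_h = 0.2, tol_a = 0.15,
                           seed, id = "synth") {
  stopifnot(length >= 5, !missing(seed))
  set.seed(seed)
  if (nrow(regions)) {
    stopifnot(all(regions$start >= 1), all(regions$end <= length),
              all(regions$end - regions$start + 1 >= 5))
    ord <- order(regions$start)
    regions <- regions[ord, , drop = FALSE]
    if (nrow(regions) > 1 &&
        any(regions$start[-1] <= regions$end[-nrow(regions)]))
      stop("designed regions overlap")
  }
  for (col in c("delta_h", "delta_a", "delta_id"))
    if (is.null(regions[[col]])) regions[[col]] <- 0
  regions[is.na(regions)] <- 0

  aa <- aa_alphabet(); kd <- kyte_doolittle(); ti <- top_idp()
  mean_kd <- mean(kd); mean_ti <- mean(ti)
  chars <- sample(aa, length, replace = TRUE)

  sample_region <- function(len, dh, da) {
    if (mean_kd + dh > max(kd) || mean_kd + dh < min(kd))
      stop("hydropathy target ", dh, " outside achievable range")
    if (mean_ti + da > max(ti) || mean_ti + da < min(ti))
      stop("composition target ", da, " outside achievable range")
    # exponential tilt toward the joint target, then rejection on both
    tilt <- function(bh, ba) {
      w <- exp(bh * kd + ba * ti); w / sum(w)
    }
    obj <- function(b) {
      w <- tilt(b[1], b[2])
      (sum(w * kd) - (mean_kd + dh))^2 + (sum(w * ti) - (mean_ti + da))^2
    }
    b <- stats::optim(c(0, 0), obj)$par
    w <- tilt(b[1], b[2])
    for (try in 1:2000) {
      r <- sample(aa, len, replace = TRUE, prob = w)
      if (abs(mean(kd[r]) - mean_kd - dh) <= tol_h &&
          abs(mean(ti[r]) - mean_ti - da) <= tol_a)
        return(r)
    }
    stop("could not realise composition targets (delta_h=", dh,
         ", delta_a=", da, ") within tolerance")
  }

  for (k in seq_len(nrow(regions))) {
    idx <- seq.int(regions$start[k], regions$end[k])
    chars[idx] <- sample_region(length(idx), regions$delta_h[k],
                                regions$delta_a[k])
  }
  scores <- pmin(1, pmax(0, base_disorder + stats::rnorm(length, 0, jitter)))
  bg <- rep(TRUE, length)
  for (k in seq_len(nrow(regions)))
    bg[seq.int(regions$start[k], regions$end[k])] <- FALSE
  for (k in seq_len(nrow(regions))) {
    idx <- seq.int(regions$start[k], regions$end[k])
    target <- mean(scores[bg]) + regions$delta_id[k]
    if (target < 0 || target > 1)
      stop("disorder-shift target unachievable (region mean ", target, ")")
    scores[idx] <- scores[idx] - mean(scores[idx]) + target
    scores[idx] <- pmin(1, pmax(0, scores[idx]))
  }
  seqobj <- protein_sequence(paste(chars, collapse = ""), id = id)
  prof <- disorder_profile(scores, id = id, residues = chars)
  for (k in seq_len(nrow(regions))) {
    idx <- seq.int(regions$start[k], regions$end[k])
    regions$realised_delta_h[k] <- mean(kd[chars[idx]]) - mean(kd[chars[bg]])
    regions$realised_delta_a[k] <- mean(ti[chars[idx]]) - mean(ti[chars[bg]])
    regions$realised_delta_id[k] <- mean(scores[idx]) - mean(scores[bg])
  }
  list(seq = seqobj, profile = prof, truth = regions)
}

#' Generate toy monomer/complex structure files with a planned O/M pattern
#'
#' Writes minimal PDB files realising a per-structure observed/missing plan
#' on an idealised extended chain (CA/N/C backbone at 3.8 Angstrom CA
#' spacing). Complexes get a second chain; in "ordered + contact"
#' structures a partner atom is placed 4.0 Angstrom from a designated
#' region residue so the 4.5 Angstrom interface rule fires, otherwise the
#' partner sits 30 Angstrom away. Returns the files plus the truth label
#' the curation rules should reproduce.
#'
#' @param n Declared sequence length.
#' @param region `c(start, end)` of the designed disordered region.
#' @param plan Character vector over the complexes, each one of
#'   `"ordered_contact"`, `"ordered_nocontact"`, `"missing"`.
#' @param dir Output directory (created).
#' @param prefix File-name prefix.
#' @return List: `monomer` (path), `complexes` (paths), `chain` ("A"),
#'   `truth` (expected label: DOR / DDR / CDR / unclassified), `region`.
#' @export
synth_structures <- function(n, region, plan, dir = tempfile("structs"),
                             prefix = "toy") {
  stopifnot(length(region) == 2L, region[1] >= 1, region[2] <= n,
            region[2] - region[1] + 1 >= 5)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- seq.int(region[1], region[2])

  write_toy_pdb <- function(path, present, partner = NULL) {
    lines <- character()
    serial <- 0L
    for (i in which(present)) {
      for (at in c("N", "CA", "C")) {
        serial <- serial + 1L
        off <- switch(at, N = -1.2, CA = 0, C = 1.2)
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, at, "GLY", "A", i, 3.8 * i + off, 0, 0,
          substr(at, 1, 1)))
      }
    }
    if (!is.null(partner)) {
      # partner chain B: CA trace; one residue near `partner$near` if contact
      for (j in 1:6) {
        serial <- serial + 1L
        y <- if (!is.null(partner$near) && j == 1) partner$y else 30
        x <- if (!is.null(partner$near) && j == 1) 3.8 * partner$near
             else 3.8 * j
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, "CA", "GLY", "B", j, x, y, 0, "C"))
      }
    }
    writeLines(c(lines, "END"), path)
    path
  }

  present_mono <- rep(TRUE, n); present_mono[reg] <- FALSE
  monomer <- write_toy_pdb(file.path(dir, paste0(prefix, "_monomer.pdb")),
                           present_mono)
  complexes <- character(length(plan))
  for (k in seq_along(plan)) {
    present <- rep(TRUE, n)
    partner <- list(near = NULL)
    if (plan[k] == "missing") {
      present[reg] <- FALSE
      partner <- list(near = NULL)
    } else if (plan[k] == "ordered_contact") {
      partner <- list(near = reg[1], y = 4.0)
    } else if (plan[k] == "ordered_nocontact") {
      partner <- list(near = NULL)
    } else stop("unknown plan entry '", plan[k], "'")
    complexes[k] <- write_toy_pdb(
      file.path(dir, sprintf("%s_complex%02d.pdb", prefix, k)), present,
      partner)
  }
  truth <- if (all(plan == "missing")) "DDR"
  else if (all(plan != "missing") && any(plan == "ordered_contact")) "DOR"
  else if (any(plan == "ordered_contact") && any(plan == "missing")) "CDR"
  else "unclassified"
  list(monomer = monomer, complexes = complexes, chain = "A",
       truth = truth, region = region)
}

#' Run the curation rules on a synthetic structure set
#'
#' Convenience wrapper: derives observations and interface sets from the
#' files produced by [synth_structures()] and classifies the designed
#' region.
#'
#' @param s Output of [synth_structures()].
#' @param n Declared sequence length.
#' @return A `region_annotation`.
#' @export
curate_synth <- function(s, n) {
  mono <- residue_order_states(s$monomer, s$chain, n)
  cplx <- lapply(s$complexes, residue_order_states, chain = s$chain,
                 declared_length = n)
  ifaces <- lapply(s$complexes, function(p) {
    tryCatch(interface_residues(p, s$chain), error = function(e) integer())
  })
  classify_region(seq.int(s$region[1], s$region[2]), mono, cplx, ifaces)
}
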