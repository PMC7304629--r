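#' Amino-acid scales used by the feature calculations
#'
#' `kyte_doolittle()` returns the Kyte--Doolittle hydropathy scale,
#' `top_idp()` the TOP-IDP disorder-propensity scale (Campen et al. 2008),
#' and `residue_charge()` the formal side-chain charge at neutral pH
#' (K, R = +1; D, E = -1; all others 0). All are named numeric vectors over
#' the 20 standard one-letter codes.
#'
#' @return Named numeric vector of length 20.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' @rdname kyte_doolittle
#' @export
top_idp <- function() {
  c(A =  0.060, R =  0.180, N =  0.007, D =  0.192, C =  0.020,
    Q =  0.318, E =  0.736, G =  0.166, H =  0.303, I = -0.486,
    L = -0.326, K =  0.586, M = -0.397, F = -0.697, P =  0.987,
    S =  0.341, T =  0.059, W = -0.884, Y = -0.510, V = -0.121)
}

#' @rdname kyte_doolittle
#' @export
residue_charge <- function() {
  ch <- setNames(numeric(20), names(kyte_doolittle()))
  ch[c("K", "R")] <- 1
  ch[c("D", "E")] <- -1
  ch
}

# the 20 standard one-letter codes, fixed order
aa_alphabet <- function() names(kyte_doolittle())
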