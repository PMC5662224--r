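#' Default kinetic rate set for the regulatory circuits
#'
#' Returns the mass-action rate constants used by all circuit schemes.
#' With unit volume, molecule numbers and concentrations are equivalent and
#' every propensity carries units of s^-1.  Defaults correspond to rates
#' typical of prokaryotic gene expression: an mRNA lifetime of ~5 min, a
#' protein lifetime set by dilution at a ~69-min doubling time, and a
#' repressor pool of ~1,000 molecules per cell at full induction.
#'
#' @param kTX1 Transcription rate of the gene-of-interest DNA (s^-1 per free
#'   DNA copy).
#' @param kTX2 Transcription rate of the separate repressor DNA (s^-1); in
#'   the hybrid scheme this is the weak constitutive promoter, default
#'   6.7e-4 s^-1 there (see [build_network()]).
#' @param kTL_P Translation rate of the protein of interest from M1
#'   (s^-1 per mRNA).  The burst size is \code{kTL_P / deg_M}.
#' @param kTL_R Translation rate of the repressor (s^-1 per mRNA).
#' @param k_rep_on,k_rep_off Repressor-DNA association/dissociation (s^-1).
#' @param k_ind_on,k_ind_off Repressor-inducer association/dissociation
#'   (s^-1).
#' @param deg_M mRNA degradation rate, both transcripts (s^-1).
#' @param deg_P,deg_R,deg_RI First-order removal (degradation/dilution) of
#'   protein, free repressor, and inducer-bound repressor (s^-1).
#'   DNA-bound repressor is protected from degradation; degradation of
#'   inducer-bound repressor liberates its inducer molecule.
#' @return An object of class \code{rate_set} (a named list of rates).
#' @export
#' @examples
#' r <- rate_set()
#' r$kTL_P / r$deg_M   # burst size b, ~203 proteins per transcript
rate_set <- function(kTX1 = 1.7e-3,
                     kTX2 = 1.7e-3,
                     kTL_P = 0.67,
                     kTL_R = 0.0333,
                     k_rep_on = 1e-5,
                     k_rep_off = 1e-4,
                     k_ind_on = 1e-5,
                     k_ind_off = 1e-7,
                     deg_M = 0.0033,
                     deg_P = 1.6667e-4,
                     deg_R = 1.6667e-4,
                     deg_RI = 1.6667e-4) {
  r <- list(kTX1 = kTX1, kTX2 = kTX2, kTL_P = kTL_P, kTL_R = kTL_R,
            k_rep_on = k_rep_on, k_rep_off = k_rep_off,
            k_ind_on = k_ind_on, k_ind_off = k_ind_off,
            deg_M = deg_M, deg_P = deg_P, deg_R = deg_R, deg_RI = deg_RI)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("rate '", nm, "' must be a single finite non-negative number")
  }
  structure(r, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> (all units s^-1)\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Names of the supported circuit schemes
#'
#' The five regulatory schemes: (i) constitutive expression, (ii) repression
#' by a constitutively expressed repressor, (iii) repression by an
#' autoregulated repressor expressed from a separate gene, (iv) bicistronic
#' autoregulation (gene of interest and repressor on one transcript), and
#' (v) a hybrid in which the repressor is expressed both bicistronically
#' and from a weak, never-repressed constitutive promoter.
#'
#' @return Character vector of scheme names, in (i)..(v) order.
#' @export
circuit_schemes <- function() {
  c("constitutive", "constitutive_repressor", "autoregulated_repressor",
    "bicistronic_autoregulation", "hybrid")
}
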