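# Species indices used throughout: D1, D1R, D2, D2R, M1, M2, P, R, RI, I.
# D1/D2 are free DNA copies; D1R/D2R repressor-bound (transcriptionally
# silent, protected from degradation); RI inducer-bound repressor.

circuit_species <- c("D1", "D1R", "D2", "D2R", "M1", "M2", "P", "R", "RI", "I")

# Full reaction table.  Each row: name, reactants (species=order), net
# stoichiometry change, rate name or fixed value, translation flag, and the
# schemes that include it.
.reaction_table <- function(rates) {
  S <- circuit_species
  rx <- function(name, react, net, rate, tl, schemes) {
    reac <- integer(length(S)); names(reac) <- S
    chg <- integer(length(S)); names(chg) <- S
    reac[names(react)] <- unlist(react)
    chg[names(net)] <- unlist(net)
    list(name = name, reactants = reac, net = chg, rate = rate,
         is_translation = tl, schemes = schemes)
  }
  list(
    rx("transcription_D1", list(D1 = 1L), list(M1 = 1L), rates$kTX1, FALSE,
       c("constitutive", "constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("transcription_D2", list(D2 = 1L), list(M2 = 1L), rates$kTX2, FALSE,
       c("constitutive_repressor", "autoregulated_repressor", "hybrid")),
    rx("repression_D1_on", list(D1 = 1L, R = 1L),
       list(D1 = -1L, R = -1L, D1R = 1L), rates$k_rep_on, FALSE,
       c("constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("repression_D1_off", list(D1R = 1L),
       list(D1R = -1L, D1 = 1L, R = 1L), rates$k_rep_off, FALSE,
       c("constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("repression_D2_on", list(D2 = 1L, R = 1L),
       list(D2 = -1L, R = -1L, D2R = 1L), rates$k_rep_on, FALSE,
       "autoregulated_repressor"),
    rx("repression_D2_off", list(D2R = 1L),
       list(D2R = -1L, D2 = 1L, R = 1L), rates$k_rep_off, FALSE,
       "autoregulated_repressor"),
    rx("translation_P", list(M1 = 1L), list(P = 1L), rates$kTL_P, TRUE,
       c("constitutive", "constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("translation_R_M1", list(M1 = 1L), list(R = 1L), rates$kTL_R, TRUE,
       c("bicistronic_autoregulation", "hybrid")),
    rx("translation_R_M2", list(M2 = 1L), list(R = 1L), rates$kTL_R, TRUE,
       c("constitutive_repressor", "autoregulated_repressor", "hybrid")),
    rx("induction_on", list(R = 1L, I = 1L),
       list(R = -1L, I = -1L, RI = 1L), rates$k_ind_on, FALSE,
       c("constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("induction_off", list(RI = 1L),
       list(RI = -1L, R = 1L, I = 1L), rates$k_ind_off, FALSE,
       c("constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("degradation_M1", list(M1 = 1L), list(M1 = -1L), rates$deg_M, FALSE,
       c("constitutive", "constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("degradation_M2", list(M2 = 1L), list(M2 = -1L), rates$deg_M, FALSE,
       c("constitutive_repressor", "autoregulated_repressor", "hybrid")),
    rx("degradation_P", list(P = 1L), list(P = -1L), rates$deg_P, FALSE,
       c("constitutive", "constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("degradation_R", list(R = 1L), list(R = -1L), rates$deg_R, FALSE,
       c("constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid")),
    rx("degradation_RI", list(RI = 1L), list(RI = -1L, I = 1L),
       rates$deg_RI, FALSE,
       c("constitutive_repressor", "autoregulated_repressor",
         "bicistronic_autoregulation", "hybrid"))
  )
}

#' Build a regulatory-circuit reaction network
#'
#' Assembles the concrete mass-action reaction list for one of the five
#' circuit schemes.  Repression is monomeric binding of free repressor R to
#' free DNA (no cooperativity); bound DNA (D1R, D2R) neither transcribes nor
#' loses its repressor to degradation.  One inducer molecule binding R
#' prevents DNA binding; degradation of inducer-bound repressor liberates
#' the inducer.  In the hybrid scheme the second (weak) promoter is never
#' repressed.
#'
#' Inducer handling has two limits.  In \code{"fast"} mode the free-inducer
#' count is held constant (rapid exchange with the environment): binding,
#' unbinding and repressor degradation leave I unchanged.  In \code{"slow"}
#' mode the inducer pool is conserved: I + RI stays at its initial value.
#'
#' @param scheme One of [circuit_schemes()] (or a roman numeral
#'   \code{"i"}..\code{"v"}).
#' @param rates A [rate_set()].  For the hybrid scheme, if \code{kTX2} is
#'   left at the \code{rate_set()} default it is replaced by the hybrid
#'   default 6.7e-4 s^-1 (about 40% of the autoregulated promoter's rate).
#' @param n_dna1 Copies of the gene-of-interest DNA (default 10,
#'   plasmid-like copy number).
#' @param n_dna2 Copies of the separate repressor DNA; defaults to 10 for
#'   schemes using it and 0 otherwise.
#' @param inducer Initial free-inducer molecule count.
#' @param inducer_mode \code{"fast"} (constant free count) or \code{"slow"}
#'   (conserved pool).
#' @return An object of class \code{network_spec}: species names, reaction
#'   names, reactant-order matrix, net-stoichiometry matrix, rate vector,
#'   translation flags, initial state (all DNA unrepressed, no mRNA or
#'   protein, \code{inducer} free inducer), and the arguments used.
#' @export
#' @examples
#' net <- build_network("bicistronic_autoregulation", inducer = 1000)
#' length(net$reactions)  # 11 reactions
build_network <- function(scheme,
                          rates = rate_set(),
                          n_dna1 = 10,
                          n_dna2 = NULL,
                          inducer = 0,
                          inducer_mode = c("fast", "slow")) {
  roman <- c(i = "constitutive", ii = "constitutive_repressor",
             iii = "autoregulated_repressor", iv = "bicistronic_autoregulation",
             v = "hybrid")
  if (is.character(scheme) && scheme %in% names(roman))
    scheme <- roman[[scheme]]
  scheme <- match.arg(scheme, circuit_schemes())
  inducer_mode <- match.arg(inducer_mode)
  stopifnot(inherits(rates, "rate_set"))
  if (n_dna1 < 1) stop("n_dna1 must be >= 1")
  if (inducer < 0) stop("inducer count must be >= 0")

  uses_dna2 <- scheme %in% c("constitutive_repressor",
                             "autoregulated_repressor", "hybrid")
  if (is.null(n_dna2)) n_dna2 <- if (uses_dna2) 10 else 0
  if (n_dna2 < 0) stop("n_dna2 must be >= 0")
  if (uses_dna2 && n_dna2 < 1)
    stop("scheme '", scheme, "' transcribes the separate repressor gene; n_dna2 must be >= 1")

  if (scheme == "hybrid" && identical(rates$kTX2, rate_set()$kTX2))
    rates$kTX2 <- 6.7e-4

  tab <- .reaction_table(rates)
  keep <- vapply(tab, function(r) scheme %in% r$schemes, logical(1))
  tab <- tab[keep]

  S <- circuit_species
  reactants <- vapply(tab, function(r) r$reactants, integer(length(S)))
  net <- vapply(tab, function(r) r$net, integer(length(S)))
  rownames(reactants) <- rownames(net) <- S

  if (inducer_mode == "fast") net["I", ] <- 0L

  init <- stats::setNames(integer(length(S)), S)
  init["D1"] <- as.integer(n_dna1)
  init["D2"] <- as.integer(n_dna2)
  init["I"] <- as.integer(round(inducer))

  structure(list(
    scheme = scheme,
    species = S,
    reactions = vapply(tab, `[[`, character(1), "name"),
    reactants = reactants,
    net = net,
    rates_vec = vapply(tab, `[[`, numeric(1), "rate"),
    is_translation = vapply(tab, `[[`, logical(1), "is_translation"),
    init = init,
    rates = rates,
    n_dna1 = as.integer(n_dna1),
    n_dna2 = as.integer(n_dna2),
    inducer = as.integer(round(inducer)),
    inducer_mode = inducer_mode
  ), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$scheme, "\n")
  cat("  reactions:", length(x$reactions),
      " DNA copies:", x$n_dna1, "/", x$n_dna2,
      " inducer:", x$inducer, paste0("(", x$inducer_mode, ")"), "\n")
  invisible(x)
}

#' Read a circuit configuration file
#'
#' Reads a JSON or YAML file describing a circuit (fields: \code{scheme},
#' optional \code{rates} overrides, \code{n_dna1}, \code{n_dna2},
#' \code{inducer}, \code{inducer_mode}) and returns the built network.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{network_spec}.
#' @export
read_circuit_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$scheme)) stop("config must name a 'scheme'")
  rates <- do.call(rate_set, as.list(cfg$rates %||% list()))
  build_network(cfg$scheme, rates,
                n_dna1 = cfg$n_dna1 %||% 10,
                n_dna2 = cfg$n_dna2 %||% NULL,
                inducer = cfg$inducer %||% 0,
                inducer_mode = cfg$inducer_mode %||% "fast")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
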