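# Coulomb constant in kcal * Angstrom / (mol * e^2) and Hartree conversion.
COULOMB_KCAL <- 332.0637
HARTREE_KCAL <- 627.509474

#' Construct an interaction-energy record
#'
#' Holds a total interaction energy and its electrostatic, exchange,
#' induction and dispersion components, labelled by the method that produced
#' them (for quantum records also basis set and exchange scaling).
#'
#' @param total,electrostatic,exchange,induction,dispersion energies in
#'   kcal/mol.
#' @param method label, e.g. `"surrogate"` or `"SAPT0"`.
#' @param basis optional basis-set label.
#' @param scaled logical, exchange-scaled variant.
#' @return object of class `energy_record`.
#' @export
energy_record <- function(total, electrostatic, exchange, induction, dispersion,
                          method = "surrogate", basis = NA_character_,
                          scaled = FALSE) {
  structure(list(total = total, electrostatic = electrostatic,
                 exchange = exchange, induction = induction,
                 dispersion = dispersion, method = method, basis = basis,
                 scaled = scaled),
            class = "energy_record")
}

#' @export
print.energy_record <- function(x, ...) {
  cat(sprintf(
    "<%s energy: total %.4f (elst %.4f, exch %.4f, ind %.4f, disp %.4f) kcal/mol>\n",
    x$method, x$total, x$electrostatic, x$exchange, x$induction, x$dispersion))
  invisible(x)
}

#' Classical surrogate parameters
#'
#' Per-element Lennard-Jones well depths and minimum-energy radii for the
#' classical surrogate backend. Atomic partial charges come from the monomers
#' themselves (`partial_charges`).
#'
#' @param epsilon named numeric, element -> well depth in kcal/mol.
#' @param r_min named numeric, element -> pair minimum-energy radius in
#'   Angstrom (combined arithmetically across elements).
#' @return object of class `surrogate_params`.
#' @export
surrogate_params <- function(
    epsilon = c(H = 0.03, C = 0.07, N = 0.17, O = 0.21, F = 0.06,
                Na = 0.047, S = 0.25, Cl = 0.265, Br = 0.32),
    r_min = c(H = 2.4, C = 3.8, N = 3.6, O = 3.5, F = 3.4,
              Na = 2.7, S = 4.0, Cl = 4.4, Br = 4.4)) {
  stopifnot(all(epsilon > 0), all(r_min > 0))
  structure(list(epsilon = epsilon, r_min = r_min), class = "surrogate_params")
}

#' Classical surrogate interaction energy
#'
#' Pairwise intermolecular Coulomb plus Lennard-Jones model standing behind
#' the pluggable energy-backend contract: electrostatics from atomic partial
#' charges (constant 332.0637 kcal A / (mol e^2)), exchange as the 12-power
#' repulsion, dispersion as the -6-power attraction
#' (eps * ((rm/r)^12 - 2 (rm/r)^6), minimum -eps at rm), induction zero.
#' Intra-monomer pairs are excluded. Lorentz-Berthelot combination:
#' arithmetic-mean radii, geometric-mean well depths.
#'
#' @param config `dimer_config` whose monomers carry `partial_charges`.
#' @param params [surrogate_params].
#' @return [energy_record] with `total = sum(components)` exactly.
#' @export
surrogate_energy <- function(config, params = surrogate_params()) {
  qp <- config$protein$partial_charges
  ql <- config$ligand$partial_charges
  if (is.null(qp) || is.null(ql))
    stop("surrogate backend needs partial charges on both monomers")
  elP <- config$protein$elements; elL <- config$ligand$elements
  missing_el <- setdiff(unique(c(elP, elL)),
                        intersect(names(params$epsilon), names(params$r_min)))
  if (length(missing_el) > 0)
    stop("no surrogate parameters for element(s): ",
         paste(missing_el, collapse = ", "))
  P <- config$protein$coords; L <- config$ligand$coords
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  d <- sqrt(pmax(d2, 1e-12))
  elst <- COULOMB_KCAL * sum(outer(qp, ql) / d)
  eps <- sqrt(outer(params$epsilon[elP], params$epsilon[elL]))
  rm_ <- outer(params$r_min[elP], params$r_min[elL], "+") / 2
  s6 <- (rm_ / d)^6
  exch <- sum(eps * s6 * s6)
  disp <- -2 * sum(eps * s6)
  energy_record(total = elst + exch + disp + 0,
                electrostatic = elst, exchange = exch,
                induction = 0, dispersion = disp, method = "surrogate")
}

#' Surrogate backend closure
#'
#' Wraps [surrogate_energy] into the backend contract used by
#' [generate_batch]: a function mapping a `dimer_config` to an
#' [energy_record]. Monomer partial charges ride on the configuration.
#'
#' @param params [surrogate_params].
#' @param charges optional named list, monomer name -> per-atom partial
#'   charges, overriding/supplying charges for monomers lacking them.
#' @return function `dimer_config -> energy_record`.
#' @export
surrogate_backend <- function(params = surrogate_params(), charges = NULL) {
  function(config) {
    if (!is.null(charges)) {
      if (is.null(config$protein$partial_charges))
        config$protein$partial_charges <- charges[[config$protein$name]]
      if (is.null(config$ligand$partial_charges))
        config$ligand$partial_charges <- charges[[config$ligand$name]]
    }
    surrogate_energy(config, params)
  }
}

#' Constant-energy stub backend
#'
#' Returns the same record for every configuration; useful for exercising the
#' batch loop deterministically.
#'
#' @param total energy in kcal/mol.
#' @return backend function.
#' @export
backend_constant <- function(total = -1) {
  function(config) energy_record(total, total, 0, 0, 0, method = "stub")
}

#' Scripted stub backend
#'
#' Replays a fixed sequence of total energies (recycled), independent of the
#' configuration; useful for driving the rejection-retry schedule in tests.
#'
#' @param totals numeric vector of totals in kcal/mol, replayed in order.
#' @return backend function with state.
#' @export
backend_script <- function(totals) {
  i <- 0L
  function(config) {
    i <<- i + 1L
    t <- totals[((i - 1L) %% length(totals)) + 1L]
    energy_record(t, t, 0, 0, 0, method = "stub")
  }
}

#' Accept or reject a configuration on its total energy
#'
#' @param record [energy_record].
#' @param like_charged logical; like-charged (repulsive) dimers use the
#'   higher threshold.
#' @param policy [rejection_policy].
#' @return TRUE to accept, FALSE to reject.
#' @export
accept_energy <- function(record, like_charged = FALSE,
                          policy = rejection_policy()) {
  if (!is.finite(record$total)) stop("non-finite total energy")
  thr <- if (like_charged) policy$charged_repulsive_threshold else policy$threshold
  record$total <= thr
}

#' Non-electrostatic part of an energy record
#'
#' Sum of the exchange, induction and dispersion components; used in place of
#' the total when judging the interaction range of charged dimers, whose bare
#' Coulomb term decays too slowly to define a sensible cutoff.
#'
#' @param record [energy_record].
#' @return energy in kcal/mol.
#' @export
nonelectrostatic_total <- function(record) {
  record$exchange + record$induction + record$dispersion
}
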