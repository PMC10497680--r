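# ---- radial specification ---------------------------------------------------

#' Radial sampling specification
#'
#' Bounds for the van der Waals separation `r`: sampling is uniform on
#' \[`r_min`, `r_switch`\] and the density decreases linearly to zero on
#' \[`r_switch`, `r_max`\], biasing draws away from the weakly interacting
#' large-separation region.
#'
#' @param r_min,r_switch,r_max bounds in Angstrom, `r_min <= r_switch <= r_max`.
#' @return object of class `radial_spec`.
#' @export
radial_spec <- function(r_min, r_switch, r_max) {
  stopifnot(is.finite(r_min), is.finite(r_switch), is.finite(r_max),
            r_min <= r_switch, r_switch <= r_max)
  structure(list(r_min = r_min, r_switch = r_switch, r_max = r_max),
            class = "radial_spec")
}

#' Default radial bounds by dimer class
#'
#' The six default rows keyed by monomer charge states and interaction-site
#' class. Specific (HBD/HBA or LB/LA) sites reach deeper clash than general
#' sites because hydrogen-bonded and Lewis pairs remain attractive at closer
#' approach; like-charged pairs never clash favourably so their `r_min` is 0.
#'
#' @return data.frame with columns `charge_states`, `site_class`, `r_min`,
#'   `r_max`, `r_switch`.
#' @export
default_radial_table <- function() {
  data.frame(
    charge_states = c("opposite-charged", "like-charged",
                      "charged/neutral", "charged/neutral",
                      "neutral/neutral", "neutral/neutral"),
    site_class = c("any", "any", "general", "specific", "general", "specific"),
    r_min = c(-1.8, 0.0, -1.0, -1.6, -1.0, -1.3),
    r_max = c(5.0, 5.0, 5.0, 5.0, 3.0, 3.0),
    r_switch = c(1.5, 2.5, 1.5, 1.5, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Look up the radial spec for a site dimer
#'
#' @param charge_class one of "neutral/neutral", "charged/neutral",
#'   "like-charged", "opposite-charged".
#' @param pair_class pair class string from [enumerate_site_dimers]
#'   ("general/general" or a specific class).
#' @param table radial bounds table, defaulting to [default_radial_table].
#' @return [radial_spec].
#' @export
radial_spec_for <- function(charge_class, pair_class,
                            table = default_radial_table()) {
  site_class <- if (identical(pair_class, "general/general")) "general" else "specific"
  hit <- table[table$charge_states == charge_class &
                 table$site_class %in% c(site_class, "any"), , drop = FALSE]
  if (nrow(hit) == 0)
    stop("no radial spec for ", charge_class, " / ", pair_class)
  radial_spec(hit$r_min[1], hit$r_switch[1], hit$r_max[1])
}

#' Sample van der Waals separations from the biased radial density
#'
#' Inverse-CDF draws from the density that is constant on
#' \[`r_min`, `r_switch`\] and decreases linearly to zero at `r_max`. When
#' `upper` is given (rejection retry chains), the density is truncated at
#' `upper` and renormalized.
#'
#' @param spec [radial_spec].
#' @param n number of draws.
#' @param upper optional upper truncation in Angstrom, clamped to
#'   \[`r_min`, `r_max`\].
#' @return numeric vector of separations in Angstrom.
#' @export
sample_r <- function(spec, n = 1, upper = NULL) {
  a <- spec$r_min; s <- spec$r_switch; b <- spec$r_max
  if (is.null(upper)) upper <- b
  upper <- min(max(upper, a), b)
  if (upper <= a) return(rep(a, n))
  # areas under unit-height density: rectangle then truncated triangle
  c_tri <- b - s
  area_at <- function(x) {
    rect <- pmin(x, s) - a
    tri <- if (x > s) (x - s) - (x - s)^2 / (2 * c_tri) else 0
    rect + tri
  }
  total <- area_at(upper)
  v <- runif(n, 0, total)
  out <- numeric(n)
  rect_area <- s - a
  in_rect <- v <= rect_area
  out[in_rect] <- a + v[in_rect]
  if (any(!in_rect)) {
    w <- v[!in_rect] - rect_area
    out[!in_rect] <- s + c_tri * (1 - sqrt(pmax(0, 1 - 2 * w / c_tri)))
  }
  out
}

#' Closed-form CDF of the biased radial density
#'
#' Used by tests and diagnostics to compare empirical draws against the
#' target distribution.
#'
#' @param x quantiles in Angstrom.
#' @param spec [radial_spec].
#' @param upper optional truncation (as in [sample_r]).
#' @return cumulative probabilities.
#' @export
radial_cdf <- function(x, spec, upper = NULL) {
  a <- spec$r_min; s <- spec$r_switch; b <- spec$r_max
  if (is.null(upper)) upper <- b
  upper <- min(max(upper, a), b)
  c_tri <- b - s
  area_at <- function(q) {
    q <- pmin(pmax(q, a), upper)
    rect <- pmin(q, s) - a
    tri <- ifelse(q > s, (q - s) - (q - s)^2 / (2 * c_tri), 0)
    rect + tri
  }
  area_at(x) / area_at(upper)
}

# ---- angular sampling -------------------------------------------------------

# Uniform draw over a union of closed intervals, length-weighted.
sample_interval_union <- function(union, n = 1) {
  len <- union[, 2] - union[, 1]
  if (sum(len) <= 0) {
    if (nrow(union) == 0) stop("empty interval union")
    return(rep(union[1, 1], n))  # degenerate point interval(s)
  }
  k <- sample.int(nrow(union), n, replace = TRUE, prob = len)
  runif(n, union[k, 1], union[k, 2])
}

#' Sample the five angular internal coordinates
#'
#' `theta_P`, `tau_P`, `theta_L`, `tau_L` are drawn uniformly over the
#' owning site's allowed interval unions (length-weighted across intervals);
#' `tau_PL` is always uniform over (-180, 180].
#'
#' @param site_P,site_L [interaction_site]s.
#' @return named numeric vector of the five angles in degrees.
#' @export
sample_angles <- function(site_P, site_L) {
  if (nrow(site_P$theta_range) == 0 || nrow(site_L$theta_range) == 0 ||
      nrow(site_P$tau_range) == 0 || nrow(site_L$tau_range) == 0)
    stop("empty allowed interval union on a site")
  c(theta_P = sample_interval_union(site_P$theta_range),
    tau_P = sample_interval_union(site_P$tau_range),
    theta_L = sample_interval_union(site_L$theta_range),
    tau_L = sample_interval_union(site_L$tau_range),
    tau_PL = runif(1, -180, 180))
}

# ---- coordinate perturbation ------------------------------------------------

#' Perturb every atom by a small random displacement
#'
#' Each atom is independently displaced along a uniformly oriented direction
#' by a distance uniform on \[0, `max_disp`\]. The unperturbed coordinates are
#' retained on the configuration (`$pre_perturb`).
#'
#' @param config `dimer_config`.
#' @param max_disp maximum displacement in Angstrom (default 0.1).
#' @return perturbed `dimer_config` with `perturbed = TRUE`.
#' @export
perturb_coordinates <- function(config, max_disp = 0.1) {
  stopifnot(max_disp >= 0)
  jitter1 <- function(coords) {
    n <- nrow(coords)
    dir <- matrix(rnorm(3 * n), n, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    coords + dir * runif(n, 0, max_disp)
  }
  config$pre_perturb <- list(protein = config$protein$coords,
                             ligand = config$ligand$coords)
  if (max_disp > 0) {
    config$protein$coords <- jitter1(config$protein$coords)
    config$ligand$coords <- jitter1(config$ligand$coords)
  }
  config$perturbed <- TRUE
  config
}

# ---- rejection policy and batch loop ----------------------------------------

#' Energy rejection policy
#'
#' Configurations whose total energy exceeds `threshold` (20 kcal/mol) are
#' rejected; like-charged (repulsive) dimers use
#' `charged_repulsive_threshold` (200 kcal/mol) instead because their
#' electrostatic floor is high everywhere. After each consecutive rejection
#' the radial upper bound for the next attempt expands by `expansion_step`
#' above the first rejected `r`.
#'
#' @param threshold kcal/mol, default 20.
#' @param charged_repulsive_threshold kcal/mol, default 200.
#' @param expansion_step Angstrom, default 0.1.
#' @return object of class `rejection_policy`.
#' @export
rejection_policy <- function(threshold = 20, charged_repulsive_threshold = 200,
                             expansion_step = 0.1) {
  stopifnot(threshold > 0, charged_repulsive_threshold > 0, expansion_step > 0)
  structure(list(threshold = threshold,
                 charged_repulsive_threshold = charged_repulsive_threshold,
                 expansion_step = expansion_step),
            class = "rejection_policy")
}

#' Generate a batch of accepted dimer configurations
#'
#' For one interaction-site dimer, repeats until `n` configurations are
#' accepted: sample the five angles, sample `r` from the (possibly truncated)
#' biased radial density, solve the translation (resampling on infeasible
#' separations), build the Cartesian dimer, perturb every atom by up to
#' `max_disp`, evaluate the energy backend, and accept if the total is at or
#' below the policy threshold. After the k-th consecutive rejection the next
#' attempt draws `r` from \[`r_min`, `r_first_rejected` + k * 0.1\]; the range
#' resets on acceptance.
#'
#' @param mono_P,mono_L [monomer]s.
#' @param site_P,site_L their [interaction_site]s.
#' @param spec [radial_spec] for this dimer class.
#' @param backend function `dimer_config -> energy_record`.
#' @param policy [rejection_policy].
#' @param n number of accepted configurations (default 50).
#' @param like_charged logical; use the 200 kcal/mol threshold.
#' @param radii [vdw_radii] table.
#' @param max_disp per-atom perturbation bound in Angstrom.
#' @param site_dimer_id provenance label.
#' @param max_attempts safety cap on total attempts.
#' @return list of accepted `dimer_config`s, with an `attempt_log`
#'   attribute (data.frame: attempt, index, r_target, upper_bound, total,
#'   accepted).
#' @export
generate_batch <- function(mono_P, mono_L, site_P, site_L, spec, backend,
                           policy = rejection_policy(), n = 50,
                           like_charged = FALSE, radii = vdw_radii(),
                           max_disp = 0.1,
                           site_dimer_id = paste(site_P$id, site_L$id, sep = "|"),
                           max_attempts = 200 * n) {
  accepted <- vector("list", n)
  log <- list()
  attempt <- 0L
  k_fail <- 0L
  r_first_rejected <- NA_real_
  i <- 1L
  while (i <= n) {
    if (attempt >= max_attempts)
      stop("exceeded ", max_attempts, " attempts for site dimer ", site_dimer_id)
    attempt <- attempt + 1L
    upper <- if (k_fail > 0L)
      min(spec$r_max, r_first_rejected + k_fail * policy$expansion_step)
    else NULL
    angles <- sample_angles(site_P, site_L)
    r_target <- sample_r(spec, 1, upper = upper)
    r_PL <- tryCatch(
      solve_translation(mono_P, mono_L, site_P, site_L, angles, r_target, radii),
      dimergen_infeasible_separation = function(e) NA_real_)
    if (is.na(r_PL)) next  # resample; infeasibility is not an energy rejection
    ic <- internal_coords(r_PL, angles[["theta_P"]], angles[["tau_P"]],
                          angles[["theta_L"]], angles[["tau_L"]],
                          angles[["tau_PL"]], r = r_target)
    config <- cartesian_from_internal(mono_P, mono_L, site_P, site_L, ic,
                                      site_dimer_id = site_dimer_id, index = i)
    config <- perturb_coordinates(config, max_disp)
    rec <- tryCatch(backend(config), error = function(e) {
      tryCatch(backend(config), error = function(e2) {
        warning("energy backend failed twice for ", site_dimer_id,
                " attempt ", attempt, ": ", conditionMessage(e2))
        NULL
      })
    })
    if (is.null(rec)) next
    ok <- accept_energy(rec, like_charged = like_charged, policy = policy)
    log[[length(log) + 1L]] <- data.frame(
      attempt = attempt, index = i, r_target = r_target,
      upper_bound = if (is.null(upper)) spec$r_max else upper,
      total = rec$total, accepted = ok)
    if (ok) {
      config$energies <- list(rec)
      accepted[[i]] <- config
      i <- i + 1L
      k_fail <- 0L
      r_first_rejected <- NA_real_
    } else {
      if (k_fail == 0L) r_first_rejected <- r_target
      k_fail <- k_fail + 1L
    }
  }
  attr(accepted, "attempt_log") <- do.call(rbind, log)
  accepted
}

# Derive a reproducible per-site-dimer seed from a run seed and an ordinal.
substream_seed <- function(seed, ordinal) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(ordinal) * 16807) %% 2147483647)
}
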