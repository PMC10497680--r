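#' @importFrom stats runif rnorm setNames
#' @importFrom utils write.csv head tail
NULL

# ---- element tables ---------------------------------------------------------

#' Van der Waals radii (Alvarez set) with ion overrides
#'
#' Returns a named vector of van der Waals radii in Angstrom. Defaults are the
#' Alvarez crystallographic radii; the sodium entry is overridden to 1.50 A
#' (down from the published 2.50 A) so that sodium complexes sample the same
#' region of the intermolecular potential as other cations.
#'
#' @param overrides named numeric vector of radii replacing or extending the
#'   defaults (e.g. `c(Na = 2.50)` to restore the published sodium value).
#' @return named numeric vector, element symbol -> radius in Angstrom.
#' @export
vdw_radii <- function(overrides = NULL) {
  r <- c(
    H = 1.20, C = 1.77, N = 1.66, O = 1.50, F = 1.46,
    Na = 1.50, P = 1.90, S = 1.89, Cl = 1.82, Br = 1.86, I = 2.04
  )
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    r[names(overrides)] <- overrides
  }
  if (any(r <= 0)) stop("all van der Waals radii must be positive")
  r
}

# Covalent radii (Cordero) used for distance-based bond perception.
covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

#' Substitution map used to sanitize monomer names
#'
#' Dataset filenames join fields with underscores, so monomer names must be
#' strictly alphanumeric. Each non-alphanumeric character is replaced by a
#' fixed token (for example `(` becomes `x`); characters absent from the map
#' are dropped.
#' @export
name_substitutions <- c(
  "(" = "x", ")" = "y", "+" = "p", "-" = "m",
  "," = "q", "." = "d", " " = "", "_" = "",
  "[" = "x", "]" = "y", "'" = ""
)

#' Sanitize an identifier into a filename-safe monomer name
#'
#' @param x character vector of raw names.
#' @param map named character substitution map; see [name_substitutions].
#' @return character vector of alphanumeric names.
#' @export
sanitize_name <- function(x, map = name_substitutions) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9]$", ch)) ch
      else if (ch %in% names(map)) unname(map[ch])
      else ""
    }, character(1))
    paste0(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- angular interval unions ------------------------------------------------

# Normalize an angle to (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Build a normalized union of angular intervals
#'
#' `theta` intervals are clamped to \[0, 180\]; `tau` intervals are wrapped to
#' (-180, 180\], splitting intervals that cross the branch cut (e.g.
#' \[135, 225\] becomes \[135, 180\] and \[-180, -135\]).
#'
#' @param intervals two-column matrix (lo, hi) in degrees, or NULL for the
#'   full range.
#' @param kind "theta" or "tau".
#' @return two-column matrix of normalized closed intervals, sorted by lower
#'   bound.
#' @export
angle_union <- function(intervals = NULL, kind = c("theta", "tau")) {
  kind <- match.arg(kind)
  full <- if (kind == "theta") c(0, 180) else c(-180, 180)
  if (is.null(intervals)) intervals <- matrix(full, ncol = 2)
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (any(intervals[, 2] < intervals[, 1])) stop("interval hi < lo")
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    lo <- intervals[i, 1]; hi <- intervals[i, 2]
    if (kind == "theta") {
      out[[length(out) + 1L]] <- c(max(0, lo), min(180, hi))
    } else {
      if (hi - lo >= 360) { out[[length(out) + 1L]] <- c(-180, 180); next }
      # wrap the lower end into [-180, 180) so -180 stays a valid left edge
      lo_w <- lo - 360 * floor((lo + 180) / 360)
      hi_w <- lo_w + (hi - lo)
      if (hi_w <= 180) {
        out[[length(out) + 1L]] <- c(lo_w, hi_w)
      } else {
        out[[length(out) + 1L]] <- c(lo_w, 180)
        out[[length(out) + 1L]] <- c(-180, hi_w - 360)
      }
    }
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("lo", "hi")
  m
}

# Is an angle inside a normalized interval union (closed intervals)?
in_union <- function(x, union, tol = 1e-9) {
  any(x >= union[, 1] - tol & x <= union[, 2] + tol)
}

# Parse "[90,180]" or "[-45,45];[135,225]" into a raw interval matrix.
parse_interval_string <- function(s) {
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  m <- t(vapply(parts, function(p) {
    nums <- regmatches(p, gregexpr("-?[0-9.]+", p))[[1]]
    if (length(nums) != 2) stop("cannot parse interval: ", p)
    as.numeric(nums)
  }, numeric(2)))
  unname(m)
}

format_interval_union <- function(u) {
  paste(apply(u, 1, function(r) {
    sprintf("[%s,%s]", format(r[1], trim = TRUE), format(r[2], trim = TRUE))
  }), collapse = ";")
}

# ---- monomer ----------------------------------------------------------------

#' Construct a monomer
#'
#' A monomer is a rigid molecule or conformer with fixed 3D coordinates, a
#' formal charge, and a set label ("protein" or "ligand"). Its heavy-atom bond
#' graph is perceived from covalent radii at construction and retained as the
#' reference connectivity for downstream change detection.
#'
#' @param name alphanumeric identifier (see [sanitize_name]).
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of Cartesian coordinates in Angstrom.
#' @param charge integer formal charge in elementary charges.
#' @param set "protein" or "ligand".
#' @param partial_charges optional per-atom partial charges (for the
#'   classical surrogate energy backend); must sum to `charge` within 1e-6.
#' @return object of class `monomer`.
#' @export
monomer <- function(name, elements, coords, charge = 0L,
                    set = c("protein", "ligand"), partial_charges = NULL) {
  set <- match.arg(set)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) < 1) stop("monomer needs at least one atom")
  if (nrow(coords) != length(elements)) stop("coords/elements length mismatch")
  if (!all(is.finite(coords))) stop("non-finite coordinates in monomer ", name)
  if (!is.null(partial_charges)) {
    if (length(partial_charges) != length(elements))
      stop("partial_charges length mismatch")
    if (abs(sum(partial_charges) - charge) > 1e-6)
      stop("partial charges of ", name, " do not sum to the formal charge")
  }
  g <- bond_graph(elements, coords)
  obj <- list(
    name = name, elements = elements, coords = coords,
    charge = as.integer(charge), set = set,
    partial_charges = partial_charges,
    graph = g,
    h_assignment = assign_hydrogens(elements, coords)
  )
  class(obj) <- "monomer"
  obj
}

#' @export
print.monomer <- function(x, ...) {
  cat(sprintf("<monomer %s: %d atoms, charge %+d, %s set>\n",
              x$name, length(x$elements), x$charge, x$set))
  invisible(x)
}

#' @export
format.monomer <- function(x, ...) {
  sprintf("%s (%d atoms, %+d)", x$name, length(x$elements), x$charge)
}

charge_class <- function(charge) {
  if (charge > 0) "cation" else if (charge < 0) "anion" else "neutral"
}

# ---- interaction site -------------------------------------------------------

#' Construct an interaction site
#'
#' An interaction site anchors the intermolecular coordinate system on a
#' monomer: three noncollinear reference points A, B, C (not necessarily
#' atomic centres), a category, and allowed ranges for the polar angle theta
#' and the dihedral tau.
#'
#' @param monomer_name name of the owning monomer.
#' @param category one of "general", "HBD", "HBA", "LB", "LA".
#' @param A,B,C numeric length-3 points in Angstrom.
#' @param theta_range,tau_range interval matrices (lo, hi) in degrees, or NULL
#'   for the unrestricted default; see [angle_union].
#' @param id optional site identifier (defaults to name/category).
#' @return object of class `interaction_site`.
#' @export
interaction_site <- function(monomer_name, category, A, B, C,
                             theta_range = NULL, tau_range = NULL, id = NULL) {
  cats <- c("general", "HBD", "HBA", "LB", "LA")
  category <- cats[match(tolower(category), tolower(cats))]
  if (is.na(category)) stop("unknown site category")
  A <- as.numeric(A); B <- as.numeric(B); C <- as.numeric(C)
  stopifnot(length(A) == 3, length(B) == 3, length(C) == 3)
  v1 <- B - A; v2 <- C - A
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-8 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
    stop("site points A, B, C are collinear for monomer ", monomer_name)
  obj <- list(
    monomer = monomer_name, category = category,
    A = A, B = B, C = C,
    theta_range = angle_union(theta_range, "theta"),
    tau_range = angle_union(tau_range, "tau"),
    id = if (is.null(id)) paste(monomer_name, category, sep = ":") else id
  )
  class(obj) <- "interaction_site"
  obj
}

#' @export
print.interaction_site <- function(x, ...) {
  cat(sprintf("<site %s [%s] on %s>\n", x$id, x$category, x$monomer))
  invisible(x)
}

# Tabulate a list of interaction_site objects (used by the pairing module).
site_table <- function(sites, monomers) {
  stopifnot(length(sites) > 0)
  mono_charge <- vapply(monomers, function(m) m$charge, integer(1))
  names(mono_charge) <- vapply(monomers, function(m) m$name, character(1))
  data.frame(
    site_id = vapply(sites, function(s) s$id, character(1)),
    monomer = vapply(sites, function(s) s$monomer, character(1)),
    category = vapply(sites, function(s) s$category, character(1)),
    charge = unname(mono_charge[vapply(sites, function(s) s$monomer, character(1))]),
    stringsAsFactors = FALSE
  )
}

# ---- SD (V2000) I/O ---------------------------------------------------------
# Minimal fixed-width V2000 serializer. Deliberately self-contained: it must
# round-trip monoatomic ions (Na+, Cl-) and records with appended dummy site
# atoms, both of which fall outside what general cheminformatics SDF classes
# accept.

sd_format_record <- function(name, elements, coords, bonds, datablock) {
  n <- length(elements)
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  lines <- c(
    name, "  dimergen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], elements))
  if (nb > 0)
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2],
                              rep(1L, nb)))
  lines <- c(lines, "M  END")
  for (key in names(datablock))
    lines <- c(lines, sprintf("> <%s>", key), datablock[[key]], "")
  c(lines, "$$$$")
}

sd_parse_records <- function(path) {
  lines <- readLines(path)
  idx <- c(0L, which(lines == "$$$$"))
  out <- list()
  for (k in seq_len(length(idx) - 1L)) {
    rec <- lines[(idx[k] + 1L):(idx[k + 1L] - 1L)]
    rec <- rec[cumsum(nzchar(rec) | seq_along(rec) > 1) > 0]
    parsed <- tryCatch({
      name <- rec[1]
      n <- as.integer(substr(rec[4], 1, 3))
      nb <- as.integer(substr(rec[4], 4, 6))
      if (is.na(n) || n < 1) stop("bad counts line")
      atoms <- rec[5:(4 + n)]
      coords <- matrix(NA_real_, n, 3)
      coords[, 1] <- as.numeric(substr(atoms, 1, 10))
      coords[, 2] <- as.numeric(substr(atoms, 11, 20))
      coords[, 3] <- as.numeric(substr(atoms, 21, 30))
      if (any(is.na(coords))) stop("missing coordinates")
      elements <- trimws(substr(atoms, 31, 34))
      bonds <- NULL
      if (!is.na(nb) && nb > 0) {
        bl <- rec[(5 + n):(4 + n + nb)]
        bonds <- cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)))
      }
      db <- character(0)
      keys <- grep("^> *<.+>", rec)
      for (i in keys)
        db[sub("^> *<(.+)>.*$", "\\1", rec[i])] <- rec[i + 1L]
      list(name = name, elements = elements, coords = coords, bonds = bonds,
           datablock = db)
    }, error = function(e)
      stop("malformed SD record ", k, " in ", path, ": ", conditionMessage(e)))
    out[[k]] <- parsed
  }
  out
}

sd_prop <- function(rec, key, default = NULL) {
  if (key %in% names(rec$datablock)) unname(rec$datablock[[key]]) else default
}

#' Read monomers from an SD file
#'
#' One monomer per SD record. The formal charge is taken from the
#' `FORMAL_CHARGE` data field (default 0) and the set label from `SET`
#' (default given by `set`). The heavy-atom reference bond graph is perceived
#' from covalent radii. Per-atom partial charges for the surrogate backend
#' may be supplied in a `PARTIAL_CHARGES` field (space-separated).
#'
#' @param path SD (V2000) file.
#' @param set default set label when a record lacks a `SET` field.
#' @return named list of [monomer] objects.
#' @export
read_monomers <- function(path, set = "ligand") {
  recs <- sd_parse_records(path)
  out <- list()
  for (rec in recs) {
    pc <- sd_prop(rec, "PARTIAL_CHARGES")
    if (!is.null(pc)) pc <- as.numeric(strsplit(trimws(pc), "[[:space:]]+")[[1]])
    m <- monomer(
      name = rec$name, elements = rec$elements, coords = rec$coords,
      charge = as.integer(sd_prop(rec, "FORMAL_CHARGE", "0")),
      set = sd_prop(rec, "SET", set),
      partial_charges = pc
    )
    out[[m$name]] <- m
  }
  out
}

#' Write monomers to an SD file
#'
#' @param monomers list of [monomer] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_monomers <- function(monomers, path) {
  lines <- unlist(lapply(monomers, function(m) {
    db <- c(SET = m$set, FORMAL_CHARGE = as.character(m$charge))
    if (!is.null(m$partial_charges))
      db <- c(db, PARTIAL_CHARGES = paste(format(m$partial_charges, trim = TRUE),
                                          collapse = " "))
    # heavy-atom graph edges (original atom indices) plus H attachments
    heavy <- which(m$elements != "H")
    bonds <- igraph::as_edgelist(m$graph, names = FALSE)
    bonds <- if (nrow(bonds) > 0) cbind(heavy[bonds[, 1]], heavy[bonds[, 2]])
             else matrix(integer(0), 0, 2)
    hs <- which(!is.na(m$h_assignment))
    if (length(hs) > 0) bonds <- rbind(bonds, cbind(m$h_assignment[hs], hs))
    sd_format_record(m$name, m$elements, m$coords, bonds, db)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read interaction sites from an SD file with appended site atoms
#'
#' Each record holds the owning monomer's atoms followed by exactly three
#' trailing dummy atoms of element `I` giving points A, B, C in order. Data
#' fields: `SITE_TYPE` (general/HBD/HBA/LB/LA), optional `THETA_RANGE` and
#' `TAU_RANGE` interval strings such as `"[90,180]"` or
#' `"[-45,45];[135,225]"`; absent ranges default to the full range.
#'
#' @param path SD file.
#' @return list of [interaction_site] objects.
#' @export
read_sites <- function(path) {
  recs <- sd_parse_records(path)
  out <- list()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    el <- rec$elements
    n <- length(el)
    if (n < 4 || any(el[(n - 2):n] != "I") || el[n - 3] == "I")
      stop("record ", i, ": expected exactly 3 trailing dummy 'I' atoms")
    th <- sd_prop(rec, "THETA_RANGE")
    ta <- sd_prop(rec, "TAU_RANGE")
    s <- interaction_site(
      monomer_name = rec$name,
      category = sd_prop(rec, "SITE_TYPE", "general"),
      A = rec$coords[n - 2, ], B = rec$coords[n - 1, ], C = rec$coords[n, ],
      theta_range = if (is.null(th)) NULL else parse_interval_string(th),
      tau_range = if (is.null(ta)) NULL else parse_interval_string(ta),
      id = sd_prop(rec, "SITE_ID")
    )
    out[[length(out) + 1L]] <- s
  }
  out
}

#' Write interaction sites to an SD file
#'
#' Inverse of [read_sites]: each site is written as its monomer's atoms plus
#' three trailing `I` dummy atoms at A, B, C.
#'
#' @param sites list of [interaction_site] objects.
#' @param monomers named list of [monomer] objects covering all site owners.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, monomers, path) {
  lines <- unlist(lapply(sites, function(s) {
    m <- monomers[[s$monomer]]
    if (is.null(m)) stop("no monomer named ", s$monomer)
    el <- c(m$elements, "I", "I", "I")
    coords <- rbind(m$coords, s$A, s$B, s$C)
    db <- c(SET = m$set, FORMAL_CHARGE = as.character(m$charge),
            SITE_TYPE = s$category,
            THETA_RANGE = format_interval_union(s$theta_range),
            TAU_RANGE = format_interval_union(s$tau_range),
            SITE_ID = s$id)
    sd_format_record(m$name, el, coords, NULL, db)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
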