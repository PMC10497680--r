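# ---- energy label slots -----------------------------------------------------

splinter_bases <- c("jun-cc-pV(D + d)Z", "aug-cc-pV(D + d)Z")
splinter_components <- c("total", "electrostatic", "exchange", "induction",
                         "dispersion")

#' The 20 energy label slots of a Splinter record
#'
#' Fields 5-24 of the metadata line: for each basis set (jun then aug), the
#' unscaled then exchange-scaled total/electrostatic/exchange/induction/
#' dispersion energies, all in kcal/mol.
#'
#' @return data.frame with columns `field`, `key`, `basis`, `scaled`,
#'   `component`.
#' @export
splinter_energy_fields <- function() {
  rows <- expand.grid(component = splinter_components,
                      scaled = c(FALSE, TRUE),
                      basis = splinter_bases,
                      stringsAsFactors = FALSE)
  rows$field <- 4L + seq_len(nrow(rows))
  rows$key <- paste(ifelse(rows$basis == splinter_bases[1], "jun", "aug"),
                    ifelse(rows$scaled, "scaled", "unscaled"),
                    rows$component, sep = ".")
  rows[, c("field", "key", "basis", "scaled", "component")]
}

#' Map energy records onto the 20 Splinter slots
#'
#' @param records list of [energy_record]s carrying `basis`
#'   (`"jun"`/`"aug"` or full basis string) and `scaled` labels.
#' @return named numeric over the 20 slot keys; unset slots are NA.
#' @export
energy_slots <- function(records) {
  ef <- splinter_energy_fields()
  out <- setNames(rep(NA_real_, nrow(ef)), ef$key)
  for (rec in records) {
    b <- if (is.na(rec$basis)) NA_character_
         else if (grepl("^jun", rec$basis)) "jun"
         else if (grepl("^aug", rec$basis)) "aug"
         else NA_character_
    if (is.na(b)) next
    pre <- paste(b, ifelse(isTRUE(rec$scaled), "scaled", "unscaled"), sep = ".")
    out[paste(pre, "total", sep = ".")] <- rec$total
    out[paste(pre, "electrostatic", sep = ".")] <- rec$electrostatic
    out[paste(pre, "exchange", sep = ".")] <- rec$exchange
    out[paste(pre, "induction", sep = ".")] <- rec$induction
    out[paste(pre, "dispersion", sep = ".")] <- rec$dispersion
  }
  out
}

fmt_energy <- function(x) ifelse(is.na(x), "", sprintf("%.8g", x))

# ---- filenames ---------------------------------------------------------------

#' Build the canonical record filename stem
#'
#' Eleven underscore-joined items: protein monomer name, protein site type,
#' ligand monomer name, ligand site type, index, r, theta_P, tau_P, theta_L,
#' tau_L, tau_PL. Names must be pre-sanitized (no underscores; see
#' [sanitize_name]). `r` is printed with one decimal and angles as integer
#' degrees unless other digit counts are configured.
#'
#' @param protein_name,ligand_name sanitized monomer names.
#' @param protein_type,ligand_type site categories.
#' @param index integer configuration index.
#' @param ic [internal_coords] supplying `r` and the five angles.
#' @param r_digits,angle_digits formatting precision.
#' @return filename stem (no extension).
#' @export
make_filename <- function(protein_name, protein_type, ligand_name, ligand_type,
                          index, ic, r_digits = 1, angle_digits = 0) {
  for (nm in c(protein_name, ligand_name)) {
    if (grepl("_", nm, fixed = TRUE))
      stop("name contains an underscore (sanitize first): ", nm)
    if (!grepl("^[A-Za-z0-9]+$", nm))
      stop("name is not alphanumeric (sanitize first): ", nm)
  }
  fa <- function(x) formatC(x, format = "f", digits = angle_digits)
  paste(protein_name, protein_type, ligand_name, ligand_type,
        as.integer(index),
        formatC(ic$r, format = "f", digits = r_digits),
        fa(ic$theta_P), fa(ic$tau_P), fa(ic$theta_L), fa(ic$tau_L),
        fa(ic$tau_PL), sep = "_")
}

#' Parse a record filename stem back into its parts
#'
#' @param stem filename stem produced by [make_filename] (any `.xyz`
#'   extension is stripped).
#' @return list with `protein_name`, `protein_type`, `ligand_name`,
#'   `ligand_type`, `index`, `r`, `theta_P`, `tau_P`, `theta_L`, `tau_L`,
#'   `tau_PL`.
#' @export
parse_filename <- function(stem) {
  stem <- sub("\\.xyz$", "", basename(stem))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) != 11) stop("expected 11 underscore-separated items, got ",
                                length(parts))
  list(protein_name = parts[1], protein_type = parts[2],
       ligand_name = parts[3], ligand_type = parts[4],
       index = as.integer(parts[5]), r = as.numeric(parts[6]),
       theta_P = as.numeric(parts[7]), tau_P = as.numeric(parts[8]),
       theta_L = as.numeric(parts[9]), tau_L = as.numeric(parts[10]),
       tau_PL = as.numeric(parts[11]))
}

# ---- record read/write ------------------------------------------------------

#' Write a dimer configuration as a Splinter .xyz record
#'
#' Line 1 is the total atom count; line 2 holds exactly 25 comma-separated
#' fields: title, total charge, monomer-1 charge, monomer-2 charge, the 20
#' energy slots in kcal/mol (empty when missing), and the number of atoms in
#' monomer 1. Protein atoms are written first, then ligand atoms, element and
#' Cartesian coordinates in Angstrom at 6 decimals.
#'
#' @param config `dimer_config`.
#' @param path output file.
#' @param energies named numeric over slot keys (see [energy_slots]), or a
#'   list of [energy_record]s; missing slots become the empty-field sentinel.
#' @param title field-1 string; defaults to the canonical filename stem of
#'   the configuration when derivable, else the site-dimer id.
#' @return `path`, invisibly.
#' @export
write_splinter_xyz <- function(config, path, energies = NULL, title = NULL) {
  if (is.null(title)) {
    title <- if (!is.na(config$site_dimer_id)) config$site_dimer_id else "dimer"
    title <- gsub(",", ";", title, fixed = TRUE)
  }
  if (grepl(",", title, fixed = TRUE)) stop("title must not contain commas")
  slots <- if (is.null(energies)) energy_slots(list())
           else if (is.list(energies) && !is.numeric(energies)) energy_slots(energies)
           else {
             s <- energy_slots(list())
             unknown <- setdiff(names(energies), names(s))
             if (length(unknown) > 0)
               stop("unmapped energy label(s): ", paste(unknown, collapse = ", "))
             s[names(energies)] <- energies
             s
           }
  np <- length(config$protein$elements)
  nl <- length(config$ligand$elements)
  qp <- config$protein$charge; ql <- config$ligand$charge
  line2 <- paste(c(title, qp + ql, qp, ql, fmt_energy(slots), np),
                 collapse = ",")
  el <- c(config$protein$elements, config$ligand$elements)
  xyz <- rbind(config$protein$coords, config$ligand$coords)
  lines <- c(as.character(np + nl), line2,
             sprintf("%-2s %13.6f %13.6f %13.6f", el, xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Splinter .xyz record
#'
#' @param path record file.
#' @return list of class `splinter_record`: `title`, `total_charge`,
#'   `charge_1`, `charge_2`, `energies` (named over the 20 slot keys, NA
#'   when the field was empty), `n_monomer1`, `elements`, `coords`, and
#'   `config` (a `dimer_config` reconstructed from the monomer partition).
#' @export
read_splinter_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  fields <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  # a trailing empty field is dropped by strsplit; restore to length 25
  if (length(fields) < 25) fields <- c(fields, rep("", 25 - length(fields)))
  if (length(fields) != 25)
    stop("metadata line has ", length(fields), " fields; expected 25")
  ef <- splinter_energy_fields()
  energies <- setNames(ifelse(fields[5:24] == "", NA_real_,
                              suppressWarnings(as.numeric(fields[5:24]))),
                       ef$key)
  if (any(fields[5:24] != "" & is.na(energies)))
    stop("unparseable energy field in ", path)
  np <- as.integer(fields[25])
  if (is.na(np) || np < 1 || np > n - 1)
    stop("monomer-1 atom count out of range in ", path)
  toks <- strsplit(trimws(lines[3:(2 + n)]), "[[:space:]]+")
  el <- vapply(toks, `[[`, character(1), 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  config <- list(
    protein = list(name = NA_character_, elements = el[seq_len(np)],
                   coords = xyz[seq_len(np), , drop = FALSE],
                   charge = as.integer(fields[3])),
    ligand = list(name = NA_character_, elements = el[(np + 1):n],
                  coords = xyz[(np + 1):n, , drop = FALSE],
                  charge = as.integer(fields[4])),
    site_dimer_id = NA_character_, index = NA_integer_,
    target_internal = NULL, perturbed = NA)
  class(config) <- "dimer_config"
  structure(list(title = fields[1], total_charge = as.integer(fields[2]),
                 charge_1 = as.integer(fields[3]),
                 charge_2 = as.integer(fields[4]),
                 energies = energies, n_monomer1 = np,
                 elements = el, coords = xyz, config = config),
            class = "splinter_record")
}

#' @export
print.splinter_record <- function(x, ...) {
  cat(sprintf("<splinter record %s: %d atoms (%d + %d), charge %+d>\n",
              x$title, length(x$elements), x$n_monomer1,
              length(x$elements) - x$n_monomer1, x$total_charge))
  invisible(x)
}

# ---- dataset tree ------------------------------------------------------------

#' Write a dataset directory tree
#'
#' One directory per molecular dimer, with `random`, `opt_raw` and
#' `opt_perturb` subdirectories holding the corresponding records; empty
#' stages are omitted entirely (nonstandard dimers, which arise only by
#' proton transfer during optimization, have no `random` directory). Each
#' dimer directory also gets an `energies.json` table keyed by record
#' filename with secondary keys naming the two basis sets and unscaled total
#' energies stored in Hartrees.
#'
#' @param dataset named list: dimer name -> list with any of `random`,
#'   `opt_raw`, `opt_perturb`, each a list of entries
#'   `list(config =, energies =, name =)` where `energies` is a slot vector
#'   or record list and `name` the filename stem.
#' @param root output root directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_splinter_tree <- function(dataset, root) {
  if (file.exists(root) && !dir.exists(root))
    stop("refusing to write over existing non-directory ", root)
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  for (dimer_name in names(dataset)) {
    stages <- dataset[[dimer_name]]
    ddir <- file.path(root, dimer_name)
    dir.create(ddir, showWarnings = FALSE)
    etab <- list()
    for (stage in intersect(c("random", "opt_raw", "opt_perturb"), names(stages))) {
      entries <- stages[[stage]]
      if (length(entries) == 0) next
      sdir <- file.path(ddir, stage)
      dir.create(sdir, showWarnings = FALSE)
      for (e in entries) {
        slots <- if (is.numeric(e$energies)) {
          s <- energy_slots(list()); s[names(e$energies)] <- e$energies; s
        } else energy_slots(e$energies)
        fn <- paste0(e$name, ".xyz")
        write_splinter_xyz(e$config, file.path(sdir, fn), energies = slots,
                           title = e$name)
        etab[[fn]] <- list()
        for (bi in seq_along(splinter_bases)) {
          tot <- slots[[paste(c("jun", "aug")[bi], "unscaled", "total", sep = ".")]]
          if (!is.na(tot))
            etab[[fn]][[splinter_bases[bi]]] <- tot / HARTREE_KCAL
        }
      }
    }
    if (length(etab) > 0)
      jsonlite::write_json(etab, file.path(ddir, "energies.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  invisible(root)
}
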