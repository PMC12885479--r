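#' Tubulin dimer templates
#'
#' A `dimer_template` holds the coordinates of one alpha/beta tubulin dimer
#' (atoms or coarse-grained beads), together with the lattice geometry it
#' implies: the axial rise per dimer along a protofilament (`dimer_repeat`,
#' in Angstrom), the axial rotation per dimer (`supertwist`, degrees; zero
#' for the compacted GDP lattice, nonzero for the expanded GTP lattice) and
#' the distance of the dimer from the microtubule axis (`radius`).
#'
#' Conventions used throughout the package: the microtubule axis is +z with
#' the minus end toward -z; within a dimer the alpha monomer occupies the
#' minus-proximal (lower-z) half. Residue numbers follow tubulin author
#' numbering.
#'
#' @name dimer_template
NULL

new_dimer_template <- function(atoms, dimer_repeat, supertwist, radius,
                               nucleotide_state) {
  atoms <- as_tibble(atoms)
  need <- c("monomer", "residue_number", "residue_name", "atom_name",
            "charge_class", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L) {
    abort(paste0("Template atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!setequal(unique(atoms$monomer), c("alpha", "beta"))) {
    abort("A dimer template must contain exactly the monomers 'alpha' and 'beta'.")
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("Template coordinates must be finite.")
  }
  if (any(atoms$residue_number < 1L)) abort("Residue numbers must be >= 1.")
  stopifnot(dimer_repeat > 0, radius > 0)
  nucleotide_state <- match.arg(nucleotide_state, c("GDP", "GTP", "other"))
  structure(
    list(atoms = atoms, dimer_repeat = dimer_repeat,
         supertwist = supertwist, radius = radius,
         nucleotide_state = nucleotide_state),
    class = "dimer_template"
  )
}

#' @export
print.dimer_template <- function(x, ...) {
  cat(sprintf(
    "<dimer_template> %s | %d atoms | repeat %.1f A | supertwist %.2f deg | radius %.0f A\n",
    x$nucleotide_state, nrow(x$atoms), x$dimer_repeat, x$supertwist, x$radius))
  invisible(x)
}

#' Load a tubulin dimer template from a PDB file
#'
#' Reads a single-model PDB coordinate file (for real use, a dimer extracted
#' from a microtubule reconstruction such as 7SJ7 for the GDP lattice or
#' 6DPU for the GTP lattice), labels the mapped chains as alpha/beta
#' monomers, classifies residue charges and recenters the dimer so its
#' centroid lies at distance `radius` from the +z microtubule axis (along
#' +x, with the centroid z placed at `dimer_repeat / 2`).
#'
#' @param coordinate_file Path to a PDB file.
#' @param chain_map Named character vector mapping chain ids to monomers,
#'   e.g. `c(A = "alpha", B = "beta")`.
#' @param dimer_repeat Axial rise per dimer, Angstrom.
#' @param supertwist Axial rotation per dimer, degrees (default 0).
#' @param nucleotide_state `"GDP"`, `"GTP"` or `"other"`.
#' @param radius Distance of the dimer centroid from the microtubule axis,
#'   Angstrom.
#' @return A `dimer_template`.
#' @export
load_dimer_template <- function(coordinate_file, chain_map,
                                dimer_repeat, supertwist = 0,
                                nucleotide_state = "GDP", radius = 115) {
  if (!file.exists(coordinate_file)) {
    abort(paste0("Coordinate file not found: ", coordinate_file))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(coordinate_file, verbose = FALSE),
    error = function(e) abort(paste0("Could not parse PDB file '",
                                     coordinate_file, "': ", conditionMessage(e)))
  )
  if (is.null(names(chain_map)) || !all(chain_map %in% c("alpha", "beta"))) {
    abort("`chain_map` must be a named vector with values 'alpha'/'beta'.")
  }
  at <- as_tibble(pdb$atom)
  missing_chain <- setdiff(names(chain_map), unique(at$chain))
  if (length(missing_chain) > 0L) {
    abort(paste0("Chain(s) not present in '", coordinate_file, "': ",
                 paste(missing_chain, collapse = ", ")))
  }
  atoms <- at |>
    dplyr::filter(.data$chain %in% names(chain_map)) |>
    dplyr::transmute(
      monomer = unname(chain_map[.data$chain]),
      residue_number = as.integer(.data$resno),
      residue_name = .data$resid,
      atom_name = .data$elety,
      charge_class = classify_charge(.data$resid),
      x = .data$x, y = .data$y, z = .data$z
    )
  centroid <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
  atoms$x <- atoms$x - centroid[1] + radius
  atoms$y <- atoms$y - centroid[2]
  atoms$z <- atoms$z - centroid[3] + dimer_repeat / 2
  log_msg("template", sprintf("loaded %d atoms from %s (%d chains)",
                              nrow(atoms), basename(coordinate_file),
                              length(chain_map)))
  new_dimer_template(atoms, dimer_repeat, supertwist, radius, nucleotide_state)
}

# Base bead geometry of the synthetic pseudo-dimer, in cylindrical
# coordinates (radius A, azimuth deg, local z A on the 82-A dimer repeat;
# alpha occupies z in [0, 41), beta [41, 82)). The grafted tail anchors at
# residue 437 (r = 116, z = 8, just outside the hard wall at r = 115);
# basic site beads are partially buried below the wall so tails approach
# their interaction wells from outside only, which keeps zero-attraction
# proximity contacts rare and bound-state volumes small. Axial placement
# relative to the anchor (site beads of the minus-side beta neighbour sit
# at local z - 90): site 1 just below the anchor at the longitudinal
# interface (-7..-5 A, reachable by the N-terminal glutamates), site 2
# distal on the beta body (-26..-23 A, reached by the C-terminal
# residues), site 3 mid-body cis (+13..+15 A), site 4 distal cis
# (+22..+25 A). Sites 1/3 are buried deeper (r ~109.5-109.8) than the
# GDP-specific sites 2/4 (r 111.6), so the accessibility contrast between
# the presets is carried by sites 2 and 4.
.fixture_beads <- function() {
  tribble_row <- function(monomer, resname, resno, r, theta, z) {
    tibble(monomer = monomer, residue_name = resname,
           residue_number = as.integer(resno), r = r, theta = theta, z = z)
  }
  dplyr::bind_rows(
    # alpha anchor for the grafted tail
    tribble_row("alpha", "VAL", 437, 116, 0.0, 8),
    # site 1 (trans, beta): R390 R391 K392
    tribble_row("beta", "ARG", 390, 109.8, -1.5, 85),
    tribble_row("beta", "ARG", 391, 109.8,  0.0, 84),
    tribble_row("beta", "LYS", 392, 109.8,  1.5, 83),
    # site 2 (trans, beta): K174 R380 R213 K379 R306
    tribble_row("beta", "LYS", 174, 111.6, -3.0, 66),
    tribble_row("beta", "ARG", 380, 111.6, -1.0, 67),
    tribble_row("beta", "ARG", 213, 111.6,  1.0, 65),
    tribble_row("beta", "LYS", 379, 111.6,  3.0, 66),
    tribble_row("beta", "ARG", 306, 111.6,  0.0, 64),
    # site 3 (cis, alpha): K311 R308 K338 R339
    tribble_row("alpha", "LYS", 311, 109.5, -2.0, 22),
    tribble_row("alpha", "ARG", 308, 109.5,  0.0, 21),
    tribble_row("alpha", "LYS", 338, 109.5,  2.0, 22),
    tribble_row("alpha", "ARG", 339, 109.5,  0.0, 23),
    # site 4 (cis, alpha): K112 R123 R156 K163 K430
    tribble_row("alpha", "LYS", 112, 111.6, -3.0, 31),
    tribble_row("alpha", "ARG", 123, 111.6, -1.0, 32),
    tribble_row("alpha", "ARG", 156, 111.6,  1.0, 30),
    tribble_row("alpha", "LYS", 163, 111.6,  3.0, 31),
    tribble_row("alpha", "LYS", 430, 111.6,  0.0, 33),
    # filler body beads below the surface (neutral + one acidic)
    tribble_row("alpha", "ALA",  50, 112,  4.0, 5),
    tribble_row("alpha", "GLY",  60, 112, -4.0, 15),
    tribble_row("beta",  "GLY", 100, 112,  4.0, 50),
    tribble_row("beta",  "GLU", 410, 112, -4.0, 72)
  )
}

#' Build a synthetic pseudo-dimer template
#'
#' Generates a deterministic coarse-grained stand-in for a real tubulin
#' dimer: one bead per residue of interest, comprising the alphaCTT anchor
#' (residue 437) and every basic residue of the four interaction-site
#' clusters, plus a few filler body beads. Bead positions get a small
#' seeded jitter; the residue inventory is seed-independent. Marked
#' synthetic throughout — it carries no experimental coordinates.
#'
#' @param seed Integer seed controlling the coordinate jitter.
#' @param nucleotide_state `"GDP"` (default) or `"GTP"`.
#' @param dimer_repeat Axial rise per dimer; defaults to 82 (GDP) or
#'   83.5 (GTP) Angstrom.
#' @param supertwist Axial rotation per dimer in degrees; defaults to 0
#'   (GDP) or 0.2 (GTP).
#' @param radius Microtubule radius at the dimer centroid, Angstrom.
#' @return A `dimer_template`.
#' @examples
#' tpl <- make_fixture_template(seed = 1)
#' nrow(tpl$atoms)
#' @export
make_fixture_template <- function(seed,
                                  nucleotide_state = "GDP",
                                  dimer_repeat = NULL,
                                  supertwist = NULL,
                                  radius = 115) {
  nucleotide_state <- match.arg(nucleotide_state, c("GDP", "GTP"))
  if (is.null(dimer_repeat)) {
    dimer_repeat <- if (nucleotide_state == "GDP") 82.0 else 83.5
  }
  if (is.null(supertwist)) {
    supertwist <- if (nucleotide_state == "GDP") 0 else 0.2
  }
  beads <- .fixture_beads()
  with_seed(seed, {
    jitter <- matrix(runif(3L * nrow(beads), -0.4, 0.4), ncol = 3L)
    theta <- beads$theta * pi / 180
    atoms <- tibble(
      monomer = beads$monomer,
      residue_number = beads$residue_number,
      residue_name = beads$residue_name,
      atom_name = "BB",
      charge_class = classify_charge(beads$residue_name),
      x = beads$r * cos(theta) + jitter[, 1],
      y = beads$r * sin(theta) + jitter[, 2],
      z = beads$z * dimer_repeat / 82 + jitter[, 3]
    )
    new_dimer_template(atoms, dimer_repeat, supertwist, radius, nucleotide_state)
  })
}
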