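#' Lattice geometry parameters
#'
#' Helical-symmetry parameters of the microtubule lattice. For the canonical
#' 13-protofilament, 3-start lattice each successive protofilament is rotated
#' by 360/13 degrees about the axis and raised by
#' `n_starts * (dimer_repeat / 2) / n_protofilaments` — the 3-start monomer
#' helix rises three monomer heights (1.5 dimers) per full turn, which is
#' what breaks the lateral alpha/beta register at the seam.
#'
#' @param n_protofilaments Number of protofilaments (default 13).
#' @param n_starts Helix start number in monomer rises (default 3).
#' @param n_rings Number of dimer rings to stack (default 3).
#' @param dimer_repeat Axial rise per dimer, Angstrom.
#' @return A `lattice_parameters` list including the derived
#'   `lateral_rotation` (degrees) and `lateral_rise` (Angstrom).
#' @examples
#' lattice_parameters(dimer_repeat = 82)$lateral_rise # 3 * 41 / 13
#' @export
lattice_parameters <- function(n_protofilaments = 13L, n_starts = 3L,
                               n_rings = 3L, dimer_repeat = 82.0) {
  n_protofilaments <- as.integer(n_protofilaments)
  n_starts <- as.integer(n_starts)
  n_rings <- as.integer(n_rings)
  if (n_protofilaments < 2L) abort("`n_protofilaments` must be >= 2.")
  if (n_starts < 1L) abort("`n_starts` must be >= 1.")
  if (n_rings < 1L) abort("`n_rings` must be >= 1.")
  if (dimer_repeat <= 0) abort("`dimer_repeat` must be positive.")
  structure(
    list(
      n_protofilaments = n_protofilaments,
      n_starts = n_starts,
      n_rings = n_rings,
      dimer_repeat = dimer_repeat,
      lateral_rotation = 360 / n_protofilaments,
      lateral_rise = n_starts * (dimer_repeat / 2) / n_protofilaments
    ),
    class = "lattice_parameters"
  )
}

subunit_label <- function(pf_index, ring_index) {
  sprintf("pf%02d_r%d", pf_index, ring_index)
}

rotation_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), nrow = 3L)
}

new_lattice_model <- function(template, params, placements, seam_pf,
                              axial_box = NULL, tails = NULL,
                              tail_def = NULL) {
  structure(
    list(template = template, params = params, placements = placements,
         seam_pf = seam_pf, axial_box = axial_box,
         minus_end_direction = c(0, 0, -1),
         tails = tails, tail_def = tail_def),
    class = "lattice_model"
  )
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf(
    "<lattice_model> %s | %d pf x %d ring(s) = %d dimers | seam at pf %d%s%s\n",
    x$template$nucleotide_state, x$params$n_protofilaments,
    max(x$placements$ring_index) + 1L, nrow(x$placements), x$seam_pf,
    if (!is.null(x$axial_box)) sprintf(" | periodic box %.1f A", x$axial_box) else "",
    if (!is.null(x$tails)) sprintf(" | %d grafted tails",
                                   length(unique(x$tails$tail_id))) else ""))
  invisible(x)
}

#' Build one ring of the microtubule lattice
#'
#' Replicates the dimer template around the microtubule axis by rigid-body
#' transforms: protofilament `p` is rotated by `p * lateral_rotation` about
#' +z and translated axially by `p * lateral_rise`. After all
#' `n_protofilaments` steps the accumulated rise equals
#' `n_starts * dimer_repeat / 2` (1.5 dimers for the 13-pf/3-start default),
#' so the lateral alpha/beta register breaks at the wrap from the last
#' protofilament back to the first; that wrap is recorded as the seam.
#'
#' @param template A `dimer_template`.
#' @param params A `lattice_parameters` object.
#' @return A `lattice_model` with one ring (`ring_index` 0).
#' @export
build_ring <- function(template, params) {
  stopifnot(inherits(template, "dimer_template"),
            inherits(params, "lattice_parameters"))
  params <- lattice_parameters(params$n_protofilaments, params$n_starts,
                               params$n_rings, template$dimer_repeat)
  pf <- seq_len(params$n_protofilaments) - 1L
  placements <- tibble(
    pf_index = pf,
    ring_index = 0L,
    subunit_id = subunit_label(pf, 0L),
    angle_deg = pf * params$lateral_rotation,
    dz = pf * params$lateral_rise,
    rotation = lapply(pf * params$lateral_rotation, rotation_z),
    translation = lapply(pf * params$lateral_rise, function(d) c(0, 0, d))
  )
  log_msg("lattice", sprintf("built ring: %d protofilaments, seam at pf %d",
                             params$n_protofilaments,
                             params$n_protofilaments - 1L))
  new_lattice_model(template, params, placements,
                    seam_pf = params$n_protofilaments - 1L)
}

#' Stack rings along the microtubule axis
#'
#' Copies a single ring `n_rings` times, translating copy `r` by
#' `r * dimer_repeat` along +z and rotating it by `r * supertwist` about the
#' axis (zero supertwist for the untwisted GDP lattice).
#'
#' @param ring A one-ring `lattice_model` from [build_ring()].
#' @param n_rings Number of rings (default taken from the model parameters).
#' @return A `lattice_model` with `n_protofilaments * n_rings` dimers.
#' @export
stack_rings <- function(ring, n_rings = ring$params$n_rings) {
  stopifnot(inherits(ring, "lattice_model"))
  if (!all(ring$placements$ring_index == 0L)) {
    abort("`stack_rings()` expects a single-ring model (ring_index 0 only).")
  }
  n_rings <- as.integer(n_rings)
  if (n_rings < 1L) abort("`n_rings` must be >= 1.")
  tw <- ring$template$supertwist
  rep_d <- ring$params$dimer_repeat
  placements <- purrr::map_dfr(seq_len(n_rings) - 1L, function(r) {
    p <- ring$placements
    p$ring_index <- r
    p$subunit_id <- subunit_label(p$pf_index, r)
    p$angle_deg <- p$angle_deg + r * tw
    p$dz <- p$dz + r * rep_d
    p$rotation <- lapply(p$angle_deg, rotation_z)
    p$translation <- lapply(p$dz, function(d) c(0, 0, d))
    p
  })
  params <- ring$params
  params$n_rings <- n_rings
  log_msg("lattice", sprintf("stacked %d rings: %d dimers", n_rings,
                             nrow(placements)))
  new_lattice_model(ring$template, params, placements, ring$seam_pf)
}

#' Make the lattice axially periodic
#'
#' Wraps a stacked model into an "infinite" microtubule by declaring an
#' axial periodic box of length `n_rings * dimer_repeat`; downstream
#' distance computations then apply the minimum-image convention along z.
#' Only an untwisted lattice can be made periodic — with a nonzero
#' supertwist the protofilaments would not match up with their periodic
#' image, so such models (e.g. the GTP lattice) must stay finite.
#'
#' @param model A stacked `lattice_model`.
#' @return The model with `axial_box` set.
#' @export
apply_periodic_box <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  if (abs(model$template$supertwist) > 1e-12) {
    abort(paste0(
      "Cannot make a supertwisted lattice periodic: with a nonzero ",
      "supertwist the protofilaments would not match up with their axial ",
      "image. Keep the model finite (e.g. solvent-padded) instead."))
  }
  model$axial_box <- model$params$n_rings * model$params$dimer_repeat
  log_msg("lattice", sprintf("periodic axial box: %.1f A", model$axial_box))
  model
}

#' Materialise the atom table of a lattice model
#'
#' Applies every placement's rigid transform to the template atoms and
#' returns one tidy table of body atoms (grafted tail beads are kept
#' separately in `model$tails`).
#'
#' @param model A `lattice_model`.
#' @return A tibble with `subunit_id`, `pf_index`, `ring_index`, `monomer`,
#'   `residue_number`, `residue_name`, `atom_name`, `charge_class`,
#'   `x`, `y`, `z`.
#' @export
lattice_atoms <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  tpl <- model$template$atoms
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  purrr::pmap_dfr(
    model$placements[, c("subunit_id", "pf_index", "ring_index",
                         "rotation", "translation")],
    function(subunit_id, pf_index, ring_index, rotation, translation) {
      moved <- xyz %*% t(rotation)
      tibble(
        subunit_id = subunit_id, pf_index = pf_index, ring_index = ring_index,
        monomer = tpl$monomer, residue_number = tpl$residue_number,
        residue_name = tpl$residue_name, atom_name = tpl$atom_name,
        charge_class = tpl$charge_class,
        x = moved[, 1] + translation[1],
        y = moved[, 2] + translation[2],
        z = moved[, 3] + translation[3]
      )
    })
}

#' Graft C-terminal tails onto every alpha subunit
#'
#' Adds a bead-per-residue tail chain to each alpha subunit, bonded at
#' 3.8 Angstrom spacing to the anchor residue (437) and initialised fully
#' extended radially outward from the microtubule surface, with a small
#' seeded angular jitter per tail. If an initial tail clashes with a body
#' atom (< 2 Angstrom) it is regrown with fresh jitter up to a bounded
#' number of retries. Beta tails are grafted only if a beta
#' `tail_definition` is supplied; they are excluded from downstream
#' analysis by default.
#'
#' @param model A `lattice_model`.
#' @param tail A [tail_definition()]; default the Y-alphaCTT 438-451.
#' @param seed Integer seed for the angular jitter.
#' @param bond_length Bead spacing along the extended chain, Angstrom.
#' @return The model with a `tails` tibble attached.
#' @export
graft_tails <- function(model, tail = tail_definition(), seed = 1L,
                        bond_length = 3.8) {
  stopifnot(inherits(model, "lattice_model"), inherits(tail, "tail_definition"))
  body <- lattice_atoms(model)
  anchors <- body |>
    dplyr::filter(.data$monomer == tail$parent_monomer,
                  .data$residue_number == tail$first_residue - 1L)
  if (nrow(anchors) != nrow(model$placements)) {
    abort(sprintf(
      "Every %s subunit needs an anchor residue %d position (found %d of %d).",
      tail$parent_monomer, tail$first_residue - 1L, nrow(anchors),
      nrow(model$placements)))
  }
  body_xyz <- as.matrix(body[, c("x", "y", "z")])
  n_beads <- nrow(tail$residues)
  with_seed(seed, {
    tails <- purrr::pmap_dfr(
      anchors[, c("subunit_id", "pf_index", "ring_index", "x", "y", "z")],
      function(subunit_id, pf_index, ring_index, x, y, z) {
        anchor <- c(x, y, z)
        radial <- c(x, y, 0) / sqrt(x^2 + y^2)
        tangent <- c(-radial[2], radial[1], 0)
        for (try in seq_len(25L)) {
          jit <- runif(2L, -1, 1) * 0.15
          dir <- radial + jit[1] * tangent + jit[2] * c(0, 0, 1)
          dir <- dir / sqrt(sum(dir^2))
          pos <- t(anchor + outer(dir, seq_len(n_beads) * bond_length))
          d2min <- min(vapply(seq_len(n_beads), function(i) {
            min(colSums((t(body_xyz) - pos[i, ])^2))
          }, numeric(1)))
          if (d2min >= 4) break
          if (try == 25L) {
            abort(sprintf("Could not place tail on %s without clashes.",
                          subunit_id))
          }
        }
        tibble(
          tail_id = subunit_id, pf_index = pf_index, ring_index = ring_index,
          bead = seq_len(n_beads),
          residue_number = tail$residues$residue_number,
          residue_name = tail$residues$residue_name,
          charge_class = tail$residues$charge_class,
          x = pos[, 1], y = pos[, 2], z = pos[, 3]
        )
      })
    log_msg("lattice", sprintf("grafted %d tails x %d beads",
                               nrow(model$placements), n_beads))
    model$tails <- tails
    model$tail_def <- tail
    model
  })
}
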