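#' Coarse-grained simulation parameters
#'
#' Parameters of the Metropolis Monte-Carlo tail sampler: one bead per tail
#' residue, harmonic bonds, a hard cylindrical wall at the lattice surface
#' and square-well attraction between acidic tail beads and the basic site
#' beads of each tail's partner subunits. Energies are in units of kT;
#' `time_per_sweep` is a bookkeeping label that gives trajectories a time
#' axis — it has no dynamical meaning. The default well depths are
#' calibration constants of this package, not experimentally measured
#' values.
#'
#' @param beads_per_tail Beads per tail (default 14, residues 438-451).
#' @param bond_length Equilibrium bond length, Angstrom.
#' @param bond_spring_k Bond spring constant, kT per Angstrom^2.
#' @param bead_radius Bead radius, Angstrom (bookkeeping).
#' @param wall_radius Hard-wall cylinder radius at the lattice surface,
#'   Angstrom (0 disables the wall).
#' @param well_depth Named numeric, attraction well depth per site id in kT
#'   (>= 0).
#' @param well_range Square-well interaction range, Angstrom.
#' @param temperature Temperature in kT units (default 1).
#' @param max_displacement Maximum single-bead trial displacement per axis,
#'   Angstrom.
#' @param n_sweeps Monte-Carlo sweeps (one trial move per bead per sweep).
#' @param frame_stride Sweeps between emitted frames.
#' @param pivot_every Apply one pivot move per tail every this many sweeps.
#' @param seed Integer RNG seed.
#' @param time_per_sweep Nominal ns per sweep for the time axis.
#' @param condition_tag `"GDP"`, `"GTP"` or `"other"`.
#' @return A `cg_parameters` list.
#' @export
cg_parameters <- function(beads_per_tail = 14L, bond_length = 3.8,
                          bond_spring_k = 20, bead_radius = 1.9,
                          wall_radius = 115,
                          well_depth = c(`1` = 2.0, `2` = 2.0,
                                         `3` = 1.5, `4` = 1.5),
                          well_range = 6, temperature = 1,
                          max_displacement = 0.6,
                          n_sweeps = 10000L, frame_stride = 10L,
                          pivot_every = 10L, seed = 1L,
                          time_per_sweep = 0.01,
                          condition_tag = "other") {
  stopifnot(bond_length > 0, bond_spring_k > 0, well_range > 0,
            temperature > 0, max_displacement > 0, wall_radius >= 0,
            frame_stride >= 1L, n_sweeps >= 1L)
  wd <- rep(0, 4)
  names(wd) <- as.character(1:4)
  wd[names(well_depth)] <- well_depth
  if (any(wd < 0)) abort("well_depth values must be >= 0.")
  structure(
    list(beads_per_tail = as.integer(beads_per_tail),
         bond_length = bond_length, bond_spring_k = bond_spring_k,
         bead_radius = bead_radius, wall_radius = wall_radius,
         well_depth = wd, well_range = well_range,
         temperature = temperature, max_displacement = max_displacement,
         n_sweeps = as.integer(n_sweeps),
         frame_stride = as.integer(frame_stride),
         pivot_every = as.integer(pivot_every),
         seed = as.integer(seed), time_per_sweep = time_per_sweep,
         condition_tag = condition_tag),
    class = "cg_parameters"
  )
}

#' GDP and GTP lattice presets
#'
#' Both presets share all geometric and mechanical parameters; they differ
#' only in the site well depths. The GDP preset keeps all four sites
#' attractive; the GTP preset sets the site-2 and site-4 well depths to
#' zero, encoding the suppression of those contacts in the expanded GTP
#' lattice. The well depths are package calibration constants (kT), not
#' published quantities.
#'
#' @param ... Overrides forwarded to [cg_parameters()].
#' @return A `cg_parameters` object.
#' @export
gdp_preset <- function(...) {
  cg_parameters(condition_tag = "GDP", ...)
}

#' @rdname gdp_preset
#' @export
gtp_preset <- function(...) {
  cg_parameters(well_depth = c(`1` = 2.0, `2` = 0, `3` = 1.5, `4` = 0),
                condition_tag = "GTP", ...)
}

#' Build a coarse-grained system from a grafted lattice model
#'
#' Maps the lattice into the simulator's world: per tail, the anchor
#' position (residue 437), the initial extended tail conformation, and the
#' basic-residue bead positions of the tail's cis (sites 3-4) and trans
#' (sites 1-2) partner subunits. In finite models, tails without a trans
#' partner are excluded (with a logged count); in periodic models all tails
#' are simulated.
#'
#' @param model A grafted, usually periodic, `lattice_model`.
#' @param partners Partner map from [resolve_partners()] (resolved from the
#'   model if absent).
#' @param params A `cg_parameters` object.
#' @param sites Site table.
#' @return A `cg_system` object.
#' @export
build_cg_system <- function(model, partners = NULL, params = cg_parameters(),
                            sites = default_site_definitions()) {
  stopifnot(inherits(model, "lattice_model"))
  if (is.null(model$tails)) abort("Graft tails first: see graft_tails().")
  if (is.null(partners)) partners <- resolve_partners(model, sites)
  drop_n <- sum(!partners$resolvable)
  if (drop_n > 0L) {
    warn(sprintf(
      "%d tail(s) have no trans partner in this finite model and are excluded from the simulation.",
      drop_n))
  }
  keep <- partners |> dplyr::filter(.data$resolvable)
  if (nrow(keep) == 0L) abort("No resolvable tails to simulate.")
  body <- lattice_atoms(model)
  tail_def <- model$tail_def
  n_beads <- nrow(tail_def$residues)

  tails <- model$tails |>
    dplyr::filter(.data$tail_id %in% keep$tail_id) |>
    dplyr::arrange(match(.data$tail_id, keep$tail_id), .data$bead)
  anchors <- body |>
    dplyr::filter(.data$monomer == tail_def$parent_monomer,
                  .data$residue_number == tail_def$first_residue - 1L) |>
    dplyr::filter(.data$subunit_id %in% keep$tail_id) |>
    dplyr::arrange(match(.data$subunit_id, keep$tail_id))

  site_hosts <- sites |>
    dplyr::transmute(site_id = .data$site_id, host = .data$host,
                     monomer = .data$monomer,
                     body_residue = .data$residue_number)
  site_beads <- keep |>
    tidyr::crossing(site_hosts) |>
    dplyr::mutate(partner_id = dplyr::if_else(
      .data$host == "adjacent_beta_trans", .data$trans_partner,
      .data$cis_partner)) |>
    dplyr::inner_join(
      body |>
        dplyr::filter(.data$charge_class == "basic") |>
        dplyr::select(partner_id = "subunit_id", monomer = "monomer",
                      body_residue = "residue_number",
                      "x", "y", "z"),
      by = c("partner_id", "monomer", "body_residue")) |>
    dplyr::arrange(match(.data$tail_id, keep$tail_id), .data$site_id,
                   .data$body_residue)
  counts <- site_beads |> dplyr::count(.data$tail_id)
  offsets <- c(0L, cumsum(counts$n[match(keep$tail_id, counts$tail_id)]))

  structure(
    list(
      tail_ids = keep$tail_id,
      n_beads = n_beads,
      atoms = tails |>
        dplyr::transmute(tail_id = .data$tail_id, bead = .data$bead,
                         residue_number = .data$residue_number,
                         residue_name = .data$residue_name,
                         charge_class = .data$charge_class,
                         atom_name = "BB"),
      coords0 = as.matrix(tails[, c("x", "y", "z")]),
      anchors = as.matrix(anchors[, c("x", "y", "z")]),
      site_xyz = as.matrix(site_beads[, c("x", "y", "z")]),
      site_site = as.integer(site_beads$site_id),
      site_tail = site_beads$tail_id,
      site_body_residue = site_beads$body_residue,
      site_offset = as.integer(offsets),
      acidic_bead = tail_def$residues$charge_class == "acidic",
      axial_box = model$axial_box,
      condition_tag = model$template$nucleotide_state
    ),
    class = "cg_system"
  )
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<cg_system> %d tails x %d beads | %d site beads%s\n",
              length(x$tail_ids), x$n_beads, nrow(x$site_xyz),
              if (!is.null(x$axial_box))
                sprintf(" | axial box %.1f A", x$axial_box) else ""))
  invisible(x)
}

#' Energy of a coarse-grained configuration
#'
#' Vectorised reference evaluation of the system energy: harmonic bond
#' energy, hard-wall indicator (0 when no bead penetrates the wall,
#' `Inf` otherwise) and the square-well site attraction (sum of `-eps_s`
#' over acidic-bead/site-bead pairs within the well range, with
#' minimum-image distances when periodic).
#'
#' @param system A `cg_system`.
#' @param params A `cg_parameters`.
#' @param coords Optional bead coordinate matrix (defaults to the system's
#'   current/initial coordinates).
#' @return A list with `bond`, `wall`, `site_attraction`, `total` (kT).
#' @export
cg_energy <- function(system, params, coords = system$coords0) {
  n_tails <- length(system$tail_ids)
  nb <- system$n_beads
  box <- system$axial_box
  bond <- 0
  site <- 0
  wall <- 0
  for (t in seq_len(n_tails)) {
    idx <- ((t - 1L) * nb + 1L):(t * nb)
    chain <- rbind(system$anchors[t, ], coords[idx, , drop = FALSE])
    d <- sqrt(rowSums(diff(chain)^2))
    bond <- bond + sum(0.5 * params$bond_spring_k *
                         (d - params$bond_length)^2)
    if (params$wall_radius > 0 &&
        any(coords[idx, 1]^2 + coords[idx, 2]^2 <
              params$wall_radius^2 - 1e-12)) {
      wall <- Inf
    }
    srange <- (system$site_offset[t] + 1L):system$site_offset[t + 1L]
    if (system$site_offset[t + 1L] > system$site_offset[t]) {
      ac <- coords[idx, , drop = FALSE][system$acidic_bead, , drop = FALSE]
      sb <- system$site_xyz[srange, , drop = FALSE]
      eps_s <- params$well_depth[as.character(system$site_site[srange])]
      for (i in seq_len(nrow(ac))) {
        dvec <- min_image_distance(sb, matrix(ac[i, ], ncol = 3L), box)
        site <- site - sum(eps_s[dvec <= params$well_range])
      }
    }
  }
  list(bond = bond, wall = wall, site_attraction = site,
       total = bond + wall + site)
}

#' Run the Metropolis Monte-Carlo tail simulation
#'
#' Per sweep, one trial single-bead displacement per bead, plus (every
#' `pivot_every` sweeps) one pivot move per tail about a random bead;
#' trial moves are accepted with probability `min(1, exp(-dE/kT))`, the
#' hard wall rejects outright, and anchors never move. The RNG is seeded
#' from `params$seed`, so trajectories are bit-reproducible. A warning is
#' raised when the displacement acceptance rate leaves (0.01, 0.99).
#'
#' @param system A `cg_system`.
#' @param params A `cg_parameters`.
#' @return A `tail_trajectory` (frames every `frame_stride` sweeps, times
#'   `sweep * time_per_sweep` ns) with an `acceptance` attribute list.
#' @export
simulate_tails <- function(system, params) {
  stopifnot(inherits(system, "cg_system"), inherits(params, "cg_parameters"))
  if (params$beads_per_tail != system$n_beads) {
    abort("params$beads_per_tail does not match the system's bead count.")
  }
  n_tails <- length(system$tail_ids)
  periodic <- !is.null(system$axial_box)
  res <- with_seed(params$seed, {
    cg_mc_run(
      coords = system$coords0, anchors = system$anchors,
      site_xyz = system$site_xyz, site_site = system$site_site,
      site_offset = system$site_offset,
      eps = unname(params$well_depth[as.character(1:4)]),
      acidic_bead = system$acidic_bead,
      n_tails = n_tails, n_beads = system$n_beads,
      bond_length = params$bond_length, bond_k = params$bond_spring_k,
      wall_radius = params$wall_radius, well_range = params$well_range,
      temperature = params$temperature, max_disp = params$max_displacement,
      n_sweeps = params$n_sweeps, frame_stride = params$frame_stride,
      pivot_every = params$pivot_every,
      axial_box = if (periodic) system$axial_box else 0,
      periodic = periodic)
  })
  if (res$accept_displacement < 0.01 || res$accept_displacement > 0.99) {
    warn(sprintf(
      "Displacement acceptance rate %.3f outside (0.01, 0.99); check max_displacement.",
      res$accept_displacement))
  }
  nf <- res$n_frames
  coords <- array(res$frames, dim = dim(res$frames))[, , seq_len(nf), drop = FALSE]
  times <- seq_len(nf) * params$frame_stride * params$time_per_sweep
  log_msg("simulate", sprintf(
    "%d sweeps, %d frames, acceptance disp %.2f pivot %.2f, E_total %.1f kT",
    params$n_sweeps, nf, res$accept_displacement,
    ifelse(is.na(res$accept_pivot), 0, res$accept_pivot), res$energy_total))
  traj <- new_tail_trajectory(
    atoms = system$atoms, coords = coords, times = times,
    axial_box = system$axial_box, condition_tag = params$condition_tag,
    acceptance = list(displacement = res$accept_displacement,
                      pivot = res$accept_pivot,
                      energy_total = res$energy_total,
                      energy_bond = res$energy_bond,
                      energy_site = res$energy_site,
                      final_coords = res$final_coords))
  traj
}
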