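# Shared fixtures, built in code. The default periodic GDP model is cached
# per test run because lattice construction is cheap but repeated often.

default_gdp_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tpl <- make_fixture_template(seed = 1)
      m <- build_ring(tpl, lattice_parameters(dimer_repeat = tpl$dimer_repeat))
      m <- apply_periodic_box(stack_rings(m, 3))
      cache <<- suppressMessages(graft_tails(m, seed = 1))
    }
    cache
  }
})

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Run simulate -> contacts -> series for a preset and seed at the default
# study scale (39 tails, 1e4 sweeps).
run_preset <- function(preset = c("gdp", "gtp"), seed = 1, n_sweeps = 10000,
                       well_scale = 1, model = default_gdp_model()) {
  preset <- match.arg(preset)
  maker <- if (preset == "gdp") gdp_preset else gtp_preset
  params <- maker(seed = seed, n_sweeps = n_sweeps)
  params$well_depth <- params$well_depth * well_scale
  partners <- resolve_partners(model)
  sys <- build_cg_system(model, partners, params)
  traj <- quiet(simulate_tails(sys, params))
  contacts <- quiet(detect_contacts(traj, model, partners))
  list(params = params, system = sys, traj = traj, contacts = contacts,
       series = inaccessibility_series(contacts, traj$times,
                                       n_tails = length(sys$tail_ids),
                                       condition_tag = params$condition_tag))
}

# Mean inaccessible fraction over the second half of a series (after the
# rise from the fully extended start).
equilibrated_mean <- function(series) {
  v <- series$table$inaccessible_fraction
  mean(v[(length(v) %/% 2):length(v)])
}

# Brute-force all-pairs salt-bridge oracle for a single frame tibble.
# Enumerates every (tail acidic atom, basic site atom of the tail's
# partner) pair, O(n^2), independent of the package's pair-table path.
brute_force_bridges <- function(frame, partners, sites, criteria, tail) {
  box <- attr(frame, "axial_box", exact = TRUE)
  elig <- tail$acidic_residues
  if (criteria$include_cterm_carboxylate) {
    elig <- union(elig, tail$c_terminal_residue)
  }
  recs <- list()
  k <- 0L
  for (i in which(frame$role == "tail")) {
    if (!(frame$residue_number[i] %in% elig)) next
    tid <- frame$subunit_id[i]
    prow <- partners[partners$tail_id == tid, ]
    for (j in which(frame$role == "body")) {
      srow <- sites[sites$residue_number == frame$residue_number[j] &
                      sites$monomer == frame$monomer[j], ]
      if (nrow(srow) == 0L) next
      expected_partner <- if (srow$host == "adjacent_beta_trans") {
        prow$trans_partner
      } else {
        prow$cis_partner
      }
      if (is.na(expected_partner) ||
          frame$subunit_id[j] != expected_partner) next
      dz <- frame$z[i] - frame$z[j]
      if (!is.null(box)) dz <- dz - box * round(dz / box)
      d <- sqrt((frame$x[i] - frame$x[j])^2 + (frame$y[i] - frame$y[j])^2 +
                  dz^2)
      if (d <= criteria$cutoff) {
        k <- k + 1L
        recs[[k]] <- data.frame(
          tail_id = tid, tail_residue = frame$residue_number[i],
          site_id = srow$site_id, body_residue = frame$residue_number[j],
          distance_A = d)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(tail_id = character(0), tail_residue = integer(0),
                      site_id = integer(0), body_residue = integer(0),
                      distance_A = numeric(0)))
  }
  out <- do.call(rbind, recs)
  out <- stats::aggregate(distance_A ~ tail_id + tail_residue + site_id +
                            body_residue, data = out, FUN = min)
  out[order(out$tail_id, out$tail_residue, out$site_id, out$body_residue), ]
}

# Random coarse-grained frame over a small model: tail beads scattered in a
# shell so some land within the cutoff of site beads.
random_frame <- function(model, seed, spread = 12) {
  traj0 <- with_frame_coords(model, seed, spread)
  frame_table(traj0, model, 1)
}

with_frame_coords <- function(model, seed, spread) {
  set.seed(seed)
  tails <- model$tails
  n <- nrow(tails)
  body <- lattice_atoms(model)
  anchor_like <- as.matrix(tails[, c("x", "y", "z")])
  coords <- anchor_like + matrix(runif(3 * n, -spread, spread), ncol = 3)
  # pull a random subset of beads near random site beads to create hits
  basics <- body[body$charge_class == "basic", ]
  n_pull <- max(3L, n %/% 10L)
  pick <- sample(n, n_pull)
  near <- basics[sample(nrow(basics), n_pull, replace = TRUE), ]
  coords[pick, ] <- as.matrix(near[, c("x", "y", "z")]) +
    matrix(runif(3 * n_pull, -4, 4), ncol = 3)
  arr <- array(t(coords), dim = c(3, n, 1))
  arr <- aperm(arr, c(2, 1, 3))
  mtctt:::new_tail_trajectory(
    atoms = tails |>
      dplyr::transmute(tail_id, bead, residue_number, residue_name,
                       charge_class, atom_name = "BB"),
    coords = arr, times = 0, axial_box = model$axial_box)
}

# A small finite (non-periodic) model for partner-edge cases.
small_finite_model <- function(n_pf = 5, n_rings = 2, seed = 3) {
  tpl <- make_fixture_template(seed = seed)
  m <- build_ring(tpl, lattice_parameters(n_protofilaments = n_pf,
                                          n_rings = n_rings,
                                          dimer_repeat = tpl$dimer_repeat))
  suppressMessages(graft_tails(stack_rings(m, n_rings), seed = seed))
}
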