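# A minimal free chain (no wall, no sites) for sampler physics tests.
free_chain_system <- function(n_beads = 5) {
  atoms <- tibble::tibble(
    tail_id = "t1", bead = seq_len(n_beads),
    residue_number = 437L + seq_len(n_beads),
    residue_name = "GLY", charge_class = "neutral", atom_name = "BB")
  coords0 <- cbind(0, 0, seq_len(n_beads) * 3.8)
  structure(
    list(tail_ids = "t1", n_beads = n_beads, atoms = atoms,
         coords0 = coords0, anchors = matrix(c(0, 0, 0), nrow = 1),
         site_xyz = matrix(numeric(0), 0, 3), site_site = integer(0),
         site_tail = character(0), site_body_residue = integer(0),
         site_offset = c(0L, 0L), acidic_bead = rep(FALSE, n_beads),
         axial_box = NULL, condition_tag = "other"),
    class = "cg_system")
}

test_that("presets share geometry and the GTP preset suppresses sites 2 and 4", {
  gdp <- gdp_preset()
  gtp <- gtp_preset()
  expect_equal(gtp$well_depth[["2"]], 0)
  expect_equal(gtp$well_depth[["4"]], 0)
  expect_gt(gdp$well_depth[["2"]], 0)
  expect_gt(gdp$well_depth[["4"]], 0)
  expect_equal(gdp$well_depth[["1"]], gtp$well_depth[["1"]])
  expect_equal(gdp$well_depth[["3"]], gtp$well_depth[["3"]])
  expect_true(all(gdp$well_depth >= 0))
  shared <- c("beads_per_tail", "bond_length", "bond_spring_k", "bead_radius",
              "wall_radius", "well_range", "temperature", "max_displacement",
              "n_sweeps", "frame_stride", "pivot_every", "time_per_sweep")
  expect_identical(gdp[shared], gtp[shared])
  expect_error(cg_parameters(well_depth = c(`1` = -1)), ">= 0")
})

test_that("the CG system maps 39 tails with the site bead multiplicities", {
  model <- default_gdp_model()
  partners <- resolve_partners(model)
  sys <- build_cg_system(model, partners, gdp_preset())
  expect_equal(length(sys$tail_ids), 39)
  expect_equal(nrow(sys$coords0), 39 * 14)
  counts <- table(sys$site_site[sys$site_tail == sys$tail_ids[1]])
  expect_equal(unname(counts[c("1", "2", "3", "4")]), c(3L, 5L, 4L, 5L),
               ignore_attr = TRUE)
  # finite single-ring model: no trans partners, nothing to simulate
  tpl <- make_fixture_template(seed = 2)
  one_ring <- suppressMessages(graft_tails(
    build_ring(tpl, lattice_parameters(dimer_repeat = 82)), seed = 1))
  expect_error(
    suppressWarnings(build_cg_system(one_ring,
                                     suppressMessages(resolve_partners(one_ring)),
                                     gdp_preset())),
    "No resolvable tails")
})

test_that("energy decomposes into bond, wall flag and square-well attraction", {
  sys <- free_chain_system()
  p <- cg_parameters(beads_per_tail = 5, wall_radius = 0)
  e <- cg_energy(sys, p)
  expect_equal(e$total, e$bond + e$wall + e$site_attraction, tolerance = 1e-9)
  expect_equal(e$total, 0, tolerance = 1e-12)  # ground state
  # single acidic bead in a single site-2 well: -eps2; zero under GTP
  sys2 <- sys
  sys2$acidic_bead[3] <- TRUE
  sys2$site_xyz <- matrix(c(2, 0, 3 * 3.8), nrow = 1)
  sys2$site_site <- 2L
  sys2$site_tail <- "t1"
  sys2$site_body_residue <- 174L
  sys2$site_offset <- c(0L, 1L)
  expect_equal(cg_energy(sys2, gdp_preset(wall_radius = 0))$site_attraction,
               -2.0)
  expect_equal(cg_energy(sys2, gtp_preset(wall_radius = 0))$site_attraction, 0)
  # stretched bond: 1/2 k (d - b0)^2
  sys3 <- sys
  sys3$coords0[5, 3] <- sys3$coords0[4, 3] + 4.8
  expect_equal(cg_energy(sys3, p)$bond, 0.5 * p$bond_spring_k * 1,
               tolerance = 1e-9)
  # wall penetration reported as an infinite flag
  sysw <- free_chain_system()
  pw <- cg_parameters(beads_per_tail = 5, wall_radius = 10)
  expect_equal(cg_energy(sysw, pw)$wall, Inf)
})

test_that("the C++ sampler's running energy matches the R reference", {
  model <- default_gdp_model()
  partners <- resolve_partners(model)
  p <- gdp_preset(n_sweeps = 500, frame_stride = 50, seed = 3)
  sys <- build_cg_system(model, partners, p)
  traj <- quiet(simulate_tails(sys, p))
  final <- traj$acceptance$final_coords
  ref <- cg_energy(sys, p, coords = final)
  expect_equal(traj$acceptance$energy_bond, ref$bond, tolerance = 1e-8)
  expect_equal(traj$acceptance$energy_site, ref$site_attraction,
               tolerance = 1e-8)
  expect_equal(ref$wall, 0)  # no accepted move may penetrate the wall
})

test_that("trajectories are bit-reproducible for a seed and differ across seeds", {
  model <- default_gdp_model()
  partners <- resolve_partners(model)
  p <- gdp_preset(n_sweeps = 300, frame_stride = 30, seed = 7)
  sys <- build_cg_system(model, partners, p)
  t1 <- quiet(simulate_tails(sys, p))
  t2 <- quiet(simulate_tails(sys, p))
  expect_identical(t1$coords, t2$coords)
  f1 <- withr::local_tempfile(fileext = ".xyz")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(t1, f1)
  write_trajectory_xyz(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  p2 <- gdp_preset(n_sweeps = 300, frame_stride = 30, seed = 8)
  t3 <- quiet(simulate_tails(sys, p2))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("bond lengths stay bounded and anchors never move", {
  model <- default_gdp_model()
  partners <- resolve_partners(model)
  p <- gdp_preset(n_sweeps = 2000, frame_stride = 100, seed = 5)
  sys <- build_cg_system(model, partners, p)
  traj <- quiet(simulate_tails(sys, p))
  nb <- sys$n_beads
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , i]
    for (t in seq_along(sys$tail_ids)) {
      idx <- ((t - 1) * nb + 1):(t * nb)
      chain <- rbind(sys$anchors[t, ], xyz[idx, ])
      d <- sqrt(rowSums(diff(chain)^2))
      expect_true(all(abs(d - p$bond_length) < 1.5))
    }
    # no bead inside the wall
    expect_true(all(xyz[, 1]^2 + xyz[, 2]^2 >= p$wall_radius^2 - 1e-9))
  }
})

test_that("a free bead-spring chain samples the freely jointed equilibrium", {
  # independent oracle: bond directions uniform on the sphere, bond lengths
  # from p(l) ~ l^2 exp(-k (l - b0)^2 / 2) by rejection sampling
  n_bonds <- 5L
  k <- 20; b0 <- 3.8
  set.seed(202)
  sample_bond_length <- function(n) {
    lmax <- b0 + 5 / sqrt(k)
    out <- numeric(0)
    while (length(out) < n) {
      prop <- stats::rnorm(2 * n, b0, 1 / sqrt(k))
      prop <- prop[prop > 0]
      keep <- stats::runif(length(prop)) < (prop / lmax)^2
      out <- c(out, prop[keep])
    }
    out[seq_len(n)]
  }
  n_samp <- 10000L
  ee_oracle <- vapply(seq_len(n_samp), function(i) {
    l <- sample_bond_length(n_bonds)
    u <- matrix(stats::rnorm(3 * n_bonds), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    sqrt(sum(colSums(u * l)^2))
  }, numeric(1))

  sys <- free_chain_system(n_beads = n_bonds)
  p <- cg_parameters(beads_per_tail = n_bonds, wall_radius = 0,
                     n_sweeps = 200000L, frame_stride = 20L, seed = 404)
  traj <- quiet(simulate_tails(sys, p))
  ee_mc <- vapply(seq_len(n_frames(traj)), function(i) {
    sqrt(sum(traj$coords[n_bonds, , i]^2))
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ee_mc, ee_oracle))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(ee_mc), mean(ee_oracle), tolerance = 0.05)
})

test_that("site occupancy responds monotonically to its well depth", {
  model <- default_gdp_model()
  partners <- resolve_partners(model)
  occ <- vapply(c(0, 0.5, 1, 2, 4), function(eps2) {
    p <- gdp_preset(n_sweeps = 3000, seed = 11)
    p$well_depth[["2"]] <- eps2
    sys <- build_cg_system(model, partners, p)
    traj <- quiet(simulate_tails(sys, p))
    ct <- quiet(detect_contacts(traj, model, partners))
    s2 <- ct[ct$site_id == 2, c("frame", "tail_id")]
    nrow(unique(s2)) / n_frames(traj)
  }, numeric(1))
  expect_gte(stats::cor(c(0, 0.5, 1, 2, 4), occ, method = "spearman"), 0.9)
})

test_that("a misconfigured step size triggers the acceptance-rate warning", {
  sys <- free_chain_system()
  p <- cg_parameters(beads_per_tail = 5, wall_radius = 0,
                     max_displacement = 60, n_sweeps = 200,
                     frame_stride = 20, seed = 1)
  expect_warning(suppressMessages(simulate_tails(sys, p)),
                 "acceptance rate")
})

test_that("rate matrices show the N-terminal/site-1 and GDP-specific site-2/4 pattern", {
  gdp <- run_preset("gdp", seed = 1)
  gtp <- run_preset("gtp", seed = 1)
  m_gdp <- as.matrix(interaction_rate(gdp$contacts, n_frames(gdp$traj),
                                      condition_tag = "GDP"))
  m_gtp <- as.matrix(interaction_rate(gtp$contacts, n_frames(gtp$traj),
                                      condition_tag = "GTP"))
  # the N-terminal glutamates interact overwhelmingly with site 1
  for (res in c("E441", "E443")) {
    expect_equal(which.max(m_gdp[res, ]), 1L, ignore_attr = TRUE)
    expect_equal(which.max(m_gtp[res, ]), 1L, ignore_attr = TRUE)
  }
  # site-2/site-4 interactions of the C-terminal residues are present in
  # the GDP preset and nearly abolished in the GTP preset
  cterm <- c("E445", "E446", "E447", "E449", "E450")
  expect_gt(mean(m_gdp[cterm, "site_2"]), 0.2)
  expect_gt(mean(m_gdp[cterm, "site_4"]), 0.2)
  expect_lt(mean(m_gtp[cterm, "site_2"]), 0.1)
  expect_lt(mean(m_gtp[cterm, "site_4"]), 0.1)
  # site-1 rates are similar between the nucleotide presets
  expect_equal(mean(m_gtp[, "site_1"]), mean(m_gdp[, "site_1"]),
               tolerance = 0.35)
})
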