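#' Minimum-image distance with an axial periodic box
#'
#' Euclidean distance after shifting the z-component difference into
#' `(-axial_box/2, axial_box/2]`; plain Euclidean distance when no box is
#' given. Vectorised over rows when `a`/`b` are matrices.
#'
#' @param a,b Numeric 3-vectors or n x 3 matrices, Angstrom.
#' @param axial_box Optional axial box length, Angstrom.
#' @return Distance(s), Angstrom.
#' @examples
#' min_image_distance(c(0, 0, 1), c(0, 0, 245), axial_box = 246) # 2
#' @export
min_image_distance <- function(a, b, axial_box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3L)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
  d <- a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE]
  if (!is.null(axial_box)) {
    d[, 3] <- d[, 3] - axial_box * round(d[, 3] / axial_box)
  }
  sqrt(rowSums(d^2))
}

#' Salt-bridge detection criteria
#'
#' A salt bridge is scored when the minimum distance between an acidic
#' group atom of a tail residue and a basic group atom of a site residue is
#' at or below the cutoff (ties at exactly the cutoff count). In atomistic
#' mode the groups are the carboxylate oxygens (Glu OE1/OE2, Asp OD1/OD2,
#' optionally the C-terminal OXT/O) and the basic nitrogens (Lys NZ, Arg
#' NE/NH1/NH2); in coarse-grained mode each residue is a single bead. The
#' cutoff defaults to 4 Angstrom (atomistic) or 6 Angstrom (bead-bead); it
#' is a package convention, configurable, not an experimentally printed
#' value.
#'
#' @param mode `"cg"` (single bead per residue) or `"atomistic"`.
#' @param cutoff Distance cutoff, Angstrom; default 6 (cg) or 4 (atomistic).
#' @param include_cterm_carboxylate Also count the C-terminal main-chain
#'   carboxylate of the last tail residue (Y451) as an acidic group.
#' @return A `salt_bridge_criteria` list.
#' @export
salt_bridge_criteria <- function(mode = c("cg", "atomistic"), cutoff = NULL,
                                 include_cterm_carboxylate = FALSE) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "cg") 6.0 else 4.0
  if (!is.numeric(cutoff) || cutoff <= 0) abort("criteria.cutoff must be > 0.")
  structure(
    list(mode = mode, cutoff = cutoff,
         include_cterm_carboxylate = isTRUE(include_cterm_carboxylate),
         acidic_group_atoms = list(GLU = c("OE1", "OE2"),
                                   ASP = c("OD1", "OD2"),
                                   cterm = c("OXT", "O")),
         basic_group_atoms = list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))),
    class = "salt_bridge_criteria"
  )
}

# Acidic tail residue numbers eligible under the criteria.
eligible_tail_residues <- function(tail, criteria) {
  res <- tail$acidic_residues
  if (criteria$include_cterm_carboxylate) {
    res <- sort(union(res, tail$c_terminal_residue))
  }
  res
}

# Is each (residue_name, atom_name) an acidic group atom under the criteria?
is_acidic_group <- function(residue_name, atom_name, residue_number,
                            criteria, cterm_residue = NULL) {
  if (criteria$mode == "cg") {
    ok <- residue_name %in% c("ASP", "GLU")
    if (criteria$include_cterm_carboxylate && !is.null(cterm_residue)) {
      ok <- ok | residue_number == cterm_residue
    }
    return(ok)
  }
  ok <- (residue_name == "GLU" & atom_name %in% criteria$acidic_group_atoms$GLU) |
    (residue_name == "ASP" & atom_name %in% criteria$acidic_group_atoms$ASP)
  if (criteria$include_cterm_carboxylate && !is.null(cterm_residue)) {
    ok <- ok | (residue_number == cterm_residue &
                  atom_name %in% criteria$acidic_group_atoms$cterm)
  }
  ok
}

is_basic_group <- function(residue_name, atom_name, criteria) {
  if (criteria$mode == "cg") return(residue_name %in% c("LYS", "ARG"))
  (residue_name == "LYS" & atom_name %in% criteria$basic_group_atoms$LYS) |
    (residue_name == "ARG" & atom_name %in% criteria$basic_group_atoms$ARG)
}

# Candidate (tail acidic atom, site basic atom) pair table. `tail_atoms` and
# `body_atoms` are tibbles carrying row ids into their coordinate sets.
contact_pair_table <- function(tail_atoms, body_atoms, partners, sites,
                               criteria, tail) {
  elig <- eligible_tail_residues(tail, criteria)
  ta <- tail_atoms |>
    dplyr::mutate(.tail_row = dplyr::row_number()) |>
    dplyr::filter(.data$residue_number %in% elig,
                  is_acidic_group(.data$residue_name, .data$atom_name,
                                  .data$residue_number, criteria,
                                  tail$c_terminal_residue)) |>
    dplyr::select("tail_id", "residue_number", ".tail_row")
  ba <- body_atoms |>
    dplyr::mutate(.body_row = dplyr::row_number()) |>
    dplyr::filter(is_basic_group(.data$residue_name, .data$atom_name, criteria))
  site_hosts <- sites |>
    dplyr::transmute(site_id = .data$site_id, host = .data$host,
                     monomer = .data$monomer,
                     body_residue = .data$residue_number)
  # map each (tail, site residue) onto the concrete partner subunit
  partner_sites <- partners |>
    tidyr::crossing(site_hosts) |>
    dplyr::mutate(partner_id = dplyr::if_else(
      .data$host == "adjacent_beta_trans", .data$trans_partner,
      .data$cis_partner)) |>
    dplyr::filter(!is.na(.data$partner_id)) |>
    dplyr::select("tail_id", "site_id", "host", "monomer", "body_residue",
                  "partner_id")
  ta |>
    dplyr::inner_join(partner_sites, by = "tail_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(
      ba |>
        dplyr::select(partner_id = "subunit_id", monomer = "monomer",
                      body_residue = "residue_number", ".body_row"),
      by = c("partner_id", "monomer", "body_residue"),
      relationship = "many-to-many") |>
    dplyr::select("tail_id", tail_residue = "residue_number", "site_id",
                  "body_residue", ".tail_row", ".body_row")
}

#' Detect salt bridges in a single trajectory frame
#'
#' Scores every (tail acidic residue, site basic residue) pair of each
#' resolvable tail against the distance criterion, using minimum-image
#' distances along the axial box when one is set. A residue pair yields at
#' most one record per frame, carrying the minimum group-atom distance.
#'
#' @param frame A frame tibble as produced by [frame_table()]: columns
#'   `role` (`"tail"`/`"body"`), `subunit_id`/`tail_id` in `subunit_id`,
#'   `monomer`, `residue_number`, `residue_name`, `atom_name`, `x`, `y`,
#'   `z`, with attributes `frame_index`, `time_ns`, `axial_box`.
#' @param partners Partner map from [resolve_partners()].
#' @param sites Site table from [default_site_definitions()].
#' @param criteria A [salt_bridge_criteria()].
#' @param tail The [tail_definition()] grafted on the model.
#' @return A tibble of contact records sorted by (`tail_id`,
#'   `tail_residue`, `site_id`, `body_residue`) with columns `frame`,
#'   `time_ns`, `tail_id`, `tail_residue`, `site_id`, `body_residue`,
#'   `distance_A`.
#' @export
detect_salt_bridges <- function(frame, partners, sites = default_site_definitions(),
                                criteria = salt_bridge_criteria(),
                                tail = tail_definition()) {
  stopifnot(is.data.frame(frame), "role" %in% names(frame))
  tail_atoms <- frame |>
    dplyr::filter(.data$role == "tail") |>
    dplyr::rename(tail_id = "subunit_id")
  body_atoms <- frame |> dplyr::filter(.data$role == "body")
  check_frame_atoms(tail_atoms, body_atoms, partners, sites, criteria, tail)
  pairs <- contact_pair_table(tail_atoms, body_atoms, partners, sites,
                              criteria, tail)
  axial_box <- attr(frame, "axial_box", exact = TRUE)
  d <- min_image_distance(
    as.matrix(tail_atoms[pairs$.tail_row, c("x", "y", "z")]),
    as.matrix(body_atoms[pairs$.body_row, c("x", "y", "z")]),
    axial_box)
  fi <- attr(frame, "frame_index", exact = TRUE) %||% 0L
  tns <- attr(frame, "time_ns", exact = TRUE) %||% NA_real_
  pairs |>
    dplyr::mutate(distance_A = d) |>
    dplyr::summarise(distance_A = min(.data$distance_A),
                     .by = c("tail_id", "tail_residue", "site_id",
                             "body_residue")) |>
    dplyr::filter(.data$distance_A <= criteria$cutoff) |>
    dplyr::arrange(.data$tail_id, .data$tail_residue, .data$site_id,
                   .data$body_residue) |>
    dplyr::mutate(frame = fi, time_ns = tns, .before = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Every eligible tail residue / site residue that appears in the frame must
# carry at least one selected group atom; a residue stripped of its group
# atoms (e.g. a Glu without OE1/OE2 in atomistic mode) is a structured error.
check_frame_atoms <- function(tail_atoms, body_atoms, partners, sites,
                              criteria, tail) {
  elig <- eligible_tail_residues(tail, criteria)
  present_tail <- unique(tail_atoms$residue_number)
  have_tail <- unique(tail_atoms$residue_number[
    is_acidic_group(tail_atoms$residue_name, tail_atoms$atom_name,
                    tail_atoms$residue_number, criteria,
                    tail$c_terminal_residue)])
  miss <- setdiff(intersect(elig, present_tail), have_tail)
  site_need <- sites$residue_number
  present_body <- unique(body_atoms$residue_number)
  have_body <- unique(body_atoms$residue_number[
    is_basic_group(body_atoms$residue_name, body_atoms$atom_name, criteria)])
  miss_body <- setdiff(intersect(site_need, present_body), have_body)
  if (length(miss) > 0L || length(miss_body) > 0L) {
    abort(paste0(
      "Frame is missing selected group atoms: ",
      if (length(miss) > 0L)
        paste0("tail residue(s) ", paste(miss, collapse = ", ")) else "",
      if (length(miss) > 0L && length(miss_body) > 0L) "; " else "",
      if (length(miss_body) > 0L)
        paste0("site residue(s) ", paste(miss_body, collapse = ", ")) else ""))
  }
  invisible(TRUE)
}

#' Detect salt bridges across a whole trajectory
#'
#' Vectorised multi-frame contact detection for coarse-grained tail
#' trajectories: the candidate pair table (tail acidic bead x partner site
#' bead) is built once from the lattice model and evaluated against every
#' frame in blocks, with minimum-image distances when the model is
#' periodic.
#'
#' @param traj A `tail_trajectory` (from [simulate_tails()] or
#'   [read_trajectory()]).
#' @param model The grafted `lattice_model` the trajectory belongs to.
#' @param partners Optional partner map; resolved from the model if absent.
#' @param sites Site table.
#' @param criteria A [salt_bridge_criteria()] (coarse-grained by default).
#' @param block_frames Number of frames evaluated per vectorised block.
#' @return A contacts tibble with columns `frame`, `time_ns`, `tail_id`,
#'   `tail_residue`, `site_id`, `body_residue`, `distance_A`.
#' @export
detect_contacts <- function(traj, model, partners = NULL,
                            sites = default_site_definitions(),
                            criteria = salt_bridge_criteria("cg"),
                            block_frames = 250L) {
  stopifnot(inherits(traj, "tail_trajectory"), inherits(model, "lattice_model"))
  if (is.null(partners)) partners <- resolve_partners(model, sites)
  tail <- model$tail_def %||% tail_definition()
  body_atoms <- lattice_atoms(model)
  pairs <- contact_pair_table(traj$atoms, body_atoms, partners, sites,
                              criteria, tail)
  if (criteria$mode != "cg") {
    abort("detect_contacts() evaluates coarse-grained trajectories; use detect_salt_bridges() per frame for atomistic data.")
  }
  box <- traj$axial_box
  n_frames <- dim(traj$coords)[3]
  bx <- body_atoms$x[pairs$.body_row]
  by <- body_atoms$y[pairs$.body_row]
  bz <- body_atoms$z[pairs$.body_row]
  res <- vector("list", ceiling(n_frames / block_frames))
  bi <- 0L
  for (start in seq(1L, n_frames, by = block_frames)) {
    idx <- start:min(start + block_frames - 1L, n_frames)
    dx <- traj$coords[pairs$.tail_row, 1, idx, drop = FALSE] - bx
    dy <- traj$coords[pairs$.tail_row, 2, idx, drop = FALSE] - by
    dz <- traj$coords[pairs$.tail_row, 3, idx, drop = FALSE] - bz
    if (!is.null(box)) dz <- dz - box * round(dz / box)
    d <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(d <= criteria$cutoff, arr.ind = TRUE)
    bi <- bi + 1L
    res[[bi]] <- tibble(
      frame = idx[hit[, 3]] - 1L,
      pair = hit[, 1],
      distance_A = d[hit]
    )
  }
  hits <- dplyr::bind_rows(res)
  out <- tibble(
    frame = hits$frame,
    time_ns = traj$times[hits$frame + 1L],
    tail_id = pairs$tail_id[hits$pair],
    tail_residue = pairs$tail_residue[hits$pair],
    site_id = pairs$site_id[hits$pair],
    body_residue = pairs$body_residue[hits$pair],
    distance_A = hits$distance_A
  ) |>
    dplyr::arrange(.data$frame, .data$tail_id, .data$tail_residue,
                   .data$site_id, .data$body_residue)
  log_msg("contacts", sprintf("%d contact records over %d frames",
                              nrow(out), n_frames))
  out
}
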