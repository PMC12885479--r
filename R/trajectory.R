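#' Tail trajectories
#'
#' A `tail_trajectory` holds the time-dependent coordinates of every grafted
#' tail bead: an `atoms` tibble (one row per bead, in fixed file order), a
#' `coords` array of dimension (n_beads, 3, n_frames) in Angstrom, frame
#' `times` in ns, and the `axial_box` (if periodic). Body atoms are not
#' stored — they are rigid and come from the lattice model.
#'
#' @name tail_trajectory
NULL

new_tail_trajectory <- function(atoms, coords, times, axial_box = NULL,
                                condition_tag = "other", acceptance = NULL) {
  stopifnot(nrow(atoms) == dim(coords)[1], dim(coords)[2] == 3L,
            length(times) == dim(coords)[3])
  structure(
    list(atoms = as_tibble(atoms), coords = coords, times = times,
         axial_box = axial_box, condition_tag = condition_tag,
         acceptance = acceptance),
    class = "tail_trajectory"
  )
}

#' @export
print.tail_trajectory <- function(x, ...) {
  cat(sprintf(
    "<tail_trajectory> %s | %d beads x %d frames | %.2f-%.2f ns%s\n",
    x$condition_tag, nrow(x$atoms), dim(x$coords)[3],
    min(x$times), max(x$times),
    if (!is.null(x$axial_box)) sprintf(" | axial box %.1f A", x$axial_box) else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `tail_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Materialise one trajectory frame as a tidy atom table
#'
#' Combines the static body atoms of the lattice with the tail bead
#' positions of frame `i` into the frame tibble consumed by
#' [detect_salt_bridges()].
#'
#' @param traj A `tail_trajectory`.
#' @param model The grafted `lattice_model`.
#' @param i Frame number (1-based).
#' @param body_atoms Optional precomputed [lattice_atoms()] table.
#' @return A tibble with a `role` column (`"body"`/`"tail"`) and attributes
#'   `frame_index` (0-based), `time_ns`, `axial_box`.
#' @export
frame_table <- function(traj, model, i, body_atoms = NULL) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  if (is.null(body_atoms)) body_atoms <- lattice_atoms(model)
  body <- body_atoms |>
    dplyr::mutate(role = "body") |>
    dplyr::select("role", "subunit_id", "monomer", "residue_number",
                  "residue_name", "atom_name", "charge_class",
                  "x", "y", "z")
  tl <- traj$atoms |>
    dplyr::mutate(role = "tail", subunit_id = .data$tail_id,
                  monomer = "alpha",
                  x = traj$coords[, 1, i], y = traj$coords[, 2, i],
                  z = traj$coords[, 3, i]) |>
    dplyr::select("role", "subunit_id", "monomer", "residue_number",
                  "residue_name", "atom_name", "charge_class",
                  "x", "y", "z")
  out <- dplyr::bind_rows(body, tl)
  attr(out, "frame_index") <- i - 1L
  attr(out, "time_ns") <- traj$times[i]
  attr(out, "axial_box") <- traj$axial_box
  out
}

tail_atom_table <- function(model) {
  stopifnot(!is.null(model$tails))
  model$tails |>
    dplyr::transmute(
      tail_id = .data$tail_id, bead = .data$bead,
      residue_number = .data$residue_number,
      residue_name = .data$residue_name,
      charge_class = .data$charge_class,
      atom_name = "BB")
}

#' Write a trajectory as XYZ
#'
#' Plain-text XYZ with one block per frame: atom count, a comment line
#' `frame <i> time_ns <t>`, then one line per bead
#' (`<one-letter><residue_number> x y z`, full double precision). Bead
#' order is the fixed order of `traj$atoms`.
#'
#' @param traj A `tail_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  one <- names(.aa3)[match(traj$atoms$residue_name, .aa3)]
  labels <- paste0(one, traj$atoms$residue_number)
  nf <- n_frames(traj)
  na <- nrow(traj$atoms)
  blocks <- vapply(seq_len(nf), function(i) {
    paste(c(
      as.character(na),
      sprintf("frame %d time_ns %.6f", i - 1L, traj$times[i]),
      sprintf("%s %.6f %.6f %.6f", labels,
              traj$coords[, 1, i], traj$coords[, 2, i], traj$coords[, 3, i])
    ), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; beads as ATOM records with the tail
#' residue numbering and a segment id encoding protofilament and ring.
#' Coordinates are limited to the PDB's 3-decimal precision.
#'
#' @inheritParams write_trajectory_xyz
#' @export
write_trajectory_pdb <- function(traj, path) {
  at <- traj$atoms
  seg <- sub("^pf(\\d+)_r(\\d+)$", "\\1\\2", at$tail_id)
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   1 mtctt tail trajectory, %d frames", nf), con)
  for (i in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d  BB  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00      %-4s",
      seq_len(nrow(at)) %% 100000L, at$residue_name,
      at$residue_number %% 10000L,
      traj$coords[, 1, i], traj$coords[, 2, i], traj$coords[, 3, i], seg), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory (multi-model PDB or XYZ)
#'
#' Lazily-ordered frame reader: frames are taken in file order and indexed
#' consecutively from 0. The bead inventory must match the grafted tails of
#' `model`; a frame with a deviating atom count raises an error naming the
#' frame. XYZ comment lines carry the time axis; for PDB (or XYZ without
#' time comments) supply `time_per_frame`.
#'
#' @param source Path to a `.xyz` or (multi-model) `.pdb` file.
#' @param model The grafted `lattice_model` the trajectory belongs to.
#' @param time_per_frame Optional uniform frame spacing, ns.
#' @return A `tail_trajectory`.
#' @export
read_trajectory <- function(source, model, time_per_frame = NULL) {
  stopifnot(file.exists(source), inherits(model, "lattice_model"))
  ext <- tolower(tools::file_ext(source))
  atoms <- tail_atom_table(model)
  if (ext == "xyz") {
    out <- read_trajectory_xyz_impl(source, atoms, time_per_frame)
  } else if (ext %in% c("pdb", "ent")) {
    out <- read_trajectory_pdb_impl(source, atoms, time_per_frame)
  } else {
    abort(paste0("Unsupported trajectory format: .", ext,
                 " (expected .xyz or .pdb)"))
  }
  out$axial_box <- model$axial_box
  out
}

#' @rdname read_trajectory
#' @export
iter_frames <- read_trajectory

read_trajectory_xyz_impl <- function(source, atoms, time_per_frame) {
  lines <- readLines(source)
  n_at <- nrow(atoms)
  pos <- 1L
  coords_list <- list()
  times <- numeric(0)
  fi <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    cnt <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(cnt)) abort(sprintf("Malformed XYZ atom count at line %d.", pos))
    if (cnt != n_at) {
      abort(sprintf("Frame %d has %d atoms; the model's tails have %d.",
                    fi, cnt, n_at))
    }
    if (pos + 1L + cnt > length(lines)) {
      abort(sprintf("Frame %d is truncated.", fi))
    }
    comment <- lines[pos + 1L]
    t <- NA_real_
    m <- regmatches(comment, regexec("time_ns\\s+([-0-9.eE+]+)", comment))[[1]]
    if (length(m) == 2L) t <- as.numeric(m[2])
    block <- lines[(pos + 2L):(pos + 1L + cnt)]
    fields <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    if (ncol(fields) < 4L) abort(sprintf("Frame %d has malformed atom lines.", fi))
    coords_list[[fi + 1L]] <- matrix(as.numeric(fields[, 2:4]), ncol = 3L)
    times <- c(times, t)
    fi <- fi + 1L
    pos <- pos + 2L + cnt
  }
  if (fi == 0L) abort("No frames found in XYZ file.")
  if (anyNA(times)) {
    dt <- time_per_frame %||% 1
    times <- (seq_len(fi) - 1L) * dt
  }
  coords <- array(unlist(coords_list), dim = c(n_at, 3L, fi))
  new_tail_trajectory(atoms, coords, times)
}

read_trajectory_pdb_impl <- function(source, atoms, time_per_frame) {
  pdb <- tryCatch(
    bio3d::read.pdb(source, multi = TRUE, verbose = FALSE),
    error = function(e) abort(paste0("Could not parse multi-model PDB '",
                                     source, "': ", conditionMessage(e)))
  )
  n_at <- nrow(atoms)
  if (nrow(pdb$atom) != n_at) {
    abort(sprintf("Trajectory has %d atoms per frame; the model's tails have %d.",
                  nrow(pdb$atom), n_at))
  }
  xyz <- pdb$xyz
  fi <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n_at, 3L, fi))
  for (i in seq_len(fi)) {
    coords[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  }
  dt <- time_per_frame %||% 1
  new_tail_trajectory(atoms, coords, (seq_len(fi) - 1L) * dt)
}
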