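#' Write a built lattice model as PDB
#'
#' Body atoms and grafted tail beads in one single-model PDB: alpha atoms
#' on chain A, beta on chain B, tail beads on chain T with the tail residue
#' numbering; segment ids encode protofilament and ring as `ppRR`.
#' Coordinates carry the PDB's 3-decimal precision.
#'
#' @param model A `lattice_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  body <- lattice_atoms(model)
  seg <- function(id) sub("^pf(\\d+)_r(\\d+)$", "\\1\\2", id)
  rows <- body |>
    dplyr::transmute(
      chain = dplyr::if_else(.data$monomer == "alpha", "A", "B"),
      resno = .data$residue_number, resid = .data$residue_name,
      elety = .data$atom_name, segid = seg(.data$subunit_id),
      x = .data$x, y = .data$y, z = .data$z)
  if (!is.null(model$tails)) {
    rows <- dplyr::bind_rows(
      rows,
      model$tails |>
        dplyr::transmute(chain = "T", resno = .data$residue_number,
                         resid = .data$residue_name, elety = "BB",
                         segid = seg(.data$tail_id),
                         x = .data$x, y = .data$y, z = .data$z))
  }
  xyz <- as.vector(t(as.matrix(rows[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = rows$resno,
                   resid = rows$resid, elety = rows$elety,
                   chain = rows$chain, segid = rows$segid, verbose = FALSE)
  invisible(path)
}

#' Read or write a contacts table as CSV
#'
#' The CSV carries one row per salt-bridge record with columns
#' `frame,time_ns,tail_id,tail_residue,site_id,body_residue,distance_A`;
#' doubles are written at full precision so a round-trip is exact.
#'
#' @param contacts A contacts tibble.
#' @param path File path.
#' @return `write_contacts()` returns `path` invisibly; `read_contacts()`
#'   returns the contacts tibble.
#' @export
write_contacts <- function(contacts, path) {
  cols <- c("frame", "time_ns", "tail_id", "tail_residue", "site_id",
            "body_residue", "distance_A")
  missing_cols <- setdiff(cols, names(contacts))
  if (length(missing_cols) > 0L) {
    abort(paste0("Contacts table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  write_csv_full(as.data.frame(contacts[, cols]), path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) abort(paste0("Contacts file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df) |>
    dplyr::mutate(frame = as.integer(.data$frame),
                  tail_residue = as.integer(.data$tail_residue),
                  site_id = as.integer(.data$site_id),
                  body_residue = as.integer(.data$body_residue))
}
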