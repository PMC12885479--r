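#' Resolve cis/trans interaction partners for every tail
#'
#' For the tail grafted on the alpha subunit at (protofilament `p`, ring
#' `r`), the *trans* partner is the beta monomer of the dimer one ring
#' toward the minus end on the same protofilament, i.e. (p, r - 1); the
#' *cis* partner is the tail's own alpha subunit. In an axially periodic
#' model the ring index wraps modulo `n_rings`, so every tail is
#' resolvable; in a finite model the minus-end ring (`ring_index` 0) has no
#' trans neighbour and those tails are flagged unresolvable for the trans
#' sites (1-2) and excluded from trans-site statistics.
#'
#' @param model A `lattice_model`.
#' @param sites Site table from [default_site_definitions()].
#' @return A tibble with one row per alpha tail: `tail_id`, `pf_index`,
#'   `ring_index`, `cis_partner`, `trans_partner` (`NA` when unresolvable),
#'   `resolvable`.
#' @export
resolve_partners <- function(model, sites = default_site_definitions()) {
  stopifnot(inherits(model, "lattice_model"))
  periodic <- !is.null(model$axial_box)
  n_rings <- model$params$n_rings
  out <- model$placements |>
    dplyr::transmute(
      tail_id = .data$subunit_id,
      pf_index = .data$pf_index,
      ring_index = .data$ring_index,
      cis_partner = .data$subunit_id,
      trans_ring = if (periodic) (.data$ring_index - 1L) %% n_rings
                   else .data$ring_index - 1L
    ) |>
    dplyr::mutate(
      resolvable = .data$trans_ring >= 0L,
      trans_partner = dplyr::if_else(
        .data$resolvable, subunit_label(.data$pf_index, pmax(.data$trans_ring, 0L)),
        NA_character_)
    ) |>
    dplyr::select(-"trans_ring")
  n_un <- sum(!out$resolvable)
  if (n_un > 0L) {
    log_msg("partners", sprintf(
      "%d tail(s) on the minus-end ring have no trans partner (finite model); excluded from trans-site statistics",
      n_un))
  }
  as_tibble(out)
}
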