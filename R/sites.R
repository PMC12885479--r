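#' The four alphaCTT interaction sites on the tubulin body
#'
#' Returns the four clusters of basic residues with which the acidic residues
#' of the alphaCTT form transient salt bridges. Sites 1 and 2 are *trans*
#' sites on the beta-tubulin of the adjacent dimer along the same
#' protofilament (toward the microtubule minus end); sites 3 and 4 are *cis*
#' sites on the tail's own alpha-tubulin.
#'
#' The table is tidy: one row per (site, basic residue). Note the site-3
#' cluster lists four residues; prose summaries sometimes count five basic
#' residues per site, but the explicit residue list is taken as
#' authoritative here.
#'
#' @return A tibble with columns `site_id` (1-4), `host`
#'   (`"adjacent_beta_trans"` or `"self_alpha_cis"`), `monomer` (`"beta"` or
#'   `"alpha"`), `residue_number`, `residue_name`, `display_tag`.
#' @examples
#' default_site_definitions() |> dplyr::count(site_id)
#' @export
default_site_definitions <- function() {
  site <- function(id, host, res) {
    trans <- identical(host, "adjacent_beta_trans")
    tibble(
      site_id = id,
      host = host,
      monomer = if (trans) "beta" else "alpha",
      residue_number = as.integer(sub("^[A-Z]", "", res)),
      residue_name = unname(.aa3[substr(res, 1, 1)]),
      display_tag = sprintf("site %d (%s)", id, if (trans) "trans" else "cis")
    )
  }
  dplyr::bind_rows(
    site(1L, "adjacent_beta_trans", c("R390", "R391", "K392")),
    site(2L, "adjacent_beta_trans", c("K174", "R380", "R213", "K379", "R306")),
    site(3L, "self_alpha_cis",      c("K311", "R308", "K338", "R339")),
    site(4L, "self_alpha_cis",      c("K112", "R123", "R156", "K163", "K430"))
  )
}
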