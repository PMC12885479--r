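#' Define a tubulin C-terminal tail
#'
#' The default is the tyrosinated alpha-tubulin C-terminal tail (Y-alphaCTT),
#' residues 438-451 with sequence `DSVEGEGEEEGEEY`: an aspartate, seven
#' glutamates and a C-terminal tyrosine. Acidic residues (D/E) are the
#' salt-bridge donors tracked by the contact analysis.
#'
#' @param sequence One-letter amino-acid sequence of the tail.
#' @param first_residue Residue number of the first tail residue in tubulin
#'   (author) numbering. Default 438.
#' @param parent_monomer Monomer carrying the tail; only `"alpha"` tails are
#'   analysed downstream, but a user-supplied beta-tail can be defined.
#' @return An object of class `tail_definition`: a list with the sequence,
#'   residue numbering, a per-residue tibble (`residues`) and the acidic
#'   residue numbers (`acidic_residues`).
#' @examples
#' td <- tail_definition()
#' sum(td$residues$residue_name == "GLU") # 7 glutamates
#' @export
tail_definition <- function(sequence = "DSVEGEGEEEGEEY",
                            first_residue = 438L,
                            parent_monomer = "alpha") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  parent_monomer <- match.arg(parent_monomer, c("alpha", "beta"))
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.aa3))
  if (length(bad) > 0L) {
    abort(paste0("Unknown amino-acid code(s) in tail sequence: ",
                 paste(unique(bad), collapse = ", ")))
  }
  first_residue <- as.integer(first_residue)
  numbers <- first_residue + seq_along(aa) - 1L
  residues <- tibble(
    residue_number = numbers,
    residue_one = aa,
    residue_name = unname(.aa3[aa]),
    charge_class = classify_charge(unname(.aa3[aa]))
  )
  out <- list(
    parent_monomer = parent_monomer,
    sequence = sequence,
    first_residue = first_residue,
    c_terminal_residue = numbers[length(numbers)],
    residues = residues,
    acidic_residues = residues$residue_number[residues$charge_class == "acidic"]
  )
  class(out) <- "tail_definition"
  out
}

#' @export
print.tail_definition <- function(x, ...) {
  cat(sprintf("<tail_definition> %s tail %d-%s-%d (%d residues, %d acidic)\n",
              x$parent_monomer, x$first_residue, x$sequence,
              x$c_terminal_residue, nchar(x$sequence),
              length(x$acidic_residues)))
  invisible(x)
}

.aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Classify residues by side-chain charge
#'
#' Aspartate and glutamate are `acidic`, lysine and arginine `basic`,
#' everything else `neutral`. Operates on 3-letter residue names.
#'
#' @param residue_name Character vector of 3-letter residue names.
#' @return Character vector of `"acidic"`, `"basic"` or `"neutral"`.
#' @export
classify_charge <- function(residue_name) {
  dplyr::case_when(
    residue_name %in% c("ASP", "GLU") ~ "acidic",
    residue_name %in% c("LYS", "ARG") ~ "basic",
    TRUE ~ "neutral"
  )
}
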