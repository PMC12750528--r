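# Element vocabulary and the annotation configuration shared by the
# structure-annotation stage.

# All IUPAC element symbols up to Og; used to validate parsed atoms.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

#' Default metal element set for site detection
#'
#' Alkali and alkaline-earth metals (H excluded), all d-block transition
#' metals, the lanthanides plus Th and U, the post-transition metals, and the
#' metalloids As, Sb and Te. The metalloids are included because structures of
#' expressed proteins have been reported to carry unusual cofactors such as
#' Sb, As, Hg, V and W; the set is a whitelist and can be narrowed or extended
#' through [annotation_config()].
#'
#' @return Character vector of element symbols.
#' @export
#' @examples
#' "Zn" %in% default_metal_set()
#' "Se" %in% default_metal_set()  # FALSE: Se is not treated as a metal
default_metal_set <- function() {
  c(
    # alkali / alkaline earth
    "Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
    # transition metals (3d, 4d, 5d)
    "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
    "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
    "La", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
    # lanthanides and the common crystallographic actinides
    "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
    "Tm", "Yb", "Lu", "Th", "U",
    # post-transition metals
    "Al", "Ga", "In", "Sn", "Tl", "Pb", "Bi",
    # metalloids reported as protein cofactors
    "As", "Sb", "Te"
  )
}

#' Configuration for metal-site detection
#'
#' Collects the tunable parameters of the coordination-sphere analysis:
#' which elements count as metals, which as donor atoms, the first-shell
#' distance cutoff, and how adventitious (surface/buffer) ions are handled.
#'
#' @param metals Character vector of metal element symbols to detect.
#' @param extra_metals,drop_metals Convenience whitelist/blacklist applied on
#'   top of `metals`.
#' @param donors Donor element symbols forming the first coordination sphere.
#' @param cutoff Donor distance cutoff in Angstrom. 3.0 is a typical
#'   first-shell threshold for protein metal sites.
#' @param include_waters Should water oxygens count as donors? Defaults to
#'   `FALSE` so that stoichiometry reflects the protein's own first
#'   coordination sphere.
#' @param exclude_adventitious Drop sites with no polymer donor within
#'   `cutoff` from downstream stoichiometry. Crystallisation-buffer ions
#'   sitting on the surface must not inflate metal counts.
#'
#' @return A list of class `annotation_config`.
#' @export
#' @examples
#' cfg <- annotation_config(cutoff = 2.8, drop_metals = "Na")
#' cfg$cutoff
annotation_config <- function(metals = default_metal_set(),
                              extra_metals = character(),
                              drop_metals = character(),
                              donors = c("N", "O", "S"),
                              cutoff = 3.0,
                              include_waters = FALSE,
                              exclude_adventitious = TRUE) {
  metals <- setdiff(union(metals, extra_metals), drop_metals)
  bad <- setdiff(c(metals, donors), .element_symbols)
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("`cutoff` must be a single positive distance in Angstrom")
  }
  structure(
    list(
      metals = metals, donors = donors, cutoff = cutoff,
      include_waters = isTRUE(include_waters),
      exclude_adventitious = isTRUE(exclude_adventitious)
    ),
    class = "annotation_config"
  )
}

# Half-up rounding to `digits` decimals (base round() is half-even).
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}
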