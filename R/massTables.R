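# Elemental compositions of the building blocks. NMP residue = nucleoside
# 3'(5')-monophosphate; chaining n residues releases (n-1) waters.
.NMP_FORMULA <- c(
  A = "C10H14N5O7P",
  C = "C9H14N3O8P",
  G = "C10H14N5O8P",
  U = "C9H13N2O9P"
)

.BASE_FORMULA <- c(
  A = "C5H5N5",    # adenine
  C = "C4H5N3O",   # cytosine
  G = "C5H5N5O",   # guanine
  U = "C4H4N2O2"   # uracil
)

# Mass (not a formula): a bare proton for charge-state arithmetic.
.PROTON_MASS <- 1.00727646

#' Monoisotopic mass tables for oligonucleotide MS
#'
#' All masses are computed from elemental composition using monoisotopic
#' atomic masses, so every constant is consistent with the formula oracle by
#' construction: NMP residues A 347.06308, C 323.05185, G 363.05799,
#' U 324.03587 Da; water 18.010565; HPO3 79.96633; proton 1.007276; neutral
#' nucleobases adenine 135.0545, cytosine 111.0433, guanine 151.0494, uracil
#' 112.0273 Da.
#'
#' @return list with elements \code{nmp}, \code{base} (named numeric
#'   vectors), \code{water}, \code{hpo3}, \code{proton}.
#' @examples
#' massTables()$nmp["U"]
#' @export
massTables <- function() {
  list(
    nmp = vapply(.NMP_FORMULA, formulaMass, numeric(1)),
    base = vapply(.BASE_FORMULA, formulaMass, numeric(1)),
    water = formulaMass("H2O"),
    hpo3 = formulaMass("HPO3"),
    proton = .PROTON_MASS
  )
}
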