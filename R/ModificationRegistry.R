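#' ModificationRegistry: the modification alphabet
#'
#' A registry of post-transcriptional modification codes, each carrying its
#' parent base, elemental-composition delta versus the parent nucleoside, the
#' monoisotopic mass delta, and two behavioural flags: whether the
#' modification blocks Watson-Crick pairing (acp3U does, via the N3 acp
#' group) and, for guanosine-derived codes, whether it blocks RNase T1
#' cleavage (2'-O-methylation does; base methylation such as m7G does not by
#' default).
#'
#' The registry shipped with the package
#' (\code{inst/extdata/modifications.tsv}) is an editable tab-separated
#' table, so new codes can be added without touching code. Validity requires
#' unique codes, parent bases in A/C/G/U, and that every stored mass delta
#' agrees with the monoisotopic mass of its formula delta to 1e-4 Da.
#'
#' @slot defs data.frame with columns \code{code}, \code{parent_base},
#'   \code{formula_delta}, \code{mono_mass_delta}, \code{blocks_watson_crick},
#'   \code{blocks_t1_cleavage}.
#' @seealso [defaultRegistry()], [modMassDelta()]
#' @export
setClass("ModificationRegistry", representation(defs = "data.frame"))

setValidity("ModificationRegistry", function(object) {
  d <- object@defs
  need <- c("code", "parent_base", "formula_delta", "mono_mass_delta",
            "blocks_watson_crick", "blocks_t1_cleavage")
  if (!all(need %in% names(d))) {
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  }
  if (anyDuplicated(d$code)) return("modification codes must be unique")
  if (!all(d$parent_base %in% c("A", "C", "G", "U"))) {
    return("parent_base must be one of A/C/G/U")
  }
  calc <- vapply(d$formula_delta, formulaMass, numeric(1))
  if (any(abs(calc - d$mono_mass_delta) > 1e-4)) {
    bad <- d$code[abs(calc - d$mono_mass_delta) > 1e-4]
    return(paste("mass delta disagrees with formula for:", paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Build a modification registry from a definition table
#'
#' @param defs data.frame of modification definitions (see
#'   \linkS4class{ModificationRegistry}).
#' @return a \linkS4class{ModificationRegistry}.
#' @export
ModificationRegistry <- function(defs) {
  defs$formula_delta[is.na(defs$formula_delta)] <- ""
  new("ModificationRegistry", defs = defs)
}

#' The registry shipped with the package
#'
#' Reads \code{extdata/modifications.tsv}, which ships acp3U (+C4H7NO2,
#' +101.0477 Da), dihydrouridine D (+H2, +2.0157 Da), acp3D (+C4H9NO2,
#' +103.0633 Da) and a few common companions.
#'
#' @return a \linkS4class{ModificationRegistry}.
#' @examples
#' reg <- defaultRegistry()
#' modMassDelta(reg, "acp3U")
#' @export
defaultRegistry <- function() {
  path <- system.file("extdata", "modifications.tsv", package = "tRNAcp",
                      mustWork = TRUE)
  defs <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  ModificationRegistry(defs)
}

.regRow <- function(registry, code) {
  i <- match(code, registry@defs$code)
  if (is.na(i)) stop("unknown modification code: '", code, "'")
  registry@defs[i, , drop = FALSE]
}

#' Registry lookups
#'
#' \code{modMassDelta} returns the monoisotopic mass delta (Da) of a code
#' versus its parent nucleoside; \code{modParentBase} its parent base;
#' \code{modBlocksT1} whether it suppresses RNase T1 cleavage;
#' \code{isRegistered} whether codes are present.
#'
#' @param registry a \linkS4class{ModificationRegistry}.
#' @param code modification code string (vectorized for `isRegistered`).
#' @return numeric, character, or logical as described.
#' @export
modMassDelta <- function(registry, code) .regRow(registry, code)$mono_mass_delta

#' @rdname modMassDelta
#' @export
modParentBase <- function(registry, code) .regRow(registry, code)$parent_base

#' @rdname modMassDelta
#' @export
modBlocksT1 <- function(registry, code) isTRUE(.regRow(registry, code)$blocks_t1_cleavage)

#' @rdname modMassDelta
#' @export
isRegistered <- function(registry, code) code %in% registry@defs$code

setMethod("show", "ModificationRegistry", function(object) {
  cat("ModificationRegistry with", nrow(object@defs), "codes:",
      paste(object@defs$code, collapse = ", "), "\n")
})
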