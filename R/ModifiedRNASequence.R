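#' ModifiedRNASequence: an RNA sequence with modification annotations
#'
#' Residues are stored as a base vector over A/C/G/U plus a parallel vector
#' of modification codes (NA where unmodified). An optional Sprinzl map
#' assigns each residue a canonical tRNA position label ("1".."76" plus
#' insertion labels such as "20a", "20b" and "e11".."e17"). Labels are
#' strings, never integers: insertion labels are not numeric. Internally all
#' coordinates are 0-based half-open; Sprinzl labels are the user-facing
#' coordinate system.
#'
#' @slot id character sequence identifier.
#' @slot bases character vector of residues, each one of A/C/G/U.
#' @slot mods character vector of modification codes, NA for unmodified,
#'   parallel to \code{bases}.
#' @slot sprinzl character vector of Sprinzl labels parallel to
#'   \code{bases}; length zero when unassigned.
#' @seealso [parseModifiedSequence()], [assignSprinzl()], [residueAt()]
#' @export
setClass("ModifiedRNASequence", representation(
  id = "character",
  bases = "character",
  mods = "character",
  sprinzl = "character"
))

setValidity("ModifiedRNASequence", function(object) {
  if (length(object@id) != 1L) return("id must be a single string")
  if (length(object@bases) != length(object@mods)) {
    return("bases and mods must be parallel")
  }
  if (!all(object@bases %in% c("A", "C", "G", "U"))) {
    return("bases must be in {A, C, G, U}")
  }
  n <- length(object@sprinzl)
  if (n > 0L) {
    if (n != length(object@bases)) return("sprinzl map length mismatch")
    lab <- object@sprinzl[!is.na(object@sprinzl)]
    if (anyDuplicated(lab)) return("sprinzl map must be injective")
    ord <- match(lab, sprinzlLabels())
    if (anyNA(ord)) return("sprinzl map contains unknown labels")
    if (is.unsorted(ord, strictly = TRUE)) {
      return("sprinzl map must be order-preserving")
    }
  }
  TRUE
})

#' Construct a ModifiedRNASequence
#'
#' @param id sequence identifier.
#' @param bases character vector over A/C/G/U.
#' @param mods modification codes parallel to bases (NA = unmodified).
#' @param registry \linkS4class{ModificationRegistry} used to check that
#'   each code's parent base matches the residue it sits on.
#' @param sprinzl optional Sprinzl label vector parallel to bases.
#' @return a \linkS4class{ModifiedRNASequence}.
#' @export
ModifiedRNASequence <- function(id, bases, mods = rep(NA_character_, length(bases)),
                                registry = defaultRegistry(),
                                sprinzl = character(0)) {
  for (i in which(!is.na(mods))) {
    if (!isRegistered(registry, mods[i])) {
      stop("unknown modification code: '", mods[i], "'")
    }
    pb <- modParentBase(registry, mods[i])
    if (pb != bases[i]) {
      stop("modification '", mods[i], "' has parent base ", pb,
           " but sits on ", bases[i], " at residue ", i)
    }
  }
  new("ModifiedRNASequence", id = id, bases = bases,
      mods = as.character(mods), sprinzl = sprinzl)
}

#' @rdname ModifiedRNASequence-class
#' @param x,object a \linkS4class{ModifiedRNASequence}.
#' @export
setMethod("length", "ModifiedRNASequence", function(x) length(x@bases))

#' Accessors for ModifiedRNASequence
#'
#' \code{seqID} returns the identifier; \code{residueBases} the base vector;
#' \code{residueMods} the modification-code vector; \code{sprinzlMap} the
#' Sprinzl labels (named by 0-based residue index), or NULL if unassigned.
#'
#' @param x a \linkS4class{ModifiedRNASequence}.
#' @return see description.
#' @export
seqID <- function(x) x@id

#' @rdname seqID
#' @export
residueBases <- function(x) x@bases

#' @rdname seqID
#' @export
residueMods <- function(x) x@mods

#' @rdname seqID
#' @export
sprinzlMap <- function(x) {
  if (!length(x@sprinzl)) return(NULL)
  setNames(x@sprinzl, as.character(seq_along(x@sprinzl) - 1L))
}

setMethod("show", "ModifiedRNASequence", function(object) {
  nmod <- sum(!is.na(object@mods))
  cat("ModifiedRNASequence '", object@id, "': ", length(object@bases),
      " nt, ", nmod, " modified residue(s)",
      if (length(object@sprinzl)) ", Sprinzl-numbered" else "", "\n", sep = "")
  txt <- serializeModifiedSequence(object)
  if (nchar(txt) > 70) txt <- paste0(substr(txt, 1, 67), "...")
  cat(" ", txt, "\n")
})

#' Parse a bracketed modified-sequence string
#'
#' The text format writes unmodified residues as single letters A/C/G/U and
#' modified residues as a bracketed registry code, e.g.
#' \code{"GGCU[acp3U]AG"}: the bracket token stands for one residue whose
#' base is the code's parent base. Serialization reproduces the input text
#' byte-for-byte.
#'
#' @param text sequence string with optional bracketed modification codes.
#' @param registry \linkS4class{ModificationRegistry}; unknown codes are an
#'   error naming the offending token.
#' @param id identifier for the resulting sequence.
#' @return a \linkS4class{ModifiedRNASequence}.
#' @examples
#' s <- parseModifiedSequence("AC[acp3U]G")
#' residueBases(s)
#' serializeModifiedSequence(s)
#' @export
parseModifiedSequence <- function(text, registry = defaultRegistry(), id = "seq") {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  bases <- character(0)
  mods <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated '[' in sequence text")
      code <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!isRegistered(registry, code)) {
        stop("unknown modification code: '", code, "'")
      }
      bases <- c(bases, modParentBase(registry, code))
      mods <- c(mods, code)
      i <- j + 1L
    } else {
      if (!ch %in% c("A", "C", "G", "U")) {
        stop("invalid residue character: '", ch, "'")
      }
      bases <- c(bases, ch)
      mods <- c(mods, NA_character_)
      i <- i + 1L
    }
  }
  ModifiedRNASequence(id = id, bases = bases, mods = mods, registry = registry)
}

#' Serialize a modified sequence back to bracketed text
#'
#' Inverse of [parseModifiedSequence()]: modified residues are written as
#' their bracketed code, everything else as plain letters.
#'
#' @param x a \linkS4class{ModifiedRNASequence}.
#' @return character scalar.
#' @export
serializeModifiedSequence <- function(x) {
  out <- ifelse(is.na(x@mods), x@bases, paste0("[", x@mods, "]"))
  paste(out, collapse = "")
}

#' Attach a modification to a residue
#'
#' @param x a \linkS4class{ModifiedRNASequence}.
#' @param where Sprinzl label (if the sequence is numbered) or 1-based
#'   residue index.
#' @param code registered modification code; its parent base must match the
#'   residue base at \code{where}.
#' @param registry \linkS4class{ModificationRegistry}.
#' @return the modified sequence.
#' @export
addModification <- function(x, where, code, registry = defaultRegistry()) {
  if (!isRegistered(registry, code)) {
    stop("unknown modification code: '", code, "'")
  }
  idx <- if (is.character(where)) {
    if (!length(x@sprinzl)) stop("sequence has no Sprinzl map")
    i <- match(where, x@sprinzl)
    if (is.na(i)) {
      .stopWithClass("tRNAcp_position_absent",
                     paste0("position '", where, "' not present in this tRNA"))
    }
    i
  } else as.integer(where)
  pb <- modParentBase(registry, code)
  if (x@bases[idx] != pb) {
    stop("modification '", code, "' requires parent base ", pb,
         " but residue at ", where, " is ", x@bases[idx])
  }
  x@mods[idx] <- code
  validObject(x)
  x
}
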