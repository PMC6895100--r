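#' Canonical Sprinzl label ordering
#'
#' The full ordered vector of supported Sprinzl tRNA position labels:
#' "1".."17", "17a", "18".."20", "20a", "20b", "21".."47", the variable-loop
#' extension labels "e11".."e17", then "48".."76". This ordering makes
#' "20" < "20a" < "20b" < "21" and "47" < "e11" < ... < "48" total.
#'
#' @return character vector of labels in canonical 5'-to-3' order.
#' @export
sprinzlLabels <- function() {
  c(as.character(1:17), "17a",
    as.character(18:20), "20a", "20b",
    as.character(21:47), paste0("e", 11:17),
    as.character(48:76))
}

#' Compare Sprinzl labels by canonical order
#'
#' @param labels character vector of Sprinzl labels.
#' @return integer ranks within the canonical ordering (NA for unknown).
#' @export
sprinzlOrder <- function(labels) match(labels, sprinzlLabels())

#' CloverleafAnnotation: arm boundaries of a tRNA cloverleaf
#'
#' Stores the five 5'-to-3' segments of a cloverleaf as 0-based half-open
#' index ranges that tile the sequence: the 5' acceptor segment (acceptor
#' stem 5' strand plus positions 8-9), the D-arm (stem-loop-stem), the
#' anticodon arm, the variable loop, and the 3' T segment (T-arm, acceptor
#' stem 3' strand and NCCA end). The annotation is an input — read from a
#' file or produced by the synthetic generator — not predicted; secondary
#' structure prediction is out of scope.
#'
#' @slot arms data.frame with columns \code{arm} (acceptor, dArm, acArm,
#'   vLoop, tArm in that order), \code{start}, \code{end}.
#' @slot seqLength integer total sequence length.
#' @export
setClass("CloverleafAnnotation", representation(
  arms = "data.frame",
  seqLength = "integer"
))

.ARM_NAMES <- c("acceptor", "dArm", "acArm", "vLoop", "tArm")

setValidity("CloverleafAnnotation", function(object) {
  a <- object@arms
  if (!identical(a$arm, .ARM_NAMES)) {
    return(paste("arms must be exactly:", paste(.ARM_NAMES, collapse = ", ")))
  }
  if (a$start[1] != 0L) return("first arm must start at 0")
  if (any(a$end <= a$start)) return("empty arm range")
  if (any(a$start[-1] != a$end[-nrow(a)])) {
    return("arm ranges must be contiguous and ordered 5' to 3'")
  }
  if (a$end[nrow(a)] != object@seqLength) {
    return("arms must tile the full sequence")
  }
  TRUE
})

#' Construct a CloverleafAnnotation
#'
#' @param acceptor,dArm,acArm,vLoop,tArm length-2 integer vectors
#'   \code{c(start, end)}, 0-based half-open.
#' @return a \linkS4class{CloverleafAnnotation}.
#' @examples
#' canonicalCloverleaf()
#' @export
CloverleafAnnotation <- function(acceptor, dArm, acArm, vLoop, tArm) {
  arms <- data.frame(
    arm = .ARM_NAMES,
    start = as.integer(c(acceptor[1], dArm[1], acArm[1], vLoop[1], tArm[1])),
    end = as.integer(c(acceptor[2], dArm[2], acArm[2], vLoop[2], tArm[2])),
    stringsAsFactors = FALSE
  )
  new("CloverleafAnnotation", arms = arms, seqLength = arms$end[5])
}

#' The canonical 76-nt cloverleaf annotation
#'
#' Segment lengths 9 / 17 / 17 / 5 / 28, corresponding to Sprinzl positions
#' 1-9, 10-26, 27-43, 44-48 and 49-76.
#'
#' @param dInsert number of extra D-loop residues (0-2, labeled 20a/20b).
#' @param vExtra number of extra variable-loop residues (0-7, labeled
#'   e11..e17).
#' @return a \linkS4class{CloverleafAnnotation}.
#' @export
canonicalCloverleaf <- function(dInsert = 0L, vExtra = 0L) {
  stopifnot(dInsert >= 0, dInsert <= 2, vExtra >= 0, vExtra <= 7)
  b <- cumsum(c(9L, 17L + dInsert, 17L, 5L + vExtra, 28L))
  CloverleafAnnotation(
    acceptor = c(0L, b[1]), dArm = c(b[1], b[2]), acArm = c(b[2], b[3]),
    vLoop = c(b[3], b[4]), tArm = c(b[4], b[5])
  )
}

setMethod("show", "CloverleafAnnotation", function(object) {
  cat("CloverleafAnnotation,", object@seqLength, "nt:\n")
  a <- object@arms
  cat(paste0("  ", a$arm, " [", a$start, ",", a$end, ")"), sep = "\n")
})

#' Assign Sprinzl position labels from a cloverleaf annotation
#'
#' Deterministic label assignment for class-I tRNAs. The canonical 76-nt
#' cloverleaf yields labels "1".."76" in order. D-arm residues beyond the
#' canonical 17 are treated as D-loop insertions after position 20 and
#' labeled "20a" then "20b" (at most two; acp3U is found at 20a in mammals
#' and at 20b in plants). Variable-loop residues beyond the canonical 5 are
#' labeled "e11".."e17" and inserted between "47" and "48", so "47" is
#' always the fourth variable-loop residue — the first after "46". Long
#' variable arms beyond e17 and D-loop insertions beyond 20b are
#' unsupported and raise an error.
#'
#' @param seq a \linkS4class{ModifiedRNASequence}.
#' @param cloverleaf a \linkS4class{CloverleafAnnotation} valid for the
#'   sequence length.
#' @return the sequence with its Sprinzl map filled in.
#' @examples
#' s <- parseModifiedSequence(paste(rep("A", 76), collapse = ""))
#' s <- assignSprinzl(s, canonicalCloverleaf())
#' sprinzlMap(s)[20:23]
#' @export
assignSprinzl <- function(seq, cloverleaf) {
  stopifnot(is(seq, "ModifiedRNASequence"), is(cloverleaf, "CloverleafAnnotation"))
  if (cloverleaf@seqLength != length(seq)) {
    stop("cloverleaf annotation is for length ", cloverleaf@seqLength,
         " but sequence has ", length(seq), " residues")
  }
  a <- cloverleaf@arms
  len <- setNames(a$end - a$start, a$arm)
  if (len[["acceptor"]] != 9L) stop("acceptor segment must have 9 residues (Sprinzl 1-9)")
  if (len[["acArm"]] != 17L) stop("anticodon arm must have 17 residues (Sprinzl 27-43)")
  if (len[["tArm"]] != 28L) stop("T segment must have 28 residues (Sprinzl 49-76)")
  dExtra <- len[["dArm"]] - 17L
  if (dExtra < 0L) stop("D-arm shorter than the canonical 17 residues is unsupported")
  if (dExtra > 2L) stop("more than two D-loop insertions (beyond 20b) are unsupported")
  vExtra <- len[["vLoop"]] - 5L
  if (vExtra < 0L) stop("variable loop shorter than 5 residues is unsupported")
  if (vExtra > 7L) stop("variable loop longer than supported (e11-e17); class II tRNAs are out of scope")
  dLabels <- c(as.character(10:20), c("20a", "20b")[seq_len(dExtra)],
               as.character(21:26))
  vLabels <- c("44", "45", "46", "47", paste0("e", 11:17)[seq_len(vExtra)], "48")
  labels <- c(as.character(1:9), dLabels, as.character(27:43), vLabels,
              as.character(49:76))
  stopifnot(length(labels) == length(seq))
  seq@sprinzl <- labels
  validObject(seq)
  seq
}

#' Residue at a Sprinzl position
#'
#' @param seq a Sprinzl-numbered \linkS4class{ModifiedRNASequence}.
#' @param label Sprinzl label, e.g. "47" or "20a".
#' @return list with elements \code{base} and \code{mod} (NA if
#'   unmodified). A label absent from this tRNA raises a condition of class
#'   \code{tRNAcp_position_absent}, distinguishable from ordinary errors.
#' @export
residueAt <- function(seq, label) {
  if (!length(seq@sprinzl)) stop("sequence has no Sprinzl map; run assignSprinzl() first")
  i <- match(label, seq@sprinzl)
  if (is.na(i)) {
    .stopWithClass("tRNAcp_position_absent",
                   paste0("position '", label, "' not present in this tRNA"))
  }
  list(base = seq@bases[i], mod = seq@mods[i])
}

#' Test whether a Sprinzl position exists in a tRNA
#'
#' @inheritParams residueAt
#' @return logical.
#' @export
hasSprinzlPosition <- function(seq, label) {
  length(seq@sprinzl) > 0 && label %in% seq@sprinzl
}
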