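# In-silico RNase digestion, exact mass / m/z computation, CID product-ion
# series, ppm peak matching, and the two LC/MS normalization rules used for
# modification stoichiometry.

.T1_ENZYMES <- c("RNaseT1", "RNaseA")

# Residue NMP masses (base + registered modification delta) for a sequence.
.residueMasses <- function(bases, mods, registry, tables = massTables()) {
  m <- tables$nmp[bases]
  for (i in which(!is.na(mods))) {
    m[i] <- m[i] + modMassDelta(registry, mods[i])
  }
  unname(m)
}

.terminiAdjust <- function(fivePrime, threePrime, tables) {
  adj <- 0
  adj <- adj + switch(fivePrime,
    OH = 0,
    phosphate = tables$hpo3,
    stop("unknown 5' terminus: ", fivePrime))
  adj <- adj + switch(threePrime,
    phosphate = 0,
    cyclicPhosphate = -tables$water,
    OH = -tables$hpo3,
    stop("unknown 3' terminus: ", threePrime))
  adj
}

#' Neutral monoisotopic mass of an oligonucleotide
#'
#' Mass of a linear RNA with the given terminal chemistry: the sum of
#' nucleoside-monophosphate residue masses (plus modification deltas) minus
#' (n-1) waters, adjusted -H2O for a 2',3'-cyclic phosphate, -HPO3 for a
#' 3'-OH, and +HPO3 for a 5'-phosphate. The default termini (5'-OH,
#' 3'-linear phosphate) are those of a hydrolyzed RNase T1 product.
#'
#' @param x a \linkS4class{ModifiedRNASequence} or a bracketed sequence
#'   string such as \code{"AC[acp3U]CAG"}.
#' @param fivePrime "OH" or "phosphate".
#' @param threePrime "phosphate", "cyclicPhosphate" or "OH".
#' @param registry \linkS4class{ModificationRegistry}.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' neutralMass("U")               # UMP, 324.0359 Da
#' neutralMass("AC[acp3U]CAG")    # the acp3U47 RNase T1 hexamer
#' @export
neutralMass <- function(x, fivePrime = "OH", threePrime = "phosphate",
                        registry = defaultRegistry()) {
  if (is.character(x)) x <- parseModifiedSequence(x, registry)
  tables <- massTables()
  rm <- .residueMasses(residueBases(x), residueMods(x), registry, tables)
  n <- length(rm)
  if (n == 0L) stop("empty fragment")
  sum(rm) - (n - 1L) * tables$water + .terminiAdjust(fivePrime, threePrime, tables)
}

#' m/z of an ion at a given charge state
#'
#' Negative mode (the acquisition polarity for oligonucleotide LC/MS):
#' (M - z * 1.007276) / z. Positive mode: (M + z * 1.007276) / z.
#'
#' @param mass neutral monoisotopic mass in Da (vectorized).
#' @param z charge state, an integer >= 1.
#' @param polarity "negative" or "positive".
#' @return m/z value(s).
#' @examples
#' mzForMass(neutralMass("AC[acp3U]CAG"), z = 3)  # 678.43
#' @export
mzForMass <- function(mass, z, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  z <- as.integer(z)
  if (any(z < 1L)) stop("charge z must be >= 1")
  s <- if (polarity == "negative") -1 else 1
  (mass + s * z * .PROTON_MASS) / z
}

#' Charge states whose m/z falls in a scan window
#'
#' @param mass neutral mass in Da.
#' @param window length-2 numeric, the m/z scan range (default 600-2000).
#' @param polarity see [mzForMass()].
#' @param maxZ largest charge considered.
#' @return integer vector of charge states.
#' @export
chargesInWindow <- function(mass, window = c(600, 2000),
                            polarity = "negative", maxZ = 8L) {
  z <- seq_len(maxZ)
  mz <- vapply(z, function(zi) mzForMass(mass, zi, polarity), numeric(1))
  z[mz >= window[1] & mz <= window[2]]
}

#' In-silico RNase digestion of a modified RNA
#'
#' RNase T1 cleaves 3' of guanosine; RNase A 3' of pyrimidines (C/U).
#' Cleavage leaves a 3'-phosphate (via the 2',3'-cyclic intermediate) on the
#' upstream product and a 5'-OH on the downstream one. G residues whose
#' modification blocks T1 cleavage (e.g. 2'-O-methylguanosine) are skipped.
#' Fragments tile the parent; the parent's own 3'-terminal fragment keeps a
#' 3'-OH. Missed cleavages add merged fragments spanning up to
#' \code{missedCleavages} skipped sites.
#'
#' @param seq a \linkS4class{ModifiedRNASequence}.
#' @param enzyme "RNaseT1" or "RNaseA".
#' @param missedCleavages non-negative integer.
#' @param threePrime 3' terminus of internal products: "phosphate"
#'   (default: hydrolyzed linear phosphate) or "cyclicPhosphate".
#' @param registry \linkS4class{ModificationRegistry}.
#' @return data.frame with columns \code{parent_id}, \code{start},
#'   \code{end} (0-based half-open), \code{n_missed}, \code{seq} (bracketed
#'   text), \code{five_prime}, \code{three_prime}, \code{mass}.
#' @examples
#' s <- parseModifiedSequence("AUGCAUG")
#' digestRNA(s)$seq
#' @export
digestRNA <- function(seq, enzyme = c("RNaseT1", "RNaseA"),
                      missedCleavages = 0L,
                      threePrime = c("phosphate", "cyclicPhosphate"),
                      registry = defaultRegistry()) {
  enzyme <- match.arg(enzyme)
  threePrime <- match.arg(threePrime)
  stopifnot(is(seq, "ModifiedRNASequence"))
  bases <- residueBases(seq)
  mods <- residueMods(seq)
  n <- length(bases)
  cleavable <- if (enzyme == "RNaseT1") {
    bases == "G" &
      !vapply(seq_len(n), function(i) {
        !is.na(mods[i]) && modBlocksT1(registry, mods[i])
      }, logical(1))
  } else {
    bases %in% c("C", "U")
  }
  sites <- which(cleavable)
  sites <- sites[sites < n]          # a cut after the last residue is vacuous
  bounds <- c(0L, sites, n)          # half-open fragment boundaries
  nFrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nFrag)) {
    for (k in 0:min(missedCleavages, nFrag - i)) {
      s <- bounds[i]
      e <- bounds[i + 1L + k]
      idx <- (s + 1L):e
      tp <- if (e == n) "OH" else threePrime
      frag <- new("ModifiedRNASequence", id = seqID(seq),
                  bases = bases[idx], mods = mods[idx],
                  sprinzl = character(0))
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = seqID(seq), start = s, end = e, n_missed = k,
        seq = serializeModifiedSequence(frag),
        five_prime = "OH", three_prime = tp,
        mass = neutralMass(frag, "OH", tp, registry),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

.CID_SERIES <- c("c", "y", "w", "a", "a-B")

#' CID product-ion series of an oligonucleotide fragment
#'
#' Computes the commonly observed RNA collision-induced dissociation series
#' (McLuckey nomenclature) for a 5'-OH fragment: c_i is the 5' piece ending
#' in a 3'-phosphate (sum of the first i residue masses minus (i-1) waters);
#' a_i = c_i - HPO3; a-B_i additionally loses the 3'-terminal nucleobase of
#' the a fragment (including any base modification, so the acp group leaves
#' with its uracil); y_j = M + H2O - c_(n-j) and w_j = y_j + HPO3 are the 3'
#' complements. The complementarity identities
#' c_i + y_(n-i) = a_i + w_(n-i) = M + H2O hold to numerical precision.
#' Series b/d/x/z are not emitted.
#'
#' @param x fragment as bracketed text or \linkS4class{ModifiedRNASequence}
#'   (length >= 2).
#' @param series subset of c("c","y","w","a","a-B").
#' @param charges integer charge states to enumerate.
#' @param polarity see [mzForMass()].
#' @param fivePrime,threePrime terminal chemistry of the parent fragment.
#' @param registry \linkS4class{ModificationRegistry}.
#' @return data.frame with columns \code{series}, \code{index},
#'   \code{neutral_mass}, \code{charge}, \code{mz}.
#' @examples
#' cidSeries("UG", charges = 1)
#' @export
cidSeries <- function(x, series = .CID_SERIES, charges = 1L,
                      polarity = "negative",
                      fivePrime = "OH", threePrime = "phosphate",
                      registry = defaultRegistry()) {
  if (is.character(x)) x <- parseModifiedSequence(x, registry)
  bad <- setdiff(series, .CID_SERIES)
  if (length(bad)) {
    stop("unsupported CID series: ", paste(bad, collapse = ", "),
         " (supported: ", paste(.CID_SERIES, collapse = ", "), ")")
  }
  tables <- massTables()
  bases <- residueBases(x)
  mods <- residueMods(x)
  n <- length(bases)
  if (n < 2L) stop("fragment must have at least 2 residues for CID")
  rm <- .residueMasses(bases, mods, registry, tables)
  M <- sum(rm) - (n - 1L) * tables$water +
    .terminiAdjust(fivePrime, threePrime, tables)
  idx <- seq_len(n - 1L)
  cMass <- cumsum(rm)[idx] - (idx - 1L) * tables$water
  # neutral base lost by a-B, including any base-modification delta
  baseMass <- tables$base[bases[idx]]
  for (i in idx) {
    if (!is.na(mods[i])) baseMass[i] <- baseMass[i] + modMassDelta(registry, mods[i])
  }
  seriesMass <- list(
    "c" = cMass,
    "a" = cMass - tables$hpo3,
    "a-B" = cMass - tables$hpo3 - unname(baseMass),
    "y" = M + tables$water - rev(cMass),
    "w" = M + tables$water - rev(cMass) + tables$hpo3
  )
  rows <- lapply(series, function(s) {
    data.frame(series = s, index = idx, neutral_mass = seriesMass[[s]],
               stringsAsFactors = FALSE)
  })
  ions <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(as.integer(charges), function(z) {
    d <- ions
    d$charge <- z
    d$mz <- mzForMass(d$neutral_mass, z, polarity)
    d
  }))
  rownames(out) <- NULL
  out
}

#' Match observed peaks to theoretical ions within a ppm tolerance
#'
#' Each observed peak is assigned to the nearest theoretical m/z within
#' \code{tolPpm}; each peak gets at most one assignment and unassigned peaks
#' are flagged. Ties are broken by the smaller ppm error, then the lower
#' theoretical m/z, so matching is deterministic.
#'
#' @param theoretical data.frame of theoretical ions with an \code{mz}
#'   column (must be non-empty); other columns are carried through.
#' @param observed data.frame of peaks with columns \code{mz},
#'   \code{intensity}.
#' @param tolPpm matching tolerance in parts per million (> 0).
#' @return the observed table plus columns \code{assigned} (logical),
#'   \code{theory_index} (row of \code{theoretical}), \code{theory_mz} and
#'   \code{ppm_error}.
#' @export
matchPeaks <- function(theoretical, observed, tolPpm = 20) {
  if (is.null(theoretical) || nrow(theoretical) == 0L) {
    stop("theoretical ion list is empty")
  }
  stopifnot(tolPpm > 0, "mz" %in% names(theoretical), "mz" %in% names(observed))
  tmz <- theoretical$mz
  out <- observed
  out$assigned <- FALSE
  out$theory_index <- NA_integer_
  out$theory_mz <- NA_real_
  out$ppm_error <- NA_real_
  ord <- order(tmz)  # break exact ppm ties toward lower theoretical m/z
  for (i in seq_len(nrow(observed))) {
    ppm <- abs(observed$mz[i] - tmz) / tmz * 1e6
    cand <- ord[ppm[ord] <= tolPpm]
    if (!length(cand)) next
    best <- cand[which.min(ppm[cand])]
    out$assigned[i] <- TRUE
    out$theory_index[i] <- best
    out$theory_mz[i] <- tmz[best]
    out$ppm_error[i] <- (observed$mz[i] - tmz[best]) / tmz[best] * 1e6
  }
  out
}

#' Fragment-level modification stoichiometry
#'
#' The fragment-analysis normalization rule: the intensity of the modified
#' fragment divided by the summed intensities of the modified and unmodified
#' forms of the same fragment.
#'
#' @param intensityModified,intensityUnmodified non-negative peak
#'   intensities or areas; both zero is an undefined-signal error.
#' @return fraction in [0, 1].
#' @examples
#' fragmentModFraction(3, 1)  # 0.75
#' @export
fragmentModFraction <- function(intensityModified, intensityUnmodified) {
  stopifnot(intensityModified >= 0, intensityUnmodified >= 0)
  tot <- intensityModified + intensityUnmodified
  if (tot == 0) {
    .stopWithClass("tRNAcp_undefined_signal",
                   "both modified and unmodified intensities are zero")
  }
  intensityModified / tot
}

#' Nucleoside-level modification quantification
#'
#' The nucleoside-analysis normalization rule: the peak area of the modified
#' nucleoside divided by the peak area of the unmodified reference
#' nucleoside.
#'
#' @param areaModified non-negative XIC area of the modified nucleoside.
#' @param areaReference positive XIC area of the unmodified reference.
#' @return non-negative ratio.
#' @export
nucleosideModLevel <- function(areaModified, areaReference) {
  stopifnot(areaModified >= 0)
  if (areaReference <= 0) stop("reference nucleoside area must be > 0")
  areaModified / areaReference
}

#' Integrate an extracted-ion chromatogram over a retention-time window
#'
#' Trapezoidal integration of intensity over retention time.
#'
#' @param xic data.frame with columns \code{rt} (sorted increasing) and
#'   \code{intensity}.
#' @param window length-2 numeric retention-time window; at least two
#'   samples must fall inside it.
#' @return non-negative area.
#' @export
integrateXIC <- function(xic, window = range(xic$rt)) {
  stopifnot(all(c("rt", "intensity") %in% names(xic)))
  if (is.unsorted(xic$rt)) stop("retention times must be sorted")
  keep <- xic$rt >= window[1] & xic$rt <= window[2]
  if (sum(keep) < 2L) stop("fewer than 2 samples in the integration window")
  pracma::trapz(xic$rt[keep], xic$intensity[keep])
}
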