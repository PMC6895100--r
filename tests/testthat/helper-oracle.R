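# Independent oracles for the test suite. These deliberately do not reuse
# the package's mass machinery: masses are recomputed from scratch by
# summing element counts with an independently stated atomic-mass table, so
# agreement is a genuine cross-check.

ORACLE_ATOM <- c(H = 1.0078250, C = 12, N = 14.0030740, O = 15.9949146,
                 P = 30.9737615)

# Element counts (H, C, N, O, P) of the building blocks.
ORACLE_NMP <- list(
  A = c(H = 14, C = 10, N = 5, O = 7, P = 1),
  C = c(H = 14, C = 9,  N = 3, O = 8, P = 1),
  G = c(H = 14, C = 10, N = 5, O = 8, P = 1),
  U = c(H = 13, C = 9,  N = 2, O = 9, P = 1)
)
ORACLE_BASE <- list(
  A = c(H = 5, C = 5, N = 5, O = 0, P = 0),
  C = c(H = 5, C = 4, N = 3, O = 1, P = 0),
  G = c(H = 5, C = 5, N = 5, O = 1, P = 0),
  U = c(H = 4, C = 4, N = 2, O = 2, P = 0)
)
ORACLE_MOD <- list(
  acp3U = c(H = 7, C = 4, N = 1, O = 2, P = 0),
  D     = c(H = 2, C = 0, N = 0, O = 0, P = 0),
  acp3D = c(H = 9, C = 4, N = 1, O = 2, P = 0),
  psi   = c(H = 0, C = 0, N = 0, O = 0, P = 0),
  m5U   = c(H = 2, C = 1, N = 0, O = 0, P = 0),
  m7G   = c(H = 2, C = 1, N = 0, O = 0, P = 0),
  Gm    = c(H = 2, C = 1, N = 0, O = 0, P = 0),
  m1A   = c(H = 2, C = 1, N = 0, O = 0, P = 0)
)
ORACLE_WATER <- c(H = 2, C = 0, N = 0, O = 1, P = 0)
ORACLE_HPO3 <- c(H = 1, C = 0, N = 0, O = 3, P = 1)

oracleCountsMass <- function(counts) {
  sum(ORACLE_ATOM[names(counts)] * counts)
}

# Neutral mass of a linear oligonucleotide by element-count bookkeeping.
oracleOligoMass <- function(bases, mods = rep(NA_character_, length(bases)),
                            fivePrime = "OH", threePrime = "phosphate") {
  counts <- c(H = 0, C = 0, N = 0, O = 0, P = 0)
  for (i in seq_along(bases)) {
    counts <- counts + ORACLE_NMP[[bases[i]]][names(counts)]
    if (!is.na(mods[i])) counts <- counts + ORACLE_MOD[[mods[i]]][names(counts)]
  }
  counts <- counts - (length(bases) - 1L) * ORACLE_WATER
  if (fivePrime == "phosphate") counts <- counts + ORACLE_HPO3
  if (threePrime == "OH") counts <- counts - ORACLE_HPO3
  if (threePrime == "cyclicPhosphate") counts <- counts - ORACLE_WATER
  oracleCountsMass(counts)
}

# Exhaustive per-group boolean evaluation of the strict screen.
bruteForceScreen <- function(presence, phenotype) {
  pos <- names(phenotype)[phenotype == "positive"]
  neg <- names(phenotype)[phenotype == "negative"]
  passers <- character(0)
  for (g in rownames(presence)) {
    ok <- TRUE
    for (t in pos) if (!presence[g, t]) ok <- FALSE
    for (t in neg) if (presence[g, t]) ok <- FALSE
    if (ok) passers <- c(passers, g)
  }
  passers
}

# Random bracketed-modification sequence text for round-trip properties.
randomModifiedText <- function(len = 30, registry = defaultRegistry()) {
  codes <- registry@defs$code
  parents <- registry@defs$parent_base
  parts <- character(len)
  for (i in seq_len(len)) {
    if (runif(1) < 0.15) {
      k <- sample(length(codes), 1)
      parts[i] <- paste0("[", codes[k], "]")
    } else {
      parts[i] <- sample(c("A", "C", "G", "U"), 1)
    }
  }
  paste(parts, collapse = "")
}

# Random ModifiedRNASequence for mass property tests.
randomModifiedSeq <- function(len = 25, registry = defaultRegistry(),
                              modProb = 0.15) {
  defs <- registry@defs
  bases <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
  mods <- rep(NA_character_, len)
  for (i in seq_len(len)) {
    if (runif(1) < modProb) {
      k <- sample(nrow(defs), 1)
      bases[i] <- defs$parent_base[k]
      mods[i] <- defs$code[k]
    }
  }
  ModifiedRNASequence("rnd", bases, mods, registry)
}
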