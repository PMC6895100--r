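# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes, plus machine-readable ground truth, so the whole
# pipeline is testable offline. Each generator draws from a single RNG
# stream keyed by its seed and restores the caller's RNG state.

#' Generate a phylogenetic-profile dataset with a planted causal family
#'
#' Emulates the comparative-genomics screening setting: a set of taxa with
#' a measured modification phenotype (default 3 positive, 5 negative,
#' mirroring one modification-positive bacterium plus two protists screened
#' against five modification-negative bacteria), one planted ortholog group
#' exactly co-distributed with the phenotype, and decoy groups with
#' independent Bernoulli(1/2) presence profiles (resampled if empty). The
#' planted gene in the reference taxon is annotated "unknown" function with
#' a distinguishing domain tag; decoys get random annotations.
#'
#' @param nDecoys number of decoy groups (default 1000, genome-screen
#'   scale).
#' @param nPositive,nNegative taxa counts by phenotype.
#' @param nUnknown taxa with unmeasured phenotype (ignored by the screen).
#' @param plantedTag domain tag carried by the planted gene.
#' @param decoyUnknownFrac fraction of decoy genes annotated "unknown".
#' @param seed RNG seed.
#' @return list with elements \code{dataset} (a
#'   \linkS4class{ProfileDataset}), \code{truth} (list with
#'   \code{plantedGroup}, \code{plantedGene}, \code{referenceTaxon}).
#' @export
genProfileDataset <- function(nDecoys = 1000L, nPositive = 3L, nNegative = 5L,
                              nUnknown = 0L, plantedTag = "DTW",
                              decoyUnknownFrac = 0.2, seed = 1L) {
  stopifnot(nPositive >= 1L, nNegative >= 1L, nDecoys >= 0L)
  .withSeed(seed, {
    taxa <- c(paste0("POS", seq_len(nPositive)), paste0("NEG", seq_len(nNegative)),
              if (nUnknown > 0L) paste0("UNK", seq_len(nUnknown)))
    phenotype <- setNames(rep(c("positive", "negative", "unknown"),
                              c(nPositive, nNegative, nUnknown)), taxa)
    nTaxa <- length(taxa)
    planted <- phenotype == "positive"
    decoys <- matrix(FALSE, nrow = nDecoys, ncol = nTaxa)
    if (nDecoys > 0L) {
      for (i in seq_len(nDecoys)) {
        repeat {
          row <- runif(nTaxa) < 0.5
          if (any(row)) break
        }
        decoys[i, ] <- row
      }
    }
    presence <- rbind(planted, decoys)
    rownames(presence) <- c("OG_planted",
                            if (nDecoys > 0L) sprintf("OG_decoy%04d", seq_len(nDecoys)))
    colnames(presence) <- taxa
    refTaxon <- taxa[1]
    members <- lapply(rownames(presence), function(g) {
      present <- colnames(presence)[presence[g, ]]
      setNames(lapply(present, function(t) paste0(t, "_", g)), present)
    })
    names(members) <- rownames(presence)
    genes <- unlist(lapply(members, unlist), use.names = FALSE)
    plantedGene <- paste0(refTaxon, "_OG_planted")
    tagsPool <- c("PUA", "THUMP", "SPOUT", "TRAM", "")
    ann <- data.frame(
      gene = genes,
      function_class = ifelse(genes == plantedGene, "unknown",
                              ifelse(runif(length(genes)) < decoyUnknownFrac,
                                     "unknown", "known")),
      domains = ifelse(genes == plantedGene, plantedTag,
                       sample(tagsPool, length(genes), replace = TRUE)),
      stringsAsFactors = FALSE
    )
    dataset <- ProfileDataset(presence, phenotype, annotations = ann,
                              members = members)
    list(dataset = dataset,
         truth = list(plantedGroup = "OG_planted", plantedGene = plantedGene,
                      referenceTaxon = refTaxon))
  })
}

# One random cloverleaf-valid tRNA with requested D-loop insertions.
.randomTRNA <- function(id, dInsert = 0L, registry) {
  cl <- canonicalCloverleaf(dInsert = dInsert)
  n <- cl@seqLength
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  s <- ModifiedRNASequence(id = id, bases = bases, registry = registry)
  assignSprinzl(s, cl)
}

.setBaseAt <- function(seq, label, base) {
  i <- match(label, seq@sprinzl)
  seq@bases[i] <- base
  seq
}

#' Generate a set of synthetic tRNAs with planted modifications
#'
#' Produces structurally valid (cloverleaf-annotated, Sprinzl-numbered)
#' random tRNA sequences and plants modifications at requested Sprinzl
#' labels with a per-site probability; residues at planted labels are set
#' to the code's parent base. Sequences needing a "20a"/"20b" label get the
#' corresponding D-loop insertion. A ground-truth table records every
#' planting decision. These sequences are random-composition stand-ins:
#' structurally valid but not biologically real tRNA genes.
#'
#' @param n number of sequences.
#' @param plant data.frame with columns \code{label}, \code{code},
#'   \code{prob}: each sequence receives \code{code} at \code{label} with
#'   probability \code{prob}. Default plants acp3U at position 47 always.
#' @param registry \linkS4class{ModificationRegistry}.
#' @param seed RNG seed.
#' @return list with elements \code{seqs} (list of
#'   \linkS4class{ModifiedRNASequence}), \code{truth} (data.frame seq_id,
#'   label, code, planted).
#' @export
genTRNASet <- function(n = 20L,
                       plant = data.frame(label = "47", code = "acp3U",
                                          prob = 1, stringsAsFactors = FALSE),
                       registry = defaultRegistry(), seed = 1L) {
  needInsert <- if (any(plant$label == "20b")) 2L else if (any(plant$label == "20a")) 1L else 0L
  .withSeed(seed, {
    seqs <- vector("list", n)
    rows <- list()
    for (i in seq_len(n)) {
      id <- sprintf("tRNA_syn%03d", i)
      s <- .randomTRNA(id, dInsert = needInsert, registry)
      for (j in seq_len(nrow(plant))) {
        lab <- plant$label[j]
        code <- plant$code[j]
        doPlant <- runif(1) < plant$prob[j]
        if (doPlant) {
          s <- .setBaseAt(s, lab, modParentBase(registry, code))
          s <- addModification(s, lab, code, registry)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = id, label = lab, code = code, planted = doPlant,
          stringsAsFactors = FALSE)
      }
      seqs[[i]] <- s
    }
    list(seqs = seqs, truth = do.call(rbind, rows))
  })
}

#' Generate a synthetic peak list from theoretical ions
#'
#' True peaks are placed at the theoretical m/z values with Gaussian ppm
#' jitter and log-normal intensities; decoy peaks are uniform over the scan
#' window. The truth table records, for each emitted peak, whether it is a
#' true ion and which theoretical row it came from.
#'
#' @param theoretical data.frame of theoretical ions with an \code{mz}
#'   column.
#' @param jitterPpm Gaussian m/z jitter, ppm (default 5, typical
#'   high-resolution mass accuracy).
#' @param decoyFraction decoy peaks as a fraction of true peaks.
#' @param window m/z scan window for decoys.
#' @param seed RNG seed.
#' @return data.frame of peaks with columns \code{mz}, \code{intensity},
#'   \code{is_true}, \code{theory_index}, sorted by m/z.
#' @export
genPeakList <- function(theoretical, jitterPpm = 5, decoyFraction = 0.2,
                        window = c(600, 2000), seed = 1L) {
  stopifnot("mz" %in% names(theoretical))
  .withSeed(seed, {
    nTrue <- nrow(theoretical)
    true <- data.frame(
      mz = theoretical$mz * (1 + rnorm(nTrue, 0, jitterPpm * 1e-6)),
      intensity = rlnorm(nTrue, meanlog = log(1e5), sdlog = 0.8),
      is_true = TRUE,
      theory_index = seq_len(nTrue),
      stringsAsFactors = FALSE
    )
    nDecoy <- round(decoyFraction * nTrue)
    peaks <- true
    if (nDecoy > 0) {
      decoy <- data.frame(
        mz = runif(nDecoy, window[1], window[2]),
        intensity = rlnorm(nDecoy, meanlog = log(2e4), sdlog = 0.8),
        is_true = FALSE,
        theory_index = NA_integer_,
        stringsAsFactors = FALSE
      )
      peaks <- rbind(true, decoy)
    }
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    peaks
  })
}

#' Generate tRNA-seq pileups with misincorporation at planted sites
#'
#' For every Sprinzl position of every sequence, coverage is Poisson around
#' the target; at planted acp3U/acp3D sites the misincorporation count is
#' binomial with probability \code{pMod} and all misincorporated reads are
#' C (the C-biased U-to-C signature of the acp group); at all other
#' positions a background error probability \code{pErr} is spread uniformly
#' over the three non-reference bases and deletions.
#'
#' @param trnaSet output of [genTRNASet()].
#' @param pMod misincorporation probability at modified sites (default
#'   0.3).
#' @param pErr background per-base error probability (default 0.01).
#' @param coverage target mean coverage (default 500).
#' @param seed RNG seed.
#' @return pileup data.frame (columns \code{seq_id}, \code{sprinzl_label},
#'   \code{ref}, \code{nA}, \code{nC}, \code{nG}, \code{nU}, \code{nDel}).
#' @export
genPileups <- function(trnaSet, pMod = 0.3, pErr = 0.01, coverage = 500L,
                       seed = 1L) {
  .withSeed(seed, {
    rows <- list()
    for (s in trnaSet$seqs) {
      labels <- s@sprinzl
      mods <- residueMods(s)
      bases <- residueBases(s)
      for (i in seq_along(bases)) {
        cov <- rpois(1, coverage)
        if (cov == 0) cov <- 1L
        counts <- setNames(c(0L, 0L, 0L, 0L, 0L), c("A", "C", "G", "U", "Del"))
        modified <- !is.na(mods[i]) && mods[i] %in% c("acp3U", "acp3D")
        if (modified) {
          nMis <- rbinom(1, cov, pMod)
          counts["C"] <- counts["C"] + nMis
          counts[bases[i]] <- counts[bases[i]] + cov - nMis
        } else {
          nErr <- rbinom(1, cov, pErr)
          if (nErr > 0) {
            sinks <- c(setdiff(c("A", "C", "G", "U"), bases[i]), "Del")
            err <- table(factor(sample(sinks, nErr, replace = TRUE), levels = sinks))
            counts[names(err)] <- counts[names(err)] + as.integer(err)
          }
          counts[bases[i]] <- counts[bases[i]] + cov - nErr
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = seqID(s), sprinzl_label = labels[i], ref = bases[i],
          nA = counts[["A"]], nC = counts[["C"]], nG = counts[["G"]],
          nU = counts[["U"]], nDel = counts[["Del"]],
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a matched pair of melting curves
#'
#' Simulates the thermal-denaturation comparison of a modified and an
#' unmodified tRNA construct as two-state van't Hoff curves on the
#' 25-90 degC, 0.5 degC acquisition grid. The default midpoints (70.0 and
#' 66.7 degC at dH = 200 kJ/mol) are the package's reference conditions for
#' an acp3U47-stabilized tRNA and its unmodified counterpart.
#'
#' @param tmModified,tmUnmodified midpoints in degC.
#' @param dh van't Hoff enthalpy, kJ/mol (both constructs).
#' @param temperature acquisition grid.
#' @param noiseSd absorbance noise SD (0 = noise-free).
#' @param seed RNG seed.
#' @return list with \code{modified} and \code{unmodified}
#'   \linkS4class{MeltingCurve}s and a \code{truth} list of the parameters.
#' @export
genMeltingCurves <- function(tmModified = 70.0, tmUnmodified = 66.7,
                             dh = 200, temperature = seq(25, 90, by = 0.5),
                             noiseSd = 0, seed = 1L) {
  pMod <- TwoStateParams(tmModified, dh)
  pUnmod <- TwoStateParams(tmUnmodified, dh)
  list(
    modified = simulateMeltingCurve(pMod, temperature, noiseSd, seed = seed),
    unmodified = simulateMeltingCurve(pUnmod, temperature, noiseSd,
                                      seed = seed + 1L),
    truth = list(tmModified = tmModified, tmUnmodified = tmUnmodified, dh = dh)
  )
}
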