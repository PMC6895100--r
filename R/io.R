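# Plain-text readers and writers for the formats the pipeline exchanges:
# bracketed-modification FASTA with optional sidecar modification TSV,
# cloverleaf annotation TSV, presence-matrix / phenotype / annotation TSVs,
# pileup TSV, peak-list CSV, XIC CSV and melting-curve CSV. Everything is
# text so fixtures stay inspectable and language-portable.

#' Read modified sequences from FASTA with bracketed codes
#'
#' The sequence lines may carry bracketed modification codes
#' (\code{GGC[acp3U]AG...}); an optional sidecar TSV (columns
#' \code{seq_id}, \code{sprinzl_label}, \code{code}) adds modifications by
#' Sprinzl position after cloverleaf annotation is applied.
#'
#' @param fasta path to the FASTA file.
#' @param cloverleaf optional path to a cloverleaf TSV (columns
#'   \code{seq_id}, \code{arm}, \code{start}, \code{end}; 0-based
#'   half-open). When given, Sprinzl labels are assigned.
#' @param mods optional path to the sidecar modification TSV (requires
#'   \code{cloverleaf}).
#' @param registry \linkS4class{ModificationRegistry}.
#' @return named list of \linkS4class{ModifiedRNASequence}.
#' @export
readModifiedFasta <- function(fasta, cloverleaf = NULL, mods = NULL,
                              registry = defaultRegistry()) {
  lines <- readLines(fasta)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", fasta)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- list()
  for (k in seq_along(hdr)) {
    id <- sub("^>\\s*", "", lines[hdr[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    seqs[[id]] <- parseModifiedSequence(body, registry, id = id)
  }
  if (!is.null(cloverleaf)) {
    cl <- read.delim(cloverleaf, stringsAsFactors = FALSE)
    for (id in names(seqs)) {
      sub <- cl[cl$seq_id == id, , drop = FALSE]
      if (!nrow(sub)) next
      arms <- setNames(lapply(.ARM_NAMES, function(a) {
        r <- sub[sub$arm == a, , drop = FALSE]
        if (nrow(r) != 1L) stop("cloverleaf for '", id, "' must define arm ", a)
        c(r$start, r$end)
      }), .ARM_NAMES)
      ann <- CloverleafAnnotation(arms$acceptor, arms$dArm, arms$acArm,
                                  arms$vLoop, arms$tArm)
      seqs[[id]] <- assignSprinzl(seqs[[id]], ann)
    }
  }
  if (!is.null(mods)) {
    if (is.null(cloverleaf)) stop("sidecar modifications need a cloverleaf annotation")
    mt <- read.delim(mods, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(mt))) {
      id <- mt$seq_id[i]
      if (is.null(seqs[[id]])) stop("modification for unknown sequence '", id, "'")
      seqs[[id]] <- addModification(seqs[[id]], as.character(mt$sprinzl_label[i]),
                                    mt$code[i], registry)
    }
  }
  seqs
}

#' Write modified sequences as bracketed FASTA
#'
#' @param seqs list of \linkS4class{ModifiedRNASequence}.
#' @param path output file.
#' @export
writeModifiedFasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(c(paste0(">", seqID(s)), serializeModifiedSequence(s)), con)
  }
  invisible(path)
}

#' Read a phylogenetic-profile dataset from TSV files
#'
#' @param matrixPath presence matrix TSV: first column \code{group}, one
#'   0/1 column per taxon, plus optional per-taxon member-gene columns named
#'   \code{<taxon>.genes} (semicolon-separated gene ids).
#' @param phenotypePath TSV with columns \code{taxon}, \code{label}.
#' @param annotationPath TSV with columns \code{gene},
#'   \code{function_class}, \code{domains}.
#' @return a \linkS4class{ProfileDataset}.
#' @export
readProfileDataset <- function(matrixPath, phenotypePath, annotationPath = NULL) {
  m <- read.delim(matrixPath, stringsAsFactors = FALSE, check.names = FALSE)
  ph <- read.delim(phenotypePath, stringsAsFactors = FALSE)
  phenotype <- setNames(ph$label, ph$taxon)
  geneCols <- grep("\\.genes$", names(m), value = TRUE)
  taxa <- setdiff(names(m), c("group", geneCols))
  presence <- as.matrix(m[, taxa, drop = FALSE]) > 0
  rownames(presence) <- m$group
  members <- NULL
  if (length(geneCols)) {
    members <- lapply(seq_len(nrow(m)), function(i) {
      out <- list()
      for (gc in geneCols) {
        t <- sub("\\.genes$", "", gc)
        v <- m[[gc]][i]
        if (!is.na(v) && nzchar(v)) out[[t]] <- strsplit(v, ";", fixed = TRUE)[[1]]
      }
      out
    })
    names(members) <- m$group
  }
  ann <- if (is.null(annotationPath)) {
    data.frame(gene = character(0), function_class = character(0),
               domains = character(0), stringsAsFactors = FALSE)
  } else {
    a <- read.delim(annotationPath, stringsAsFactors = FALSE, na.strings = NULL)
    a$domains[is.na(a$domains)] <- ""
    a
  }
  ProfileDataset(presence, phenotype, annotations = ann, members = members)
}

#' Write a profile dataset to TSV files
#'
#' @param dataset a \linkS4class{ProfileDataset}.
#' @param matrixPath,phenotypePath,annotationPath output paths (see
#'   [readProfileDataset()] for the layouts).
#' @export
writeProfileDataset <- function(dataset, matrixPath, phenotypePath,
                                annotationPath = NULL) {
  p <- presenceMatrix(dataset)
  df <- data.frame(group = rownames(p), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (t in colnames(p)) df[[t]] <- as.integer(p[, t])
  mem <- groupMembers(dataset)
  for (t in colnames(p)) {
    df[[paste0(t, ".genes")]] <- vapply(rownames(p), function(g) {
      v <- mem[[g]][[t]]
      if (is.null(v)) "" else paste(v, collapse = ";")
    }, character(1))
  }
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- phenotypeLabels(dataset)
  write.table(data.frame(taxon = names(ph), label = ph),
              phenotypePath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotationPath)) {
    write.table(geneAnnotations(dataset), annotationPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dataset)
}

#' Read / write pileup TSV
#'
#' Columns: \code{seq_id}, \code{sprinzl_label}, \code{ref}, \code{nA},
#' \code{nC}, \code{nG}, \code{nU}, \code{nDel}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPileup <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(sprinzl_label = "character"))
  .checkPileup(p)
  p
}

#' @rdname readPileup
#' @param pileup pileup data.frame.
#' @export
writePileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak list CSV (columns mz, intensity[, rt])
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPeakList <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Read an XIC CSV (columns rt, intensity)
#'
#' @param path file path.
#' @return data.frame sorted by retention time.
#' @export
readXIC <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x[order(x$rt), , drop = FALSE]
}

#' Read / write a melting curve CSV (columns temperature_C, absorbance)
#'
#' @param path file path.
#' @return a \linkS4class{MeltingCurve}.
#' @export
readMeltingCurve <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  MeltingCurve(d$temperature_C, d$absorbance)
}

#' @rdname readMeltingCurve
#' @param curve a \linkS4class{MeltingCurve}.
#' @export
writeMeltingCurve <- function(curve, path) {
  write.csv(data.frame(temperature_C = curveTemperature(curve),
                       absorbance = curveAbsorbance(curve)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
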