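# Detection of acp3U sites from reverse-transcription misincorporation
# signatures in tRNA-seq pileups. acp3U blocks Watson-Crick pairing at N3
# of uracil and causes an apparent U-to-C conversion during cDNA synthesis;
# the caller looks for that signature at the D-loop positions 20/20a.

.PILEUP_COLS <- c("seq_id", "sprinzl_label", "ref", "nA", "nC", "nG", "nU", "nDel")

.checkPileup <- function(pileup) {
  miss <- setdiff(.PILEUP_COLS, names(pileup))
  if (length(miss)) stop("pileup is missing column(s): ", paste(miss, collapse = ", "))
  counts <- as.matrix(pileup[, c("nA", "nC", "nG", "nU", "nDel")])
  if (any(counts < 0)) stop("pileup counts must be non-negative")
  invisible(counts)
}

#' Per-column misincorporation rate
#'
#' 1 - count[reference] / coverage, where coverage sums the four base counts
#' and deletions; deletions therefore count as misincorporation.
#'
#' @param pileup data.frame with columns \code{seq_id},
#'   \code{sprinzl_label}, \code{ref}, \code{nA}, \code{nC}, \code{nG},
#'   \code{nU}, \code{nDel}. Zero-coverage rows are an error.
#' @return numeric vector of rates in [0, 1], one per row.
#' @examples
#' misincorporationRate(data.frame(seq_id = "t", sprinzl_label = "20",
#'   ref = "U", nA = 0, nC = 20, nG = 0, nU = 80, nDel = 0))
#' @export
misincorporationRate <- function(pileup) {
  counts <- .checkPileup(pileup)
  cov <- rowSums(counts)
  if (any(cov == 0)) stop("zero coverage at row(s): ",
                          paste(which(cov == 0), collapse = ", "))
  refCount <- counts[cbind(seq_len(nrow(pileup)),
                           match(paste0("n", pileup$ref),
                                 c("nA", "nC", "nG", "nU", "nDel")))]
  unname(1 - refCount / cov)
}

#' Call candidate acp3U sites from misincorporation signatures
#'
#' A column is called a candidate iff its reference base is U, coverage
#' meets \code{minCoverage}, the misincorporation rate meets \code{minRate},
#' and C is the strict plurality among non-reference base counts (deletions
#' count toward the rate but can never be the dominant mismatch base).
#' Output is sorted by sequence id, then canonical Sprinzl label order.
#'
#' @param pileup pileup data.frame (see [misincorporationRate()]).
#' @param labels Sprinzl labels of interest; default c("20", "20a"), the
#'   D-loop positions where the modification occurs in mammals.
#' @param minCoverage,minRate positive thresholds (defaults 50 and 0.1).
#' @return data.frame with columns \code{seq_id}, \code{sprinzl_label},
#'   \code{ref}, \code{coverage}, \code{rate}, \code{dominant_mismatch},
#'   \code{call} ("candidate"/"none"), one row per inspected column.
#' @export
callAcpCandidates <- function(pileup, labels = c("20", "20a"),
                              minCoverage = 50, minRate = 0.1) {
  stopifnot(minCoverage > 0, minRate > 0)
  counts <- .checkPileup(pileup)
  keep <- pileup$sprinzl_label %in% labels
  pileup <- pileup[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(pileup)) {
    return(data.frame(seq_id = character(0), sprinzl_label = character(0),
                      ref = character(0), coverage = numeric(0),
                      rate = numeric(0), dominant_mismatch = character(0),
                      call = character(0), stringsAsFactors = FALSE))
  }
  cov <- rowSums(counts)
  rate <- misincorporationRate(pileup)
  bases <- c("A", "C", "G", "U")
  dominant <- vapply(seq_len(nrow(pileup)), function(i) {
    nonref <- setdiff(bases, pileup$ref[i])
    v <- counts[i, paste0("n", nonref)]
    if (all(v == 0)) return(NA_character_)
    top <- which(v == max(v))
    if (length(top) > 1L) return(NA_character_)  # no strict plurality
    nonref[top]
  }, character(1))
  call <- ifelse(pileup$ref == "U" & cov >= minCoverage & rate >= minRate &
                   !is.na(dominant) & dominant == "C",
                 "candidate", "none")
  out <- data.frame(seq_id = pileup$seq_id, sprinzl_label = pileup$sprinzl_label,
                    ref = pileup$ref, coverage = cov, rate = rate,
                    dominant_mismatch = dominant, call = call,
                    stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, sprinzlOrder(out$sprinzl_label)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
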