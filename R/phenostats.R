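# Descriptive statistics of the phenotype assays: small-colony frequency
# under heat stress, the nalidixic-acid mutator-assay rate, replicate
# summaries, and the two-sample Student's t comparison.

#' A plate count with dilution and volume corrections
#'
#' @param colonies non-negative colony count.
#' @param dilution dilution factor (>= 1; e.g. 1e6 for a 10^6 dilution).
#' @param volume_ul plated volume in microliters (> 0).
#' @param condition free-text selective-condition label.
#' @return an object of class \code{plateCount}.
#' @export
plateCount <- function(colonies, dilution = 1, volume_ul = 100, condition = "") {
  stopifnot(colonies >= 0, dilution >= 1, volume_ul > 0)
  structure(list(colonies = colonies, dilution = dilution,
                 volume_ul = volume_ul, condition = condition),
            class = "plateCount")
}

#' @export
print.plateCount <- function(x, ...) {
  cat("plateCount:", x$colonies, "colonies, dilution", format(x$dilution),
      ",", x$volume_ul, "uL",
      if (nzchar(x$condition)) paste0("(", x$condition, ")"), "\n")
  invisible(x)
}

# CFU per unit volume of the undiluted culture.
.cfuDensity <- function(pc) pc$colonies * pc$dilution / pc$volume_ul

#' Small-colony frequency
#'
#' Fraction of small colonies among all colonies counted on a plate.
#'
#' @param nSmall,nNormal non-negative counts; their sum must be positive.
#' @return fraction in [0, 1].
#' @examples
#' smallColonyFrequency(25, 75)  # 0.25
#' @export
smallColonyFrequency <- function(nSmall, nNormal) {
  stopifnot(nSmall >= 0, nNormal >= 0)
  tot <- nSmall + nNormal
  if (tot == 0) stop("no colonies counted")
  nSmall / tot
}

#' Mutator-assay mutation rate
#'
#' Resistant CFU per viable CFU: the dilution- and volume-corrected colony
#' density on the selective plate divided by that on the nonselective
#' plate. This is a per-plating frequency, as in a ratio-of-plates mutator
#' assay — not a Luria-Delbruck fluctuation estimate.
#'
#' @param selective,nonselective [plateCount()] objects for the plates with
#'   and without the selective agent.
#' @return non-negative rate.
#' @examples
#' mutationRate(plateCount(10, 1), plateCount(100, 1e6))  # 1e-7
#' @export
mutationRate <- function(selective, nonselective) {
  stopifnot(inherits(selective, "plateCount"), inherits(nonselective, "plateCount"))
  if (nonselective$colonies == 0) {
    stop("zero colonies on the nonselective plate: viable count undefined")
  }
  .cfuDensity(selective) / .cfuDensity(nonselective)
}

#' Replicate summary: mean, sample SD and n
#'
#' @param values numeric vector of replicate measurements (n >= 2 for the
#'   standard deviation).
#' @return list with elements \code{mean}, \code{sd}, \code{n}.
#' @export
replicateSummary <- function(values) {
  n <- length(values)
  if (n < 2L) {
    .stopWithClass("tRNAcp_sd_undefined",
                   "standard deviation requires at least 2 replicates")
  }
  list(mean = mean(values), sd = sd(values), n = n)
}

#' Two-sample Student's t test
#'
#' Thin wrapper around [stats::t.test()] returning the statistic and
#' two-sided p value, with one extra contract: two degenerate
#' (zero-variance) groups with equal means return t = 0, p = 1 instead of
#' an error.
#'
#' @param groupA,groupB numeric vectors, each with n >= 2.
#' @param equalVariance logical; classical Student's test (default) or
#'   Welch's.
#' @return list with elements \code{t} and \code{p}.
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))$t  # -3.674
#' @export
twoSampleT <- function(groupA, groupB, equalVariance = TRUE) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2)
  degenerate <- sd(groupA) == 0 && sd(groupB) == 0
  if (degenerate) {
    if (mean(groupA) == mean(groupB)) return(list(t = 0, p = 1))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  fit <- stats::t.test(groupA, groupB, var.equal = equalVariance)
  list(t = unname(fit$statistic), p = fit$p.value)
}
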