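#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm rbinom rpois rlnorm runif lm coef pt sd setNames
#' @importFrom utils read.delim read.csv write.csv head tail packageVersion
NULL

# Monoisotopic atomic masses (Da). Source of truth for every mass in the
# package: residue and modification masses are computed from elemental
# composition, never typed in twice.
.ATOMIC_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

#' Parse a molecular formula into element counts
#'
#' Understands plain Hill-style formulas over C, H, N, O, P, S with optional
#' leading sign, e.g. \code{"C4H7NO2"} or \code{"-H2O"}. An empty string is
#' the empty formula (mass zero).
#'
#' @param formula character scalar.
#' @return named integer vector of element counts (possibly negative).
#' @examples
#' parseFormula("C4H7NO2")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  formula <- trimws(formula)
  if (formula == "" || formula == "0") {
    return(setNames(integer(0), character(0)))
  }
  sign <- 1L
  if (startsWith(formula, "-")) {
    sign <- -1L
    formula <- substring(formula, 2L)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  elems <- sub("[0-9]+$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]+$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  bad <- setdiff(elems, names(.ATOMIC_MASS))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  out <- tapply(counts, elems, sum)
  setNames(as.integer(out) * sign, names(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula character formula (see [parseFormula()]) or a named integer
#'   vector of element counts.
#' @return mass in Da.
#' @examples
#' formulaMass("H2O")
#' @export
formulaMass <- function(formula) {
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  if (!length(counts)) return(0)
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

# Add element-count vectors (names may differ).
.addCounts <- function(a, b) {
  elems <- union(names(a), names(b))
  av <- setNames(integer(length(elems)), elems)
  av[names(a)] <- av[names(a)] + a
  av[names(b)] <- av[names(b)] + b
  av
}

# Evaluate `code` under a fixed RNG seed, restoring the caller-visible RNG
# state afterwards so generators never perturb the global stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.stopWithClass <- function(class, message, call. = FALSE) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}
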