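# Comparative-genomics screen: intersect ortholog-group presence/absence
# profiles with a modification phenotype, filter by functional annotation,
# rank by domain content; plus a reciprocal-best-hit ortholog builder so the
# screen is exercisable without an external orthology database.

#' ProfileDataset: ortholog profiles, phenotype and annotations
#'
#' @slot presence logical matrix, ortholog groups (rows) x taxa (columns);
#'   presence means the taxon has at least one member gene of the group
#'   (paralog counts are ignored). Every row has at least one TRUE.
#' @slot members named list: group id -> named list taxon -> character
#'   vector of member gene ids.
#' @slot phenotype named character vector over the taxa with values
#'   "positive" (modification present), "negative" (absent) or "unknown"
#'   (not measured).
#' @slot annotations data.frame with columns \code{gene},
#'   \code{function_class} ("known"/"unknown") and \code{domains}
#'   (semicolon-separated tags, possibly empty).
#' @seealso [screenCandidates()], [scoreProfiles()]
#' @export
setClass("ProfileDataset", representation(
  presence = "matrix",
  members = "list",
  phenotype = "character",
  annotations = "data.frame"
))

setValidity("ProfileDataset", function(object) {
  p <- object@presence
  if (!is.logical(p)) return("presence must be a logical matrix")
  if (is.null(rownames(p)) || is.null(colnames(p))) {
    return("presence must have group row names and taxon column names")
  }
  if (anyDuplicated(rownames(p))) return("group ids must be unique")
  if (nrow(p) == 0L || ncol(p) == 0L) return("presence matrix is empty")
  if (any(rowSums(p) == 0L)) return("every group must be present in >= 1 taxon")
  if (!all(colnames(p) %in% names(object@phenotype))) {
    return("every taxon needs a phenotype label")
  }
  if (!all(object@phenotype %in% c("positive", "negative", "unknown"))) {
    return("phenotype labels must be positive/negative/unknown")
  }
  TRUE
})

#' Construct a ProfileDataset
#'
#' @param presence logical (or 0/1) matrix, groups x taxa, with dimnames.
#' @param phenotype named character vector (taxon -> label).
#' @param annotations gene annotation data.frame (may be empty).
#' @param members optional group -> taxon -> gene-id list; when omitted,
#'   a placeholder member gene \code{"<taxon>:<group>"} is created per
#'   present cell.
#' @return a \linkS4class{ProfileDataset}.
#' @export
ProfileDataset <- function(presence, phenotype,
                           annotations = data.frame(gene = character(0),
                                                    function_class = character(0),
                                                    domains = character(0),
                                                    stringsAsFactors = FALSE),
                           members = NULL) {
  storage.mode(presence) <- "logical"
  if (is.null(members)) {
    members <- lapply(rownames(presence), function(g) {
      taxa <- colnames(presence)[presence[g, ]]
      setNames(lapply(taxa, function(t) paste0(t, ":", g)), taxa)
    })
    names(members) <- rownames(presence)
  }
  new("ProfileDataset", presence = presence, members = members,
      phenotype = phenotype, annotations = annotations)
}

#' @rdname ProfileDataset
#' @param object,x a \linkS4class{ProfileDataset}.
#' @export
presenceMatrix <- function(x) x@presence

#' @rdname ProfileDataset
#' @export
phenotypeLabels <- function(x) x@phenotype[colnames(x@presence)]

#' @rdname ProfileDataset
#' @export
groupMembers <- function(x) x@members

#' @rdname ProfileDataset
#' @export
geneAnnotations <- function(x) x@annotations

setMethod("show", "ProfileDataset", function(object) {
  ph <- phenotypeLabels(object)
  cat("ProfileDataset:", nrow(object@presence), "ortholog groups x",
      ncol(object@presence), "taxa (",
      sum(ph == "positive"), "positive /", sum(ph == "negative"),
      "negative /", sum(ph == "unknown"), "unknown )\n")
})

#' ScreenResult: staged output of the candidate screen
#'
#' Stage counts are non-increasing and candidate sets are nested across
#' stages by construction.
#'
#' @slot stages data.frame with columns \code{stage}, \code{n}.
#' @slot candidates named list: stage -> character vector of group ids.
#' @slot scores named numeric profile-consistency score per final-stage
#'   candidate group.
#' @slot referenceTaxon taxon used for annotation filtering ("" before
#'   [filterByAnnotation()] is applied).
#' @export
setClass("ScreenResult", representation(
  stages = "data.frame",
  candidates = "list",
  scores = "numeric",
  referenceTaxon = "character"
))

setValidity("ScreenResult", function(object) {
  n <- object@stages$n
  if (any(diff(n) > 0)) return("stage counts must be non-increasing")
  sets <- object@candidates
  if (length(sets) > 1L) {
    for (k in 2:length(sets)) {
      if (!all(sets[[k]] %in% sets[[k - 1L]])) {
        return("candidates at each stage must be a subset of the previous stage")
      }
    }
  }
  TRUE
})

#' @rdname ScreenResult-class
#' @param x a \linkS4class{ScreenResult}.
#' @export
stageCounts <- function(x) x@stages

#' @rdname ScreenResult-class
#' @param stage stage name or NULL for the final stage.
#' @export
candidates <- function(x, stage = NULL) {
  if (is.null(stage)) x@candidates[[length(x@candidates)]]
  else x@candidates[[stage]]
}

#' @rdname ScreenResult-class
#' @export
profileScores <- function(x) x@scores

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:\n")
  s <- object@stages
  cat(paste0("  ", s$stage, ": ", s$n), sep = "\n")
  fin <- candidates(object)
  cat("  final candidates:",
      if (length(fin)) paste(head(fin, 10), collapse = ", ") else "(none)",
      if (length(fin) > 10) "..." else "", "\n")
})

.labeledTaxa <- function(dataset) {
  ph <- phenotypeLabels(dataset)
  list(pos = names(ph)[ph == "positive"], neg = names(ph)[ph == "negative"])
}

#' Strict phylogenetic-profile screen
#'
#' A group passes iff it is present in every positive-phenotype taxon and
#' absent in every negative-phenotype taxon; unknown-phenotype taxa are
#' ignored. This is the Venn-intersection screen used to narrow a genome's
#' ORFs down to candidates co-distributed with the modification phenotype.
#'
#' @param dataset a \linkS4class{ProfileDataset} with at least one positive
#'   and one negative taxon.
#' @return a \linkS4class{ScreenResult} with stages "total" and
#'   "intersection"; passers carry profile-consistency score 1.
#' @export
screenCandidates <- function(dataset) {
  stopifnot(is(dataset, "ProfileDataset"))
  p <- presenceMatrix(dataset)
  if (nrow(p) == 0L) stop("empty presence matrix")
  lt <- .labeledTaxa(dataset)
  if (!length(lt$pos)) stop("no positive-phenotype taxa")
  if (!length(lt$neg)) stop("no negative-phenotype taxa")
  pass <- rowSums(p[, lt$pos, drop = FALSE]) == length(lt$pos) &
    rowSums(p[, lt$neg, drop = FALSE]) == 0L
  passers <- rownames(p)[pass]
  new("ScreenResult",
      stages = data.frame(stage = c("total", "intersection"),
                          n = c(nrow(p), length(passers)),
                          stringsAsFactors = FALSE),
      candidates = list(total = rownames(p), intersection = passers),
      scores = setNames(rep(1, length(passers)), passers),
      referenceTaxon = "")
}

.referenceGenes <- function(dataset, group, referenceTaxon) {
  mem <- dataset@members[[group]]
  if (is.null(mem)) character(0) else unlist(mem[referenceTaxon], use.names = FALSE)
}

#' Filter screen candidates by functional annotation
#'
#' Retains candidates whose member gene in the reference taxon has the kept
#' function class (default "unknown": the screen targets uncharacterized
#' genes). A candidate gene missing from the annotation table is an error
#' listing the offending ids.
#'
#' @param result a \linkS4class{ScreenResult} from [screenCandidates()].
#' @param dataset the \linkS4class{ProfileDataset} screened.
#' @param keepClass function class to keep ("unknown" or "known").
#' @param referenceTaxon the taxon whose gene annotations are consulted.
#' @return the result with an "annotation" stage appended.
#' @export
filterByAnnotation <- function(result, dataset, keepClass = "unknown",
                               referenceTaxon) {
  stopifnot(is(result, "ScreenResult"), is(dataset, "ProfileDataset"))
  cur <- candidates(result)
  ann <- geneAnnotations(dataset)
  keep <- character(0)
  missing <- character(0)
  for (g in cur) {
    genes <- .referenceGenes(dataset, g, referenceTaxon)
    unseen <- setdiff(genes, ann$gene)
    if (length(unseen)) {
      missing <- c(missing, unseen)
      next
    }
    cls <- ann$function_class[match(genes, ann$gene)]
    if (any(cls == keepClass)) keep <- c(keep, g)
  }
  if (length(missing)) {
    stop("candidate gene(s) missing from annotation table: ",
         paste(unique(missing), collapse = ", "))
  }
  result@stages <- rbind(result@stages,
                         data.frame(stage = "annotation", n = length(keep),
                                    stringsAsFactors = FALSE))
  result@candidates$annotation <- keep
  result@scores <- result@scores[names(result@scores) %in% keep]
  result@referenceTaxon <- referenceTaxon
  validObject(result)
  result
}

#' Rank candidates by preferred protein-domain tags
#'
#' Candidates whose reference-taxon gene carries any preferred domain tag
#' (e.g. the uncharacterized DTW domain) sort first; ties are broken
#' lexicographically by gene id. Empty tag sets are allowed.
#'
#' @param result a \linkS4class{ScreenResult}.
#' @param dataset the screened \linkS4class{ProfileDataset}.
#' @param preferredTags character vector of domain tags.
#' @param referenceTaxon taxon for gene lookup; defaults to the one recorded
#'   by [filterByAnnotation()].
#' @return data.frame with columns \code{gene}, \code{group},
#'   \code{preferred}, in rank order.
#' @export
rankByDomain <- function(result, dataset, preferredTags = character(0),
                         referenceTaxon = result@referenceTaxon) {
  stopifnot(is(result, "ScreenResult"))
  if (!nzchar(referenceTaxon)) stop("referenceTaxon must be given")
  ann <- geneAnnotations(dataset)
  rows <- list()
  for (g in candidates(result)) {
    for (gene in .referenceGenes(dataset, g, referenceTaxon)) {
      tags <- character(0)
      i <- match(gene, ann$gene)
      if (!is.na(i) && nzchar(ann$domains[i])) {
        tags <- strsplit(ann$domains[i], ";", fixed = TRUE)[[1]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, group = g,
        preferred = any(tags %in% preferredTags),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), group = character(0),
                      preferred = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(!out$preferred, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relaxed profile-consistency score
#'
#' For each group, the fraction of phenotype-labeled taxa where presence
#' matches phenotype (present in positives, absent in negatives). Groups
#' passing the strict screen score exactly 1.
#'
#' @inheritParams screenCandidates
#' @return named numeric vector over groups.
#' @export
scoreProfiles <- function(dataset) {
  stopifnot(is(dataset, "ProfileDataset"))
  p <- presenceMatrix(dataset)
  if (nrow(p) == 0L) stop("empty presence matrix")
  lt <- .labeledTaxa(dataset)
  if (!length(lt$pos)) stop("no positive-phenotype taxa")
  labeled <- c(lt$pos, lt$neg)
  want <- colnames(p)[match(labeled, colnames(p))] %in% lt$pos
  sub <- p[, labeled, drop = FALSE]
  setNames(rowMeans(sub == matrix(want, nrow(sub), length(labeled), byrow = TRUE)),
           rownames(p))
}

#' Reciprocal-best-hit ortholog grouping
#'
#' Builds ortholog groups from pairwise gene similarity scores: for each
#' ordered taxon pair the best hit of every gene is found (ties broken by
#' the lexicographically smaller partner id), reciprocal best hits become
#' edges, and groups are the connected components of the RBH graph
#' (single-linkage). Deterministic for fixed input. If only one direction of
#' a taxon pair is supplied, its scores are used for both directions.
#'
#' @param hits data.frame with columns \code{taxon_a}, \code{gene_a},
#'   \code{taxon_b}, \code{gene_b}, \code{score} (finite). Duplicate
#'   (pair, gene_a, gene_b) rows are an error.
#' @return named list of groups, each a character vector of
#'   \code{"taxon|gene"} member ids; groups are ordered and named
#'   deterministically ("OG0001", ...) by their smallest member.
#' @export
buildRBHOrthologs <- function(hits) {
  need <- c("taxon_a", "gene_a", "taxon_b", "gene_b", "score")
  stopifnot(all(need %in% names(hits)))
  if (!all(is.finite(hits$score))) stop("scores must be finite")
  key <- paste(hits$taxon_a, hits$taxon_b, hits$gene_a, hits$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene_a, gene_b) rows in a taxon-pair table")
  }
  # symmetrize taxon pairs supplied in one direction only
  pairKey <- function(a, b) paste(a, b, sep = "\r")
  have <- unique(pairKey(hits$taxon_a, hits$taxon_b))
  rev_ <- hits[!pairKey(hits$taxon_b, hits$taxon_a) %in% have, , drop = FALSE]
  if (nrow(rev_)) {
    rev_ <- data.frame(taxon_a = rev_$taxon_b, gene_a = rev_$gene_b,
                       taxon_b = rev_$taxon_a, gene_b = rev_$gene_a,
                       score = rev_$score, stringsAsFactors = FALSE)
    hits <- rbind(hits[, need], rev_)
  }
  # best hit per (source taxon pair, source gene)
  src <- paste(hits$taxon_a, hits$taxon_b, hits$gene_a, sep = "\r")
  ord <- order(src, -hits$score, hits$gene_b)
  best <- hits[ord[!duplicated(src[ord])], , drop = FALSE]
  bestKey <- paste(best$taxon_a, best$gene_a, best$taxon_b, best$gene_b, sep = "\r")
  recip <- paste(best$taxon_b, best$gene_b, best$taxon_a, best$gene_a, sep = "\r")
  rbh <- best[recip %in% bestKey, , drop = FALSE]
  nodeA <- paste(rbh$taxon_a, rbh$gene_a, sep = "|")
  nodeB <- paste(rbh$taxon_b, rbh$gene_b, sep = "|")
  allNodes <- sort(unique(paste(hits$taxon_a, hits$gene_a, sep = "|")))
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodeA, to = nodeB, stringsAsFactors = FALSE),
    directed = FALSE, vertices = allNodes)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  names(groups) <- sprintf("OG%04d", seq_along(groups))
  groups
}
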