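# Phylogenetic-profiling screen, annotation filter, domain ranking, RBH
# ortholog builder.

makeToyDataset <- function(presence, phenotype, annotations = NULL) {
  if (is.null(annotations)) ProfileDataset(presence, phenotype)
  else ProfileDataset(presence, phenotype, annotations = annotations)
}

test_that("strict screen keeps exactly the co-distributed groups", {
  taxa <- c(paste0("P", 1:3), paste0("N", 1:5))
  phenotype <- setNames(rep(c("positive", "negative"), c(3, 5)), taxa)
  presence <- rbind(
    G1 = rep(TRUE, 8),                       # present everywhere
    G2 = c(rep(TRUE, 3), rep(FALSE, 5)),     # perfectly co-distributed
    G3 = c(TRUE, TRUE, FALSE, rep(FALSE, 5)),
    G4 = c(rep(TRUE, 3), TRUE, rep(FALSE, 4)),
    G5 = c(FALSE, rep(TRUE, 7)),
    G6 = c(rep(TRUE, 3), rep(c(TRUE, FALSE), c(1, 4)))
  )
  colnames(presence) <- taxa
  ds <- makeToyDataset(presence, phenotype)
  res <- screenCandidates(ds)
  expect_identical(candidates(res, "intersection"), "G2")
  expect_identical(stageCounts(res)$n, c(6L, 1L))
  expect_identical(sort(candidates(res)), sort(bruteForceScreen(presence, phenotype)))
})

test_that("screen equals brute force on random instances up to 50 x 10", {
  set.seed(101)
  for (rep in 1:40) {
    nG <- sample(1:50, 1)
    nT <- sample(2:10, 1)
    taxa <- paste0("T", seq_len(nT))
    presence <- matrix(runif(nG * nT) < 0.5, nG, nT,
                       dimnames = list(paste0("G", seq_len(nG)), taxa))
    presence[rowSums(presence) == 0, 1] <- TRUE
    labels <- sample(c("positive", "negative", "unknown"), nT, replace = TRUE)
    labels[1] <- "positive"
    labels[2] <- "negative"
    phenotype <- setNames(labels, taxa)
    ds <- makeToyDataset(presence, phenotype)
    expect_identical(sort(candidates(screenCandidates(ds))),
                     sort(bruteForceScreen(presence, phenotype)))
  }
})

test_that("adding a negative taxon never enlarges the candidate set", {
  set.seed(202)
  for (rep in 1:25) {
    nG <- 20
    taxa <- paste0("T", 1:6)
    presence <- matrix(runif(nG * 6) < 0.5, nG, 6,
                       dimnames = list(paste0("G", 1:nG), taxa))
    presence[rowSums(presence) == 0, 1] <- TRUE
    phenotype <- setNames(c("positive", "positive", rep("negative", 3), "unknown"),
                          taxa)
    before <- candidates(screenCandidates(makeToyDataset(presence, phenotype)))
    phenotype["T6"] <- "negative"   # promote the unknown taxon to negative
    after <- candidates(screenCandidates(makeToyDataset(presence, phenotype)))
    expect_true(all(after %in% before))
  }
})

test_that("screen preconditions are enforced", {
  presence <- matrix(TRUE, 1, 2, dimnames = list("G1", c("A", "B")))
  expect_error(
    screenCandidates(makeToyDataset(presence,
                                    c(A = "negative", B = "unknown"))),
    "no positive")
  expect_error(
    screenCandidates(makeToyDataset(presence,
                                    c(A = "positive", B = "unknown"))),
    "no negative")
})

test_that("annotation filter keeps unknown-function candidates only", {
  taxa <- c("REF", "N1")
  phenotype <- c(REF = "positive", N1 = "negative")
  presence <- matrix(c(rep(TRUE, 5), rep(FALSE, 5)), 5, 2,
                     dimnames = list(paste0("G", 1:5), taxa))
  ann <- data.frame(
    gene = paste0("REF:G", 1:5),
    function_class = c("known", "unknown", "known", "unknown", "known"),
    domains = c("", "DTW", "", "", "PUA"),
    stringsAsFactors = FALSE)
  ds <- makeToyDataset(presence, phenotype, ann)
  res <- screenCandidates(ds)
  expect_identical(stageCounts(res)$n[2], 5L)
  res <- filterByAnnotation(res, ds, keepClass = "unknown", referenceTaxon = "REF")
  expect_identical(sort(candidates(res)), c("G2", "G4"))
  expect_identical(stageCounts(res)$stage, c("total", "intersection", "annotation"))

  # all known -> empty
  ann2 <- ann
  ann2$function_class <- "known"
  ds2 <- makeToyDataset(presence, phenotype, ann2)
  res2 <- filterByAnnotation(screenCandidates(ds2), ds2, referenceTaxon = "REF")
  expect_length(candidates(res2), 0L)

  # missing annotation -> error naming the gene
  ann3 <- ann[-2, ]
  ds3 <- makeToyDataset(presence, phenotype, ann3)
  expect_error(filterByAnnotation(screenCandidates(ds3), ds3,
                                  referenceTaxon = "REF"),
               "REF:G2")
})

test_that("domain ranking puts preferred tags first, then lexicographic", {
  taxa <- c("REF", "N1")
  phenotype <- c(REF = "positive", N1 = "negative")
  presence <- matrix(c(rep(TRUE, 3), rep(FALSE, 3)), 3, 2,
                     dimnames = list(c("Gc", "Ga", "Gb"), taxa))
  ann <- data.frame(gene = c("REF:Gc", "REF:Ga", "REF:Gb"),
                    function_class = "unknown",
                    domains = c("", "", "DTW"),
                    stringsAsFactors = FALSE)
  ds <- makeToyDataset(presence, phenotype, ann)
  res <- filterByAnnotation(screenCandidates(ds), ds, referenceTaxon = "REF")
  ranked <- rankByDomain(res, ds, preferredTags = "DTW")
  expect_identical(ranked$gene[1], "REF:Gb")
  expect_true(ranked$preferred[1])
  # without preferred tags: plain lexicographic
  ranked0 <- rankByDomain(res, ds, preferredTags = character(0))
  expect_identical(ranked0$gene, sort(ranked0$gene))
})

test_that("preferred-tagged candidates always precede untagged ones", {
  set.seed(303)
  taxa <- c("REF", "N1")
  phenotype <- c(REF = "positive", N1 = "negative")
  for (rep in 1:100) {
    nG <- sample(3:8, 1)
    ids <- paste0("G", sample(100, nG))
    presence <- matrix(c(rep(TRUE, nG), rep(FALSE, nG)), nG, 2,
                       dimnames = list(ids, taxa))
    ann <- data.frame(gene = paste0("REF:", ids),
                      function_class = "unknown",
                      domains = sample(c("", "DTW", "PUA"), nG, replace = TRUE),
                      stringsAsFactors = FALSE)
    ds <- makeToyDataset(presence, phenotype, ann)
    res <- filterByAnnotation(screenCandidates(ds), ds, referenceTaxon = "REF")
    ranked <- rankByDomain(res, ds, preferredTags = "DTW")
    if (any(ranked$preferred) && any(!ranked$preferred)) {
      expect_lt(max(which(ranked$preferred)), min(which(!ranked$preferred)))
    }
  }
})

test_that("profile-consistency scores match phenotype agreement fractions", {
  taxa <- paste0("T", 1:8)
  phenotype <- setNames(rep(c("positive", "negative"), c(3, 5)), taxa)
  presence <- rbind(
    Gperfect = c(rep(TRUE, 3), rep(FALSE, 5)),
    Gubiq = rep(TRUE, 8)
  )
  colnames(presence) <- taxa
  ds <- makeToyDataset(presence, phenotype)
  sc <- scoreProfiles(ds)
  expect_equal(unname(sc["Gperfect"]), 1.0)
  expect_equal(unname(sc["Gubiq"]), 3 / 8)
})

test_that("strict-mode passers always score exactly 1", {
  for (seed in 1:10) {
    g <- genProfileDataset(nDecoys = 100, seed = seed)
    res <- screenCandidates(g$dataset)
    sc <- scoreProfiles(g$dataset)
    expect_true(all(sc[candidates(res)] == 1))
  }
})

test_that("RBH grouping recovers planted families and matches brute force", {
  # two taxa, one gene each, a single score row -> one group of two
  one <- data.frame(taxon_a = "A", gene_a = "a1", taxon_b = "B", gene_b = "b1",
                    score = 10, stringsAsFactors = FALSE)
  g1 <- buildRBHOrthologs(one)
  expect_length(g1, 1L)
  expect_identical(sort(g1[[1]]), c("A|a1", "B|b1"))

  # 3 taxa x 3 families with separated score blocks -> 3 groups
  taxa <- c("A", "B", "C")
  fams <- 1:3
  rows <- list()
  for (ta in taxa) for (tb in setdiff(taxa, ta)) {
    for (fa in fams) for (fb in fams) {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_a = ta, gene_a = paste0(tolower(ta), fa),
        taxon_b = tb, gene_b = paste0(tolower(tb), fb),
        score = if (fa == fb) 100 + fa else 10 + runif(1),
        stringsAsFactors = FALSE)
    }
  }
  set.seed(404)
  hits <- do.call(rbind, rows)
  groups <- buildRBHOrthologs(hits)
  expect_length(groups, 3L)
  for (f in fams) {
    fam <- sort(paste0(taxa, "|", tolower(taxa), f))
    expect_true(any(vapply(groups, function(g) identical(sort(g), fam),
                           logical(1))))
  }

  # duplicate rows rejected
  expect_error(buildRBHOrthologs(rbind(one, one)), "duplicate")

  # determinism
  expect_identical(buildRBHOrthologs(hits), buildRBHOrthologs(hits))
})

test_that("planted causal group survives the full screen pipeline", {
  g <- genProfileDataset(nDecoys = 200, seed = 7)
  res <- screenCandidates(g$dataset)
  expect_true(g$truth$plantedGroup %in% candidates(res))
  res <- filterByAnnotation(res, g$dataset, keepClass = "unknown",
                            referenceTaxon = g$truth$referenceTaxon)
  expect_true(g$truth$plantedGroup %in% candidates(res))
  ranked <- rankByDomain(res, g$dataset, preferredTags = "DTW")
  expect_identical(ranked$gene[1], g$truth$plantedGene)
})
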