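#' Loci covered in both tissues after filtering
#'
#' @param xBlood,xGonad filtered [MethylomeSE] objects.
#' @return character vector of shared locus keys ("scaffold:pos").
#' @export
sharedLoci <- function(xBlood, xGonad) {
  intersect(lociKeys(xBlood), lociKeys(xGonad))
}

#' Compare DMC proportions between tissues on the shared loci
#'
#' Two-sided Fisher exact test of the 2x2 table
#' (differentially methylated / not) x (tissue A / tissue B), both
#' tissues over the same `nShared` loci.
#'
#' @param nDmcA,nDmcB DMC counts per tissue among the shared loci.
#' @param nShared number of shared covered loci.
#' @return list with `odds_ratio` and `p`.
#' @export
dmProportionTest <- function(nDmcA, nShared, nDmcB) {
  stopifnot(nDmcA <= nShared, nDmcB <= nShared)
  et <- enrichmentTest(c(dm = nDmcA, rest = nShared - nDmcA),
                       c(dm = nDmcB, rest = nShared - nDmcB))
  list(odds_ratio = et$odds_ratio[1L], p = et$p[1L])
}

#' Compare gene-context distributions of DMCs across tissues
#'
#' Per tissue and gene-context category, a Fisher test of the DMC
#' counts against the shared-locus background with that tissue's DMCs
#' excluded, BH-adjusted within tissue.
#'
#' @param dmcContexts named list (by tissue) of character vectors of
#'   gene contexts, one per DMC.
#' @param backgroundContexts character vector of gene contexts for all
#'   shared loci.
#' @param categories category levels (default the four gene contexts).
#' @return data.frame with `tissue`, `category`, `odds_ratio`, `p`,
#'   `q`.
#' @export
contextDistributionCompare <- function(dmcContexts, backgroundContexts,
                                       categories = c("promoter", "exon",
                                                      "intron",
                                                      "intergenic")) {
  countBy <- function(v) {
    tab <- table(factor(v, levels = categories))
    stats::setNames(as.integer(tab), categories)
  }
  bgAll <- countBy(backgroundContexts)
  out <- lapply(names(dmcContexts), function(tis) {
    dmc <- countBy(dmcContexts[[tis]])
    bg <- bgAll - dmc           # background excludes this tissue's DMCs
    if (any(bg < 0))
      stop("DMC contexts of ", tis, " are not a subset of the background")
    et <- enrichmentTest(dmc, bg)
    cbind(tissue = tis, et)
  })
  do.call(rbind, out)
}

#' Cross-tissue shared-locus report
#'
#' Assembles the shared-locus universe, per-tissue temperature-DMC
#' counts restricted to it, their overlap, the Fisher comparison of DMC
#' proportions, and per-tissue gene-context enrichment.
#'
#' @param xBlood,xGonad filtered [MethylomeSE] objects.
#' @param dmcKeysBlood,dmcKeysGonad character keys of each tissue's
#'   temperature-associated DMCs.
#' @param contexts optional named character vector: gene context per
#'   shared locus key (enables the context comparison).
#' @return list: `n_shared`, `dmc_counts`, `overlap`, `proportion_test`,
#'   and `context_tests` when contexts are given. A locus outside the
#'   shared universe in any DMC set is an error.
#' @export
crossTissueReport <- function(xBlood, xGonad, dmcKeysBlood, dmcKeysGonad,
                              contexts = NULL) {
  shared <- sharedLoci(xBlood, xGonad)
  dmcB <- intersect(dmcKeysBlood, shared)
  dmcG <- intersect(dmcKeysGonad, shared)
  out <- list(
    n_shared = length(shared),
    dmc_counts = c(blood = length(dmcB), gonad = length(dmcG)),
    overlap = intersect(dmcB, dmcG),
    proportion_test = dmProportionTest(length(dmcB), length(shared),
                                       length(dmcG)))
  if (!is.null(contexts)) {
    stopifnot(all(shared %in% names(contexts)))
    out$context_tests <- contextDistributionCompare(
      list(blood = unname(contexts[dmcB]), gonad = unname(contexts[dmcG])),
      unname(contexts[shared]))
  }
  out
}
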