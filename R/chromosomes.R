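## Chromosome vocabulary and reference protein-coding gene totals.

CHROMOSOMES <- c(as.character(1:22), "X", "Y")

#' Reference protein-coding gene counts per chromosome
#'
#' Protein-coding gene totals per human chromosome from the GRCh38.p13
#' reference annotation (NCBI Genome Reference Consortium). These are the
#' default denominators for per-chromosome over-expression percentages: the
#' share of a chromosome's coding genes that is called over-expressed is more
#' interpretable against the reference total than against the subset present
#' on a particular array.
#'
#' @return Named integer vector over chromosomes `1..22, X, Y` (24 entries,
#'   20,399 genes in total; chromosome 21 has 234).
#' @seealso [scaledChromosomeCounts()] for proportionally scaled-down copies
#'   used by the synthetic data generator.
#' @examples
#' referenceChromosomeCounts()[["21"]] # 234
#' @export
referenceChromosomeCounts <- function() {
  setNames(
    c(2058L, 1309L, 1078L, 752L, 876L, 1048L, 989L, 677L, 786L, 733L,
      1298L, 1034L, 327L, 830L, 613L, 873L, 1197L, 270L, 1472L, 544L,
      234L, 488L, 842L, 71L),
    CHROMOSOMES
  )
}

#' Proportionally scaled chromosome gene counts
#'
#' Scales the GRCh38.p13 per-chromosome protein-coding totals down (or up) to
#' approximately `nGenes` genes while preserving the relative chromosome
#' sizes. Used for desk-scale synthetic datasets: the default synthetic
#' configuration uses `scaledChromosomeCounts(4360)`, under which chromosome
#' 21 keeps exactly 50 genes.
#'
#' @param nGenes target total number of genes (>= 24 so every chromosome
#'   retains at least one gene).
#' @return Named integer vector over chromosomes `1..22, X, Y`; the sum is
#'   close to (not necessarily exactly) `nGenes` because of rounding.
#' @examples
#' scaledChromosomeCounts(4360)[["21"]] # 50
#' @export
scaledChromosomeCounts <- function(nGenes) {
  stopifnot(is.numeric(nGenes), length(nGenes) == 1L, nGenes >= 24)
  ref <- referenceChromosomeCounts()
  counts <- as.integer(pmax(1L, round(ref * nGenes / sum(ref))))
  setNames(counts, names(ref))
}

#' Brain region codes used in the sample metadata vocabulary
#'
#' The eleven post-mortem brain structures sampled in the DS microarray
#' design: hippocampus (HIP), cerebellar cortex (CBC), and nine neocortical
#' areas (DFC, OFC, VFC, MFC, S1C, IPC, V1C, STC, ITC).
#'
#' @return Character vector of the eleven region codes.
#' @export
brainRegionCodes <- function() {
  c("HIP", "CBC", "DFC", "OFC", "VFC", "MFC", "S1C", "IPC", "V1C",
    "STC", "ITC")
}

#' Default age-rank labels
#'
#' The six categorical age strata spanning mid-gestation to the fifth decade
#' used to stratify the brain samples. Age-rank labels in metadata are
#' matched case-insensitively against this list (configurable in the
#' readers), since such labels vary slightly between sources.
#'
#' @return Character vector of six age-rank labels.
#' @export
defaultAgeRanks <- function() {
  c("16-22 wk gestation", "0-12 months", "2-10 y", "12-22 y",
    "30-39 y", "40-42 y")
}

## Normalize chromosome labels: strip any "chr" prefix, upper-case X/Y, map
## the numeric sex-chromosome codes 23 -> X and 24 -> Y. Invalid labels
## (e.g. MT, contigs) yield NA; callers decide whether that is an error.
normalizeChromosome <- function(x) {
  lab <- toupper(sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE))
  lab[lab == "23"] <- "X"
  lab[lab == "24"] <- "Y"
  lab[!lab %in% CHROMOSOMES] <- NA_character_
  lab
}
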