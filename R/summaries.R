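## Enrichment summaries, cross-stratum correlation and paired tests.

#' Per-chromosome over-expression summary
#'
#' Counts the over-expressed genes on each chromosome and expresses them as
#' a percentage of that chromosome's protein-coding total. The denominator
#' is either an externally supplied reference total per chromosome (e.g.
#' [referenceChromosomeCounts()], the GRCh38.p13 totals — the default
#' convention for published per-chromosome shares) or, when
#' `chromosomeTotals` is `NULL`, the number of annotated universe genes on
#' the chromosome. Genes without annotation are excluded.
#'
#' @param calls a [CallSet-class].
#' @param annotation data.frame with columns `gene_id`, `chromosome`
#'   (as from [readGeneAnnotation()] or [geneAnnotation()]).
#' @param universe character vector of all analyzed gene identifiers (the
#'   fixed gene universe the percentages refer to).
#' @param chromosomeTotals optional named vector of per-chromosome
#'   denominators.
#' @return data.frame with one row per chromosome present in the annotated
#'   universe: `chromosome`, `total_genes`, `overexpressed`, `percentage`
#'   (half-up, 2 decimals).
#' @examples
#' ann <- data.frame(gene_id = c("a", "b"), chromosome = c("21", "21"))
#' cs <- new("CallSet", stratum = "brain", threshold = 1.96,
#'           overexpressed = "a", underexpressed = character())
#' summarizeByChromosome(cs, ann, c("a", "b"),
#'                       chromosomeTotals = c("21" = 234))
#' @export
summarizeByChromosome <- function(calls, annotation, universe,
                                  chromosomeTotals = NULL) {
  stopifnot(is(calls, "CallSet"))
  if (!length(universe)) stop("empty gene universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann$chromosome <- normalizeChromosome(ann$chromosome)
  ann <- ann[!is.na(ann$chromosome), , drop = FALSE]
  chroms <- CHROMOSOMES[CHROMOSOMES %in% ann$chromosome]

  universeTotals <- table(factor(ann$chromosome, levels = chroms))
  over <- table(factor(
    ann$chromosome[ann$gene_id %in% calls@overexpressed],
    levels = chroms
  ))
  totals <- as.numeric(universeTotals)
  if (!is.null(chromosomeTotals)) {
    supplied <- chromosomeTotals[chroms]
    totals <- ifelse(is.na(supplied), totals, as.numeric(supplied))
  }
  data.frame(
    chromosome = chroms,
    total_genes = totals,
    overexpressed = as.integer(over),
    percentage = roundHalfUp(100 * as.integer(over) / totals, 2),
    stringsAsFactors = FALSE
  )
}

#' Per-structure over-expression summary
#'
#' One row per stratum (whole brain, brain structures, or age ranks) with
#' the over-expressed gene count and its percentage of the fixed gene
#' universe.
#'
#' @param callsByStratum named list of [CallSet-class] objects.
#' @param universeSize number of genes in the universe (constant across
#'   strata).
#' @return data.frame with columns `stratum`, `overexpressed`, `percentage`
#'   (half-up, 2 decimals).
#' @export
summarizeByStructure <- function(callsByStratum, universeSize) {
  stopifnot(universeSize >= 1)
  counts <- vapply(callsByStratum, function(cs) {
    stopifnot(is(cs, "CallSet"))
    length(cs@overexpressed)
  }, integer(1L))
  data.frame(
    stratum = names(callsByStratum) %||%
      vapply(callsByStratum, stratumLabel, ""),
    overexpressed = as.integer(counts),
    percentage = roundHalfUp(100 * counts / universeSize, 2),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Squared Pearson correlation between two Z-ratio profiles
#'
#' The agreement measure between strata: the square of the Pearson
#' correlation coefficient of the two Z-ratio vectors over their shared
#' genes (inner join on gene identifiers). This is the R-squared a linear
#' fit of one profile on the other reports.
#'
#' @param a,b [ZRatioVector-class] objects, or plain numeric vectors of
#'   equal length (already paired).
#' @param ... unused.
#' @return A single value in `[0, 1]`.
#' @details At least three shared genes are required, and both vectors must
#'   vary over the shared genes; otherwise the correlation is undefined and
#'   an error is raised.
#' @rdname zratioCorrelation
#' @export
setMethod("zratioCorrelation", signature("numeric", "numeric"),
  function(a, b, ...) {
    if (length(a) != length(b)) stop("paired vectors must have equal length")
    if (length(a) < 3L) stop("need at least 3 shared genes")
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("undefined correlation: zero variance in a Z-ratio vector")
    }
    stats::cor(a, b)^2
  }
)

#' @rdname zratioCorrelation
setMethod("zratioCorrelation", signature("ZRatioVector", "ZRatioVector"),
  function(a, b, ...) {
    shared <- intersect(a@geneIds, b@geneIds)
    if (length(shared) < 3L) stop("need at least 3 shared genes")
    zratioCorrelation(
      unname(zratio(a)[shared]),
      unname(zratio(b)[shared])
    )
  }
)

#' Pairwise R-squared matrix across strata
#'
#' Applies [zratioCorrelation()] to every pair of strata. The result is
#' symmetric with unit diagonal.
#'
#' @param vectors named list of two or more [ZRatioVector-class] objects.
#' @return Symmetric numeric matrix of squared correlations with stratum
#'   labels as dimnames.
#' @export
correlationMatrix <- function(vectors) {
  if (length(vectors) < 2L) stop("need at least two strata")
  labels <- names(vectors) %||% vapply(vectors, stratumLabel, "")
  n <- length(vectors)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r2 <- zratioCorrelation(vectors[[i]], vectors[[j]])
      m[i, j] <- r2
      m[j, i] <- r2
    }
  }
  m
}

#' Paired Wilcoxon signed-rank and t tests
#'
#' Runs both two-tailed paired location tests on a pair of matched value
#' lists (e.g. a structure's Z-ratio profile against the whole brain's).
#' For the signed-rank test, zero differences are dropped first (the
#' signed-rank convention); the exact null distribution is used for up to
#' 25 non-zero pairs and the normal approximation with continuity
#' correction beyond that. The paired t test uses all pairs.
#'
#' @param x,y equal-length numeric vectors of paired observations
#'   (length >= 5).
#' @param alpha significance level recorded alongside the results.
#' @return data.frame with one row per test: `test_name`
#'   (`wilcoxon_signed_rank`, `paired_t`), `statistic`, `p_value`, `n`
#'   (pairs used), `alpha`.
#' @export
pairedTests <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 5L) stop("need at least 5 pairs")
  d <- x - y
  nz <- d != 0
  if (!any(nz)) stop("degenerate test: all paired differences are zero")
  nW <- sum(nz)
  w <- stats::wilcox.test(x[nz], y[nz],
    paired = TRUE, alternative = "two.sided",
    exact = nW <= 25L, correct = TRUE
  )
  t <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  data.frame(
    test_name = c("wilcoxon_signed_rank", "paired_t"),
    statistic = c(unname(w$statistic), unname(t$statistic)),
    p_value = c(w$p.value, t$p.value),
    n = c(nW, length(x)),
    alpha = alpha,
    stringsAsFactors = FALSE
  )
}

#' Write a summary table or correlation matrix as TSV
#'
#' @param x data.frame (summaries) or matrix (correlations).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeSummaryTSV <- function(x, path) {
  if (is.matrix(x)) {
    tab <- data.frame(
      stratum = rownames(x),
      matrix(sprintf("%.12g", x), nrow = nrow(x)),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    colnames(tab) <- c("stratum", colnames(x))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
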