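## Readers and writers for the expression-matrix dialects, the sample
## metadata table and the gene -> chromosome annotation, plus the aligner
## that assembles a validated TrisomyExperiment from the three.

MISSING_TOKENS <- c("", "null", "NULL", "NA", "na", "NaN")

unquote <- function(x) gsub('^"|"$', "", x)

## Impute missing cells by the gene's row mean and report what was imputed.
## The Z-score standardization needs a complete per-array vector, so
## missingness is resolved at parse time rather than propagated.
imputeRowMeans <- function(values) {
  miss <- which(is.na(values), arr.ind = TRUE)
  if (nrow(miss)) {
    rm <- rowMeans(values, na.rm = TRUE)
    bad <- unique(miss[, 1L])[!is.finite(rm[unique(miss[, 1L])])]
    if (length(bad)) {
      stop("gene(s) with no observed values cannot be imputed: ",
           paste(rownames(values)[bad], collapse = ", "))
    }
    values[miss] <- rm[miss[, 1L]]
  }
  report <- data.frame(
    gene_id = rownames(values)[miss[, 1L]],
    sample_id = colnames(values)[miss[, 2L]],
    stringsAsFactors = FALSE
  )
  list(values = values, imputed = report)
}

parseNumericCells <- function(cells) {
  cells[cells %in% MISSING_TOKENS] <- NA_character_
  suppressWarnings(as.numeric(cells))
}

## Map one "key: value" characteristic onto the metadata fields. Free-text
## GEO characteristics vary, so matching is tolerant: unrecognized keys or
## values leave the field "unknown".
applyCharacteristic <- function(meta, key, value, ageRanks) {
  key <- tolower(trimws(key))
  value <- trimws(value)
  if (grepl("condition|disease|status|diagnosis|karyotype|group", key)) {
    if (grepl("down|trisomy|\\bds\\b", value, ignore.case = TRUE)) {
      meta$condition <- "DS"
    } else if (grepl("control|euploid|normal|\\bctl\\b|\\bcon\\b", value,
                     ignore.case = TRUE)) {
      meta$condition <- "control"
    }
  } else if (grepl("sex|gender", key)) {
    if (grepl("^f", value, ignore.case = TRUE)) meta$sex <- "female"
    if (grepl("^m", value, ignore.case = TRUE)) meta$sex <- "male"
  } else if (grepl("region|area|structure|tissue", key)) {
    code <- toupper(value)
    if (code %in% brainRegionCodes()) meta$region <- code
  } else if (grepl("age", key)) {
    hit <- match(tolower(value), tolower(ageRanks))
    if (!is.na(hit)) meta$age_rank <- ageRanks[[hit]]
  }
  meta
}

#' Read a GEO series-matrix text file
#'
#' Parses the series-matrix dialect: `!`-prefixed header lines followed by a
#' tab-separated expression table enclosed in `!series_matrix_table_begin` /
#' `!series_matrix_table_end`. Sample characteristics
#' (`!Sample_characteristics_ch1` lines of `key: value` pairs) are mapped
#' onto `condition`, `sex`, `age_rank` and `region` where recognizable;
#' unrecognized fields are left `"unknown"`. Missing expression cells
#' (`null`, `NA`, empty) are imputed by the gene's row mean and listed in
#' the parse report.
#'
#' @param path path to a series-matrix text file.
#' @param ageRanks age-rank vocabulary matched case-insensitively against
#'   the age characteristic (default [defaultAgeRanks()]).
#' @return A list with `values` (numeric gene x sample matrix), `metadata`
#'   (data.frame: `sample_id`, `condition`, `sex`, `age_rank`, `region`) and
#'   `report` (list with `nImputed` and the imputed `cells`).
#' @seealso [alignDataset()] to build a [TrisomyExperiment-class] from the
#'   parsed pieces; [writeSeriesMatrix()] for the inverse.
#' @export
readSeriesMatrix <- function(path, ageRanks = defaultAgeRanks()) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("not a series-matrix file: table delimiters missing or empty table")
  }

  tableFields <- strsplit(lines[(begin + 1L):(end - 1L)], "\t", fixed = TRUE)
  widths <- lengths(tableFields)
  if (length(unique(widths)) != 1L) {
    stop("ragged series-matrix table: rows have differing field counts")
  }
  header <- unquote(tableFields[[1L]])
  sampleIds <- header[-1L]
  body <- tableFields[-1L]
  geneIds <- unquote(vapply(body, `[[`, "", 1L))
  if (anyDuplicated(geneIds)) {
    stop("duplicate gene identifiers in series-matrix table")
  }
  cells <- unquote(unlist(lapply(body, `[`, -1L)))
  values <- matrix(parseNumericCells(cells),
    nrow = length(geneIds), ncol = length(sampleIds),
    byrow = TRUE, dimnames = list(geneIds, sampleIds)
  )
  imp <- imputeRowMeans(values)

  meta <- data.frame(
    sample_id = sampleIds,
    condition = "unknown", sex = "unknown",
    age_rank = "unknown", region = "unknown",
    stringsAsFactors = FALSE
  )
  charLines <- grep("^!Sample_characteristics_ch1", lines[seq_len(begin - 1L)],
    value = TRUE
  )
  for (line in charLines) {
    entries <- unquote(strsplit(line, "\t", fixed = TRUE)[[1L]][-1L])
    for (j in seq_along(entries)) {
      if (j > nrow(meta) || !nzchar(entries[[j]])) next
      kv <- strsplit(entries[[j]], ":", fixed = TRUE)[[1L]]
      if (length(kv) < 2L) next
      meta[j, ] <- applyCharacteristic(
        as.list(meta[j, ]), kv[[1L]],
        paste(kv[-1L], collapse = ":"), ageRanks
      )
    }
  }

  list(
    values = imp$values,
    metadata = meta,
    report = list(nImputed = nrow(imp$imputed), cells = imp$imputed)
  )
}

#' Write a series-matrix text file
#'
#' Emits the same dialect [readSeriesMatrix()] parses: characteristics
#' header lines for condition, sex, age rank and region, then the quoted
#' tab-separated expression table. Values are written with 12 significant
#' digits so a round trip recovers them well below 1e-9.
#'
#' @param values numeric gene x sample matrix with dimnames.
#' @param metadata data.frame with columns `sample_id`, `condition`, `sex`,
#'   `age_rank`, `region` covering the matrix columns.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeSeriesMatrix <- function(values, metadata, path) {
  stopifnot(is.matrix(values), !is.null(dimnames(values)))
  idx <- match(colnames(values), metadata$sample_id)
  if (anyNA(idx)) stop("metadata must cover every sample column")
  meta <- metadata[idx, , drop = FALSE]
  q <- function(x) paste0('"', x, '"')
  charLine <- function(key, vals) {
    paste(c("!Sample_characteristics_ch1", q(paste0(key, ": ", vals))),
      collapse = "\t"
    )
  }
  lines <- c(
    '!Series_title\t"synthetic trisomy-21 brain expression dataset"',
    paste(c("!Sample_geo_accession", q(colnames(values))), collapse = "\t"),
    charLine("condition", meta$condition),
    charLine("sex", meta$sex),
    charLine("age rank", meta$age_rank),
    charLine("brain region", meta$region),
    "!series_matrix_table_begin",
    paste(c(q("ID_REF"), q(colnames(values))), collapse = "\t"),
    vapply(seq_len(nrow(values)), function(i) {
      paste(c(q(rownames(values)[i]), sprintf("%.12g", values[i, ])),
        collapse = "\t"
      )
    }, ""),
    "!series_matrix_table_end"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a plain TSV expression matrix
#'
#' The TSV dialect has a header row (`gene_id` then sample identifiers) and
#' one row per gene. Missing cells are imputed by the gene's row mean, as in
#' [readSeriesMatrix()].
#'
#' @param path file path.
#' @return For the reader, a list with `values` and `report` as in
#'   [readSeriesMatrix()] (no metadata lives in this dialect).
#' @export
readExpressionTSV <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  geneIds <- tab[[1L]]
  if (anyDuplicated(geneIds)) stop("duplicate gene identifiers in matrix")
  values <- vapply(tab[-1L], parseNumericCells, numeric(length(geneIds)))
  values <- matrix(values,
    nrow = length(geneIds),
    dimnames = list(geneIds, colnames(tab)[-1L])
  )
  imp <- imputeRowMeans(values)
  list(
    values = imp$values,
    report = list(nImputed = nrow(imp$imputed), cells = imp$imputed)
  )
}

#' @rdname readExpressionTSV
#' @param values numeric gene x sample matrix with dimnames.
#' @export
writeExpressionTSV <- function(values, path) {
  stopifnot(is.matrix(values), !is.null(dimnames(values)))
  tab <- data.frame(
    gene_id = rownames(values),
    matrix(sprintf("%.12g", values), nrow = nrow(values)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(tab) <- c("gene_id", colnames(values))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata CSV
#'
#' Expects columns `sample_id` and `condition`; `sex`, `age_rank` and
#' `region` are filled with `"unknown"` when absent. Condition values are
#' normalized to `DS` / `control` with the same tolerant matching the
#' series-matrix parser uses.
#'
#' @param path CSV file path.
#' @return data.frame with columns `sample_id`, `condition`, `sex`,
#'   `age_rank`, `region`.
#' @export
readSampleMetadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% colnames(tab))) {
    stop("metadata must contain 'sample_id' and 'condition' columns")
  }
  for (col in c("sex", "age_rank", "region")) {
    if (!col %in% colnames(tab)) tab[[col]] <- "unknown"
  }
  cond <- rep("unknown", nrow(tab))
  cond[grepl("down|trisomy|\\bds\\b", tab$condition, ignore.case = TRUE)] <- "DS"
  cond[grepl("control|euploid|normal|\\bctl\\b|\\bcon\\b", tab$condition,
    ignore.case = TRUE
  )] <- "control"
  tab$condition <- cond
  tab[c("sample_id", "condition", "sex", "age_rank", "region")]
}

#' @rdname readSampleMetadata
#' @param metadata data.frame in the reader's layout.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene -> chromosome annotation TSV
#'
#' Two-column tab-separated table with a header; the first column is the
#' gene symbol, the second the chromosome label. Labels are normalized:
#' any `chr` prefix is stripped, `23`/`24` map to `X`/`Y`, case is folded.
#' A gene listed with two different chromosomes is an error, as is a label
#' outside `1..22, X, Y` (mitochondrial and patch contigs are unsupported).
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_id` and `chromosome` (one row per
#'   gene).
#' @export
readGeneAnnotation <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  if (ncol(tab) < 2L) stop("annotation must have two columns")
  ann <- data.frame(
    gene_id = trimws(tab[[1L]]),
    chromosome = normalizeChromosome(tab[[2L]]),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(ann$chromosome))
  if (length(bad)) {
    stop(sprintf(
      "unparseable chromosome label '%s' for gene '%s' (row %d)",
      tab[[2L]][bad[1L]], ann$gene_id[bad[1L]], bad[1L]
    ))
  }
  ann <- unique(ann)
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) {
    stop("gene(s) annotated to conflicting chromosomes: ",
         paste(unique(dup), collapse = ", "))
  }
  row.names(ann) <- NULL
  ann
}

#' @rdname readGeneAnnotation
#' @param annotation data.frame with columns `gene_id` and `chromosome`.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  write.table(annotation[c("gene_id", "chromosome")], path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Align an expression matrix with metadata and annotation
#'
#' Assembles a validated [TrisomyExperiment-class]. Samples without a usable
#' metadata record (no record at all, or condition not recognizably
#' `DS`/`control`) are dropped with a warning; genes without annotation are
#' retained in the gene universe but carry `NA` chromosome, excluding them
#' from chromosome summaries. Alignment counts are stored in
#' `metadata(x)$alignment`. Aligning an already-aligned experiment with its
#' own metadata/annotation is a no-op on the data.
#'
#' @param x numeric gene x sample matrix, or a [TrisomyExperiment-class]
#'   (in which case `metadata`/`annotation` default to its own).
#' @param metadata data.frame as returned by [readSampleMetadata()].
#' @param annotation optional data.frame as returned by
#'   [readGeneAnnotation()].
#' @return A [TrisomyExperiment-class].
#' @export
alignDataset <- function(x, metadata = NULL, annotation = NULL) {
  if (is(x, "TrisomyExperiment")) {
    metadata <- metadata %||% sampleMetadata(x)
    annotation <- annotation %||% geneAnnotation(x)
    x <- assay(x, "log2")
  }
  stopifnot(is.matrix(x), !is.null(dimnames(x)))
  if (is.null(metadata)) stop("sample metadata is required")
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata")
  }

  usable <- metadata[metadata$condition %in% c("DS", "control"), , drop = FALSE]
  keep <- colnames(x) %in% usable$sample_id
  if (!any(keep)) stop("no samples overlap between matrix and metadata")
  dropped <- colnames(x)[!keep]
  if (length(dropped)) {
    warning(sprintf(
      "dropping %d sample(s) without usable metadata: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  values <- x[, keep, drop = FALSE]
  meta <- usable[match(colnames(values), usable$sample_id), , drop = FALSE]

  chrom <- rep(NA_character_, nrow(values))
  if (!is.null(annotation)) {
    hit <- match(rownames(values), annotation$gene_id)
    chrom <- normalizeChromosome(annotation$chromosome[hit])
  }
  nUnannotated <- sum(is.na(chrom))

  se <- SummarizedExperiment(
    assays = list(log2 = values),
    colData = DataFrame(
      condition = factor(meta$condition, levels = c("control", "DS")),
      sex = meta$sex %||% "unknown",
      age_rank = meta$age_rank %||% "unknown",
      region = meta$region %||% "unknown",
      row.names = colnames(values)
    ),
    rowData = DataFrame(chromosome = chrom, row.names = rownames(values))
  )
  te <- new("TrisomyExperiment", se)
  metadata(te)$alignment <- list(
    nDroppedSamples = length(dropped),
    droppedSamples = dropped,
    nUnannotatedGenes = nUnannotated
  )
  validObject(te)
  te
}
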