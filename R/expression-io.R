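#' Build a SwitchExperiment from a matrix and group labels
#'
#' @param values numeric genes x samples matrix with unique dimnames,
#'   log2-scale intensities.
#' @param groups character or factor of "control"/"disease", either named by
#'   sample id or in column order of `values`.
#' @return a validated [SwitchExperiment-class].
#' @export
switchExperiment <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || is.null(rownames(values)))
    stop("values must carry gene rownames and sample colnames")
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  } else if (length(groups) != ncol(values)) {
    stop("groups must be named or have one entry per sample")
  }
  g <- factor(as.character(groups), levels = c("control", "disease"))
  if (anyNA(g))
    stop("group labels must be 'control' or 'disease'")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = g, row.names = colnames(values)))
  new("SwitchExperiment", se)
}

#' Read a GEO series-matrix file
#'
#' Parses the tab-delimited data block between the standard
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers of a
#' GEO series-matrix file into a [SwitchExperiment-class]. Values are taken
#' as log2 scale unless the file looks linear — any value above 50 — in
#' which case `log2(x + 1)` is applied and a message is emitted; set `scale`
#' to override the heuristic.
#'
#' @param path path to a series-matrix text file.
#' @param groupAssignment named character vector (or two-column data.frame
#'   `sample`, `group`) mapping every sample id in the file to "control" or
#'   "disease".
#' @param scale one of "auto", "log2" (leave values as read), "linear"
#'   (always apply `log2(x + 1)`).
#' @return a [SwitchExperiment-class] of all probes x samples.
#' @export
readSeriesMatrix <- function(path, groupAssignment,
                             scale = c("auto", "log2", "linear")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("no series-matrix table markers found in ", path)
  block <- lines[(begin + 1L):(end - 1L)]
  fields <- strsplit(block, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[1L]))
    stop("ragged series-matrix row at line ",
         begin + which(widths != widths[1L])[1L])
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(fields[[1L]])
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample ids in series-matrix header (line ", begin + 1L,
         ")")
  probeIds <- vapply(fields[-1L], function(f) unquote(f[1L]), character(1L))
  values <- matrix(NA_real_, nrow = length(probeIds),
                   ncol = length(sampleIds),
                   dimnames = list(probeIds, sampleIds))
  for (i in seq_along(probeIds)) {
    v <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    if (anyNA(v))
      stop("non-numeric expression value at line ", begin + 1L + i)
    values[i, ] <- v
  }
  linear <- switch(scale, auto = any(values > 50), log2 = FALSE,
                   linear = TRUE)
  if (linear) {
    message("values detected/declared as linear scale; applying log2(x + 1)")
    values <- log2(values + 1)
  }
  if (is.data.frame(groupAssignment))
    groupAssignment <- setNames(as.character(groupAssignment$group),
                                groupAssignment$sample)
  missing <- setdiff(sampleIds, names(groupAssignment))
  if (length(missing))
    stop("sample(s) in file absent from group assignment: ",
         paste(missing, collapse = ", "))
  switchExperiment(values, groupAssignment)
}

#' Read / write an expression TSV plus sample-group TSV
#'
#' The matrix TSV has gene ids in the first column (`gene`) and one column
#' per sample; the groups TSV has columns `sample` and `group`.
#'
#' @param matrixPath path to the genes x samples TSV.
#' @param groupsPath path to the two-column sample/group TSV.
#' @return `readExpression`: a [SwitchExperiment-class].
#' @export
readExpression <- function(matrixPath, groupsPath) {
  tab <- utils::read.delim(matrixPath, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(tab)[1L] != "gene")
    stop("first column of ", matrixPath, " must be named 'gene'")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$gene
  groups <- utils::read.delim(groupsPath, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(groups)))
    stop("groups TSV needs columns 'sample' and 'group'")
  switchExperiment(values, setNames(groups$group, groups$sample))
}

#' @rdname readExpression
#' @param x a [SwitchExperiment-class].
#' @return `writeExpression`: invisibly, `matrixPath`.
#' @export
writeExpression <- function(x, matrixPath, groupsPath = NULL) {
  stopifnot(is(x, "SwitchExperiment"))
  m <- SummarizedExperiment::assay(x)
  tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(groupsPath))
    utils::write.table(
      data.frame(sample = colnames(x),
                 group = as.character(sampleGroups(x))),
      groupsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

#' Collapse probes to gene symbols
#'
#' Among probes sharing a symbol the probe with the highest mean expression
#' is kept and its row is relabelled with the symbol (the common microarray
#' summarisation convention). Unmapped probes are kept under their probe id
#' when `keepUnmapped = TRUE`, otherwise dropped.
#'
#' @param x a [SwitchExperiment-class] of probes x samples.
#' @param probeMap named character vector, probe id -> gene symbol
#'   (many-to-one allowed; a probe may map to at most one symbol).
#' @param keepUnmapped keep probes absent from the map under their probe id?
#' @return a [SwitchExperiment-class] with one row per symbol (plus any
#'   retained unmapped probes).
#' @export
collapseProbes <- function(x, probeMap, keepUnmapped = FALSE) {
  stopifnot(is(x, "SwitchExperiment"))
  if (is.null(names(probeMap)))
    stop("probeMap must be named by probe id")
  if (anyDuplicated(names(probeMap)))
    stop("a probe maps to more than one symbol")
  m <- SummarizedExperiment::assay(x)
  mapped <- intersect(rownames(m), names(probeMap))
  if (!length(mapped))
    stop("no probe in the matrix is covered by the probe map")
  means <- rowMeans(m[mapped, , drop = FALSE])
  symbols <- probeMap[mapped]
  keep <- vapply(split(mapped, symbols),
                 function(p) p[which.max(means[p])], character(1L))
  out <- m[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  if (keepUnmapped) {
    unmapped <- setdiff(rownames(m), names(probeMap))
    out <- rbind(out, m[unmapped, , drop = FALSE])
  }
  switchExperiment(out, sampleGroups(x))
}

#' Drop genes that are not or only slightly expressed
#'
#' Removes genes whose maximum expression across samples lies below the
#' `floorPercentile`-th percentile of all matrix values. Gene order is
#' preserved; the number removed is reported.
#'
#' @param x a [SwitchExperiment-class].
#' @param floorPercentile percentile of all values used as the floor,
#'   in \[0, 100); default 20.
#' @return the filtered [SwitchExperiment-class].
#' @export
filterLowExpression <- function(x, floorPercentile = 20) {
  stopifnot(is(x, "SwitchExperiment"))
  if (floorPercentile < 0 || floorPercentile >= 100)
    stop("floorPercentile must lie in [0, 100)")
  m <- SummarizedExperiment::assay(x)
  floor <- stats::quantile(m, floorPercentile / 100, names = FALSE)
  keep <- apply(m, 1L, max) >= floor
  if (!any(keep))
    stop("low-expression filter removed every gene; lower floorPercentile")
  message(sum(!keep), " gene(s) removed by low-expression filter (floor ",
          format(floor, digits = 4), ")")
  x[keep, ]
}
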