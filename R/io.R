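## Delimited-text input/output for data matrices, edge labels and results.

#' Read a data matrix from delimited text
#'
#' First row holds variable names, one sample per subsequent row; the
#' delimiter is inferred from the file extension (\code{.csv} comma,
#' otherwise tab).
#'
#' @param path file path.
#' @param sep optional delimiter override.
#' @return numeric matrix with column names.
#' @export
readDataMatrix <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("data matrix must be numeric")
  m
}

#' Read labelled causal edges from delimited text
#'
#' Expects columns \code{source}, \code{target}, \code{label} (tab-separated
#' by default); labels in \{-1, +1\}.
#'
#' @param path file path.
#' @param sep delimiter (default tab).
#' @return data.frame suitable for [assembleLabels()].
#' @export
readEdgeLabels <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("source", "target", "label") %in% names(df)))
    stop("label file must have columns source, target, label")
  df
}

#' Write per-pair scores as delimited text
#'
#' Writes the score table of an [MRCLResult-class] (source, target, score,
#' predicted label, labelled flag) as tab-separated text.
#'
#' @param result [MRCLResult-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdgeScores <- function(result, path) {
  stopifnot(is(result, "MRCLResult"))
  utils::write.table(edgeScores(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an adjacency matrix as CSV
#'
#' @param graph a [CausalGraph-class] (or binary matrix).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAdjacency <- function(graph, path) {
  A <- if (is(graph, "CausalGraph")) adjacency(graph) else as.matrix(graph)
  utils::write.csv(A, path, quote = FALSE)
  invisible(path)
}
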