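#' Binary cell-state catalog from an equilibrium atlas
#'
#' Thresholds each stable (optionally also transition) state into an
#' on/off pattern over the network genes. The catalog is the reference
#' against which single cells are classified: a cell whose binarized
#' core-gene vector equals a catalog pattern is assigned that state.
#'
#' @param atlas an `equilibrium_atlas` with at least one stable state.
#' @param threshold binarization threshold (default 0.5; concentrations
#'   are normalized to \[0, 1\]).
#' @param annotations optional named character vector of descriptions,
#'   keyed by atlas label.
#' @param include_transition also catalog transition states.
#' @param transition_threshold binarization threshold applied to
#'   transition states (defaults to `threshold`). Saddle phenotypes
#'   express markers at intermediate levels, so a lower detection level
#'   (e.g. 0.2) keeps their patterns distinct from the attractors they
#'   neighbour.
#' @return object of class `state_catalog`: `patterns` (0/1 matrix, one
#'   row per state, columns = genes), `labels`, `annotations`, `genes`,
#'   `threshold`. Distinct states collapsing to one pattern are both kept
#'   with a warning.
#' @export
catalog_from_atlas <- function(atlas, threshold = 0.5, annotations = NULL,
                               include_transition = FALSE,
                               transition_threshold = threshold) {
  keep <- vapply(atlas$states, function(s)
    s$class == "stable" || (include_transition && s$class == "transition"),
    NA)
  states <- atlas$states[keep]
  if (length(states) == 0L) stop("atlas has no stable states")
  patterns <- do.call(rbind, lapply(states, function(s)
    .binarize(s$x, if (s$class == "transition") transition_threshold
                   else threshold)))
  colnames(patterns) <- atlas$genes
  labels <- vapply(states, `[[`, "", "label")
  rownames(patterns) <- labels
  if (anyDuplicated(apply(patterns, 1, paste, collapse = ""))) {
    warning("distinct states collapse to the same binary pattern; ",
            "both kept")
  }
  ann <- if (is.null(annotations)) rep(NA_character_, length(labels)) else
    unname(annotations[labels])
  structure(list(patterns = patterns, labels = labels, annotations = ann,
                 genes = atlas$genes, threshold = threshold),
            class = "state_catalog")
}

#' @export
print.state_catalog <- function(x, ...) {
  cat("state_catalog:", nrow(x$patterns), "patterns over",
      length(x$genes), "genes\n")
  df <- data.frame(label = x$labels,
                   pattern = apply(x$patterns, 1, paste, collapse = ""),
                   annotation = ifelse(is.na(x$annotations), "",
                                       x$annotations))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pseudocount transform of an expression matrix
#'
#' `Exp = Count + 1` for count data and `Exp = TPM + 1` for
#' TPM-normalized data; an optional explicit `log2` step is applied on
#' top. The transform used is recorded in the `"transform"` attribute.
#'
#' @param matrix genes-by-cells numeric matrix, nonnegative.
#' @param mode `"count"` or `"tpm"` (recorded, the arithmetic is the
#'   same pseudocount).
#' @param log2 also apply `log2` after the pseudocount.
#' @return transformed matrix.
#' @export
transform_expression <- function(matrix, mode = c("count", "tpm"),
                                 log2 = FALSE) {
  mode <- match.arg(mode)
  if (any(matrix < 0)) stop("negative expression values")
  out <- matrix + 1
  if (log2) out <- base::log2(out)
  attr(out, "transform") <- paste0(mode, "+1", if (log2) ",log2")
  out
}

# Resolve the core network genes among matrix rows, honouring an optional
# gene_map (network gene -> matrix row name).
.resolve_genes <- function(matrix, genes, gene_map = NULL) {
  rn <- rownames(matrix)
  if (is.null(rn)) stop("expression matrix has no gene (row) names")
  nm <- if (is.null(gene_map)) stats::setNames(genes, genes) else {
    full <- stats::setNames(genes, genes)
    full[names(gene_map)] <- gene_map
    full
  }
  idx <- match(unname(nm[genes]), rn)
  if (anyNA(idx)) {
    stop("core gene(s) not found in matrix and no mapping supplied: ",
         paste(genes[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Assign cells to catalog states by exact pattern match
#'
#' Binarizes every cell's core-gene vector and compares it for exact
#' equality with the catalog patterns; cells matching no pattern are
#' labelled `"unmatched"`. The default rule calls a gene "on" when its
#' value is at least `on_threshold` (default 1, i.e. any detected count);
#' the quantile rule instead thresholds each gene at its own expression
#' quantile across cells.
#'
#' @param matrix genes-by-cells expression matrix (raw counts or TPM).
#' @param catalog a `state_catalog`.
#' @param rule `"threshold"` (default) or `"quantile"`.
#' @param on_threshold detection threshold for the threshold rule.
#' @param q quantile for the quantile rule.
#' @param gene_map optional named character vector mapping network gene
#'   names to matrix row names.
#' @return object of class `state_assignment`: `assignment` (data frame
#'   of cell, label and binarized pattern) and `summary` (cell counts per
#'   catalog state plus `"unmatched"`).
#' @export
assign_cells <- function(matrix, catalog, rule = c("threshold", "quantile"),
                         on_threshold = 1, q = 0.5, gene_map = NULL) {
  stopifnot(inherits(catalog, "state_catalog"))
  rule <- match.arg(rule)
  idx <- .resolve_genes(matrix, catalog$genes, gene_map)
  core <- matrix[idx, , drop = FALSE]
  bits <- switch(rule,
    threshold = core >= on_threshold,
    quantile = core > apply(core, 1, stats::quantile, probs = q))
  bits <- bits * 1L
  key <- apply(bits, 2, paste, collapse = "")
  pat_key <- apply(catalog$patterns, 1, paste, collapse = "")
  lab <- catalog$labels[match(key, pat_key)]
  lab[is.na(lab)] <- "unmatched"
  cells <- colnames(matrix) %||% as.character(seq_len(ncol(matrix)))
  summary <- table(factor(lab, levels = c(catalog$labels, "unmatched")))
  structure(list(assignment = data.frame(cell = cells, label = lab,
                                         pattern = key),
                 summary = summary,
                 rule = rule, on_threshold = on_threshold),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat("state_assignment:", nrow(x$assignment), "cells\n")
  print(x$summary)
  invisible(x)
}

#' Hierarchical clustering of cells by correlation distance
#'
#' Average-linkage hierarchical clustering on `1 - Pearson correlation`
#' between cell expression profiles, cut into `k` groups. Cells with a
#' constant profile have undefined correlation; their distances are set
#' to zero (maximal similarity) with a warning.
#'
#' @param matrix genes-by-cells expression matrix.
#' @param k number of groups.
#' @return integer vector of group labels, named by cell.
#' @export
correlation_cluster <- function(matrix, k) {
  stopifnot(k >= 1, ncol(matrix) >= k)
  if (k == 1L) {
    return(stats::setNames(rep(1L, ncol(matrix)),
                           colnames(matrix) %||% seq_len(ncol(matrix))))
  }
  cc <- suppressWarnings(stats::cor(matrix))
  if (anyNA(cc)) {
    warning("constant cell profile(s): undefined correlations treated as ",
            "zero distance")
    cc[is.na(cc)] <- 1
  }
  d <- stats::as.dist(1 - cc)
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Read a genes-by-cells expression matrix
#'
#' `read_expression_tsv()` reads a TSV with gene names in the first
#' column and one column per cell. `read_expression_mtx()` reads a
#' MatrixMarket triplet file plus plain-text gene and barcode lists (one
#' name per line), the common sparse export convention.
#'
#' @param path TSV file path.
#' @return a dense numeric matrix with gene row names and cell column
#'   names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @param mtx MatrixMarket file path.
#' @param genes_file,barcodes_file one-name-per-line text files for rows
#'   and columns.
#' @rdname read_expression_tsv
#' @export
read_expression_mtx <- function(mtx, genes_file, barcodes_file) {
  m <- as.matrix(Matrix::readMM(mtx))
  rownames(m) <- readLines(genes_file)
  colnames(m) <- readLines(barcodes_file)
  m
}

#' Write an expression matrix as TSV
#' @param matrix genes-by-cells matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
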