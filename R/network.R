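#' Build a signed regulatory network from an edge table
#'
#' A core endogenous network is a small, closed set of master transcription
#' factors together with their activation and inhibition relationships. The
#' network is represented by an ordered gene list plus, for every target
#' gene, the set of its activators and the set of its inhibitors; these index
#' sets drive both the Hill-function ODE model ([hill_rhs()]) and the
#' dominant-inhibition Boolean model ([boolean_weights()]).
#'
#' @param edges a data frame (or anything coercible) with columns `source`,
#'   `target` and `sign`. Accepted sign tokens: `+1`, `1`, `-1` (numeric or
#'   character) and the words `activation` / `inhibition`. Self-edges are
#'   allowed (self-activation loops are common in developmental networks).
#' @param genes optional character vector fixing the gene order. Defaults to
#'   first-appearance order over the `source`/`target` columns. Every gene
#'   named in the table must be listed.
#' @return an object of class `gene_network`: a list with elements `genes`
#'   (ordered character vector), `activators` and `inhibitors` (named lists
#'   of regulator names per target), and the 0/1 incidence matrices
#'   `act_mat`, `inh_mat` (rows = targets, columns = regulators).
#' @examples
#' net <- pancreas_network()
#' net
#' sum(net$act_mat)  # 12 activations
#' sum(net$inh_mat)  # 10 inhibitions
#' @seealso [pancreas_network()], [read_network_tsv()], [network_to_json()]
#' @export
load_network <- function(edges, genes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) stop("no edges")
  need <- c("source", "target", "sign")
  if (!all(need %in% names(edges))) {
    stop("edge table needs columns: ", paste(need, collapse = ", "))
  }
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  if (any(!nzchar(src)) || any(!nzchar(tgt)) || anyNA(src) || anyNA(tgt)) {
    stop("source and target must be non-empty gene names")
  }
  sgn <- .parse_sign(edges$sign)

  key <- paste(src, tgt, sgn, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate edge in row ", d, ": ", src[d],
         ifelse(sgn[d] > 0, " -> ", " -| "), tgt[d])
  }

  seen <- unique(c(rbind(src, tgt)))  # first-appearance order, row-wise
  if (is.null(genes)) {
    genes <- seen
  } else {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) stop("duplicated names in 'genes'")
    missing <- setdiff(seen, genes)
    if (length(missing)) {
      stop("genes in table but not in 'genes': ", paste(missing, collapse = ", "))
    }
  }

  G <- length(genes)
  act_mat <- matrix(0, G, G, dimnames = list(genes, genes))
  inh_mat <- matrix(0, G, G, dimnames = list(genes, genes))
  for (k in seq_along(src)) {
    if (sgn[k] > 0) act_mat[tgt[k], src[k]] <- 1 else inh_mat[tgt[k], src[k]] <- 1
  }
  activators <- lapply(genes, function(g) genes[act_mat[g, ] > 0])
  inhibitors <- lapply(genes, function(g) genes[inh_mat[g, ] > 0])
  names(activators) <- names(inhibitors) <- genes

  structure(
    list(genes = genes, activators = activators, inhibitors = inhibitors,
         act_mat = act_mat, inh_mat = inh_mat),
    class = "gene_network")
}

.parse_sign <- function(sign) {
  tok <- trimws(tolower(as.character(sign)))
  out <- integer(length(tok))
  pos <- tok %in% c("+1", "1", "activation")
  neg <- tok %in% c("-1", "−1", "inhibition")
  if (any(!pos & !neg)) {
    bad <- which(!pos & !neg)[1L]
    stop("unknown sign token '", sign[bad], "' in row ", bad)
  }
  out[pos] <- 1L
  out[neg] <- -1L
  out
}

#' Read a signed regulation table from a 3-column TSV file
#'
#' Expected header: `source  target  sign` (tab-separated); see
#' [load_network()] for the accepted sign tokens.
#'
#' @inheritParams load_network
#' @param path path to the TSV file.
#' @return a `gene_network`.
#' @export
read_network_tsv <- function(path, genes = NULL) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  load_network(edges, genes = genes)
}

#' The core endogenous network of pancreatic lineage decisions
#'
#' The canonical eight-factor network (PDX1, PTF1A, NKX6.1, SOX9, HES1,
#' NGN3, ARX, PAX4) wiring the tip/trunk, acinar/ductal and endocrine
#' alpha/beta lineage decisions of the embryonic pancreas: 12 activation and
#' 10 inhibition relationships curated from genetic experiments, including
#' self-activation loops of PDX1, PTF1A, NKX6.1, SOX9 and NGN3. Two variant
#' networks add individually debated regulations: the activation of PDX1 by
#' PTF1A, and the inhibition of ARX by NKX6.1.
#'
#' @param variant `"core"` (default) or one of the two single-edge variants
#'   `"plus_ptf1a_pdx1"`, `"plus_nkx61_arx"`.
#' @return a `gene_network` with the canonical gene order.
#' @examples
#' net <- pancreas_network()
#' net$genes
#' @export
pancreas_network <- function(variant = c("core", "plus_ptf1a_pdx1",
                                         "plus_nkx61_arx")) {
  variant <- match.arg(variant)
  file <- paste0("pancreas_", if (variant == "core") "core" else variant, ".tsv")
  path <- system.file("extdata", file, package = "endonet", mustWork = TRUE)
  read_network_tsv(path, genes = pancreas_genes())
}

#' Canonical gene order of the pancreas core network
#' @return character vector of the eight gene symbols.
#' @export
pancreas_genes <- function() {
  c("PDX1", "PTF1A", "NKX6.1", "SOX9", "HES1", "NGN3", "ARX", "PAX4")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$genes), "genes,",
      sum(x$act_mat), "activations,", sum(x$inh_mat), "inhibitions\n")
  cat("genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a network as JSON
#'
#' Round-trips the gene order and the per-gene activator/inhibitor sets, so
#' a network used in an analysis can be archived alongside its results.
#'
#' @param network a `gene_network`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `network_to_json()`: the JSON string (invisibly when written to
#'   file); `network_from_json()`: a `gene_network`.
#' @export
network_to_json <- function(network, path = NULL) {
  stopifnot(inherits(network, "gene_network"))
  js <- jsonlite::toJSON(
    list(genes = network$genes,
         activators = network$activators,
         inhibitors = network$inhibitors),
    auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @param json a JSON string or file path produced by [network_to_json()].
#' @rdname network_to_json
#' @export
network_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  genes <- as.character(obj$genes)
  edges <- list()
  for (g in genes) {
    for (a in obj$activators[[g]]) {
      edges[[length(edges) + 1L]] <- data.frame(source = a, target = g, sign = "+1")
    }
    for (i in obj$inhibitors[[g]]) {
      edges[[length(edges) + 1L]] <- data.frame(source = i, target = g, sign = "-1")
    }
  }
  load_network(do.call(rbind, edges), genes = genes)
}
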