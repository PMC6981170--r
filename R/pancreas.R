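#' Annotate the pancreas equilibrium atlas with cell-type names
#'
#' Maps the computed equilibria of the canonical eight-factor pancreas
#' network onto developmental cell identities using marker rules. Stable
#' states are identified by their exact binarized on/off pattern: the
#' well-characterized acinar/tip, trunk, ductal, immature alpha (Ialpha,
#' NGN3+ARX on) and immature beta (Ibeta, PDX1+NKX6.1+NGN3+PAX4 on) cells;
#' the predicted progenitors TiP and TrP (early progenitor markers PDX1,
#' SOX9, HES1 with PTF1A or NKX6.1 exclusively on), AciP (PTF1A with
#' SOX9/HES1), AciP2 (PDX1 with PTF1A); and the two unclassified states
#' (NKX6.1 only; all markers off). The progenitor saddles carry
#' intermediate expression levels, so they are identified by value-range
#' rules instead: MP (multipotent progenitor) has all five early TFs
#' (PDX1, PTF1A, NKX6.1, SOX9, HES1) appreciably expressed and the
#' endocrine TFs off; EEP (early endocrine progenitor) is TrP-like with
#' NGN3 rising but below half-maximum; LEP (later endocrine progenitor)
#' has high NGN3 with the other lineage TFs below half-maximum.
#'
#' @param atlas an `equilibrium_atlas` of the pancreas network (canonical
#'   gene order).
#' @param threshold binarization threshold for the stable patterns.
#' @return named character vector mapping cell-type names (`"MP"`,
#'   `"TrP"`, ..., `"none"`) to atlas labels; unmatched cell types are
#'   dropped with a warning.
#' @export
annotate_pancreas_atlas <- function(atlas, threshold = 0.5) {
  stopifnot(identical(atlas$genes, pancreas_genes()))
  stable_patterns <- c(
    TiP        = "11011000",
    AciP2      = "11000000",
    TrP        = "10111000",
    Ibeta      = "10100101",
    AciP       = "01011000",
    acinar     = "01000000",
    trunk      = "00111000",
    NKX61_only = "00100000",
    ductal     = "00011000",
    Ialpha     = "00000110",
    none       = "00000000")

  map <- character(0)
  for (s in atlas$states) {
    x <- unname(s$x)
    if (s$class == "stable") {
      key <- paste(.binarize(x, threshold), collapse = "")
      hit <- names(stable_patterns)[stable_patterns == key]
      if (length(hit) == 1L && !hit %in% names(map)) map[hit] <- s$label
    } else if (s$class == "transition") {
      early <- x[1:5]; endo <- x[6:8]
      if (all(early > 0.2) && all(endo < 0.2) && !"MP" %in% names(map)) {
        map["MP"] <- s$label
      } else if (x[1] > 0.6 && x[3] > 0.5 && x[2] < 0.2 && x[4] > 0.5 &&
                 x[6] > 0.1 && x[6] < 0.5 && !"EEP" %in% names(map)) {
        map["EEP"] <- s$label
      } else if (x[6] > 0.7 && x[1] < 0.5 && x[3] < 0.5 && x[2] < 0.2 &&
                 !"LEP" %in% names(map)) {
        map["LEP"] <- s$label
      }
    }
  }
  expected <- c(names(stable_patterns), "MP", "EEP", "LEP")
  miss <- setdiff(expected, names(map))
  if (length(miss)) {
    warning("unannotated cell types: ", paste(miss, collapse = ", "))
  }
  map
}

#' Textual annotations for the pancreas state catalog
#'
#' One-line descriptions of the predicted cell identities, keyed by the
#' cell-type names of [annotate_pancreas_atlas()].
#'
#' @return named character vector.
#' @export
pancreas_annotations <- function() {
  c(TiP = "tip progenitor: early progenitor markers with PTF1A exclusively on",
    AciP2 = "acinar progenitor 2: PDX1 and PTF1A co-expressed",
    TrP = "trunk progenitor: early progenitor markers with NKX6.1 exclusively on",
    Ibeta = "immature beta cell: PDX1, NKX6.1, NGN3 and PAX4 on",
    AciP = "acinar progenitor (centroacinar-like): PTF1A with SOX9 and HES1",
    acinar = "acinar / tip cell: PTF1A on",
    trunk = "trunk cell: NKX6.1 with SOX9 and HES1",
    NKX61_only = "unclassified: expresses NKX6.1 only",
    ductal = "ductal cell: SOX9 and HES1 on",
    Ialpha = "immature alpha cell: NGN3 and ARX on",
    none = "unclassified: expresses none of the major cell markers",
    MP = "multipotent progenitor: all five early TFs expressed (saddle)",
    EEP = "early endocrine progenitor: trunk-like with low NGN3 (saddle)",
    LEP = "later endocrine progenitor: high NGN3 (saddle)")
}
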