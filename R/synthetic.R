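#' Specification of the synthetic single-cell generator
#'
#' Emulates the statistical structure of scRNA-seq counts over a
#' predicted cell-state catalog: each cell is drawn at one catalog
#' pattern, with "on" core genes sampled from a negative binomial at
#' `on_mean` (subject to dropout) and "off" core genes (plus background
#' filler genes) from a negative binomial at `off_mean`. The generator
#' reproduces the on/off block structure the catalog predicts while
#' adding overdispersed count noise and zero-inflation; it makes no
#' attempt to mimic real library-size or batch structure.
#'
#' @param catalog a `state_catalog`.
#' @param cells_per_state integer (recycled over states) or named vector
#'   keyed by catalog label.
#' @param on_mean,off_mean negative-binomial means of on/off genes
#'   (defaults 50 and 0.5).
#' @param dispersion NB size parameter (default 2; `Inf` gives the
#'   deterministic noise-free limit in which every gene takes its mean,
#'   rounded).
#' @param dropout_prob probability that an "on" gene reads zero
#'   (default 0.1).
#' @param n_background_genes non-core filler genes (default 50).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(catalog, cells_per_state = 200L,
                           on_mean = 50, off_mean = 0.5, dispersion = 2,
                           dropout_prob = 0.1, n_background_genes = 50L,
                           seed = 1L) {
  stopifnot(inherits(catalog, "state_catalog"),
            on_mean > 0, off_mean >= 0, on_mean > off_mean,
            dispersion > 0, dropout_prob >= 0, dropout_prob <= 1,
            n_background_genes >= 0)
  if (!is.null(names(cells_per_state))) {
    bad <- setdiff(names(cells_per_state), catalog$labels)
    if (length(bad)) {
      stop("cells_per_state references unknown label(s): ",
           paste(bad, collapse = ", "))
    }
    n <- stats::setNames(rep(0L, length(catalog$labels)), catalog$labels)
    n[names(cells_per_state)] <- as.integer(cells_per_state)
  } else {
    n <- stats::setNames(rep(as.integer(cells_per_state),
                             length(catalog$labels)), catalog$labels)
  }
  structure(list(catalog = catalog, cells_per_state = n,
                 on_mean = on_mean, off_mean = off_mean,
                 dispersion = dispersion, dropout_prob = dropout_prob,
                 n_background_genes = as.integer(n_background_genes),
                 seed = seed),
            class = "generator_spec")
}

.nb_draw <- function(n, mu, size) {
  if (n == 0L) return(integer(0))
  if (mu == 0) return(rep(0L, n))
  if (is.infinite(size)) return(rep(as.integer(round(mu)), n))
  as.integer(stats::rnbinom(n, mu = mu, size = size))
}

#' Generate a synthetic expression matrix with known state labels
#'
#' Draws `cells_per_state` cells at every catalog pattern according to
#' the generator model of [generator_spec()].
#'
#' @param spec a `generator_spec`.
#' @return list with `matrix` (integer genes-by-cells count matrix; core
#'   genes first, then background genes `BG_01`, ...) and `labels` (true
#'   catalog label per cell).
#' @examples
#' \donttest{
#' atlas <- find_equilibria(pancreas_network())
#' cat <- catalog_from_atlas(atlas)
#' sim <- generate_cells(generator_spec(cat, cells_per_state = 20, seed = 1))
#' dim(sim$matrix)
#' }
#' @export
generate_cells <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  cat <- spec$catalog
  genes <- cat$genes
  n_bg <- spec$n_background_genes
  bg_names <- if (n_bg > 0L) sprintf("BG_%02d", seq_len(n_bg)) else character(0)
  labels <- rep(cat$labels, times = spec$cells_per_state)
  n_cells <- length(labels)
  .with_seed(spec$seed, {
    M <- matrix(0L, nrow = length(genes) + n_bg, ncol = n_cells,
                dimnames = list(c(genes, bg_names),
                                sprintf("cell_%04d", seq_len(n_cells))))
    for (ci in seq_len(n_cells)) {
      pat <- cat$patterns[match(labels[ci], cat$labels), ]
      on <- pat == 1L
      v <- integer(length(genes))
      v[on] <- .nb_draw(sum(on), spec$on_mean, spec$dispersion)
      v[!on] <- .nb_draw(sum(!on), spec$off_mean, spec$dispersion)
      if (spec$dropout_prob > 0 && any(on)) {
        drop <- stats::runif(sum(on)) < spec$dropout_prob
        v[which(on)[drop]] <- 0L
      }
      M[seq_along(genes), ci] <- v
      if (n_bg > 0L) {
        M[length(genes) + seq_len(n_bg), ci] <-
          .nb_draw(n_bg, spec$off_mean, spec$dispersion)
      }
    }
    list(matrix = M, labels = labels)
  })
}
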