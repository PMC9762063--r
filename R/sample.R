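# Ancestral (forward) sampling from a parameterized CG network.

#' Sample records from a conditional-Gaussian network
#'
#' Draws `n` records by ancestral sampling in a topological order: each
#' discrete node from its CPT row given the sampled parent configuration,
#' each continuous node from its per-configuration linear-Gaussian local
#' model.
#'
#' @param structure a `pabn_network`.
#' @param params matching `pabn_params`.
#' @param n number of records (0 gives an empty, correctly-typed table).
#' @param seed integer seed.
#' @return a data.frame with one column per node.
#' @export
sample_network <- function(structure, params, n, seed = 0L) {
  abort_if(!all(structure$nodes %in% names(params)), "params lack some nodes")
  set.seed(derive_seed(seed, 0L))
  ord <- topo_sort(structure)
  out <- vector("list", length(ord))
  names(out) <- ord
  for (nd in ord) {
    loc <- params[[nd]]
    idx <- if (length(loc$dparents)) {
      codes <- do.call(cbind, lapply(loc$dparents, function(p)
        match(as.character(out[[p]]), loc$dparent_levels[[p]])))
      config_index_from_codes(codes,
        vapply(loc$dparent_levels, length, 0L))
    } else rep(1L, n)
    if (loc$type == "discrete") {
      code <- integer(n)
      for (g in unique(idx)) {
        rows <- which(idx == g)
        code[rows] <- sample.int(length(loc$levels), length(rows),
                                 replace = TRUE, prob = loc$cpt[g, ])
      }
      out[[nd]] <- factor(loc$levels[code], levels = loc$levels)
    } else {
      mu <- loc$coef[idx, 1L]
      for (j in seq_along(loc$cparents))
        mu <- mu + loc$coef[idx, j + 1L] * out[[loc$cparents[j]]]
      if (n == 0L) mu <- numeric(0)
      out[[nd]] <- mu + stats::rnorm(n, 0, sqrt(loc$sigma2[idx]))
    }
  }
  as.data.frame(out[structure$nodes], optional = TRUE,
                stringsAsFactors = FALSE)[, structure$nodes, drop = FALSE]
}
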