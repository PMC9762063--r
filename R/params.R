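# Conditional-Gaussian parameterisation.
#
# Discrete nodes are multinomial with a CPT over each configuration of their
# discrete parents; continuous nodes carry, per discrete-parent
# configuration, an intercept, one linear coefficient per continuous parent
# and a noise variance.  Parent configurations are indexed in expand.grid
# order (first parent varying fastest).

config_grid <- function(dparent_levels) {
  if (!length(dparent_levels)) return(data.frame(row.names = 1L))
  expand.grid(dparent_levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

n_configs <- function(dparent_levels) {
  if (!length(dparent_levels)) 1L else prod(vapply(dparent_levels, length, 0L))
}

# 1-based configuration index from integer level codes (matrix n x q)
config_index_from_codes <- function(codes, sizes) {
  if (!length(sizes)) return(rep(1L, NROW(codes)))
  codes <- as.matrix(codes)
  idx <- rep(1L, nrow(codes))
  mult <- 1L
  for (j in seq_along(sizes)) {
    idx <- idx + (codes[, j] - 1L) * mult
    mult <- mult * sizes[j]
  }
  idx
}

#' Local model of a discrete node
#'
#' @param levels character vector of the node's levels.
#' @param dparents names of discrete parents (possibly empty).
#' @param dparent_levels named list of the parents' level vectors.
#' @param cpt numeric matrix `n_configs x length(levels)`; each row a
#'   probability distribution over the node's levels given that parent
#'   configuration (expand.grid order over `dparent_levels`).
#' @return a local-model list used inside [cg_params()].
#' @export
cg_node_discrete <- function(levels, dparents = character(0),
                             dparent_levels = list(), cpt) {
  levels <- as.character(levels)
  cpt <- matrix(as.numeric(cpt), nrow = n_configs(dparent_levels),
                ncol = length(levels),
                dimnames = list(NULL, levels))
  list(type = "discrete", levels = levels, dparents = dparents,
       dparent_levels = dparent_levels, cparents = character(0), cpt = cpt)
}

#' Local model of a continuous node
#'
#' @inheritParams cg_node_discrete
#' @param cparents names of continuous parents (possibly empty).
#' @param coef numeric matrix `n_configs x (1 + length(cparents))`:
#'   intercept then one column per continuous parent.  A vector is treated
#'   as a single row recycled over configurations.
#' @param sigma2 noise variance per configuration (recycled).
#' @return a local-model list used inside [cg_params()].
#' @export
cg_node_gaussian <- function(dparents = character(0), dparent_levels = list(),
                             cparents = character(0), coef, sigma2) {
  q <- n_configs(dparent_levels)
  k <- 1L + length(cparents)
  if (is.null(dim(coef))) coef <- matrix(coef, nrow = q, ncol = k, byrow = TRUE)
  dimnames(coef) <- list(NULL, c("(Intercept)", cparents))
  sigma2 <- rep_len(as.numeric(sigma2), q)
  list(type = "continuous", dparents = dparents,
       dparent_levels = dparent_levels, cparents = cparents,
       coef = coef, sigma2 = sigma2)
}

#' Assemble and validate conditional-Gaussian parameters
#'
#' @param nodes named list of local models from [cg_node_discrete()] /
#'   [cg_node_gaussian()], one per network node.
#' @return a `pabn_params` object.
#' @export
cg_params <- function(nodes) {
  abort_if(is.null(names(nodes)) || any(names(nodes) == ""),
           "local models must be named by node")
  for (nm in names(nodes)) {
    loc <- nodes[[nm]]
    if (loc$type == "discrete") {
      rs <- rowSums(loc$cpt)
      abort_if(any(abs(rs - 1) > 1e-9), sprintf("CPT rows of '%s' must sum to 1", nm))
      abort_if(any(loc$cpt < 0), sprintf("negative CPT entry in '%s'", nm))
    } else {
      abort_if(any(loc$sigma2 < 0), sprintf("negative noise variance in '%s'", nm))
    }
  }
  structure(nodes, class = "pabn_params")
}

#' @export
print.pabn_params <- function(x, ...) {
  nd <- sum(vapply(x, function(l) l$type == "discrete", TRUE))
  cat(sprintf("CG parameters: %d nodes (%d discrete, %d continuous)\n",
              length(x), nd, length(x) - nd))
  invisible(x)
}

params_to_list <- function(params) {
  lapply(unclass(params), function(loc) {
    if (loc$type == "discrete") {
      list(type = "discrete", levels = loc$levels, dparents = loc$dparents,
           dparent_levels = loc$dparent_levels,
           cpt = apply(loc$cpt, 1L, identity, simplify = FALSE))
    } else {
      list(type = "continuous", dparents = loc$dparents,
           dparent_levels = loc$dparent_levels, cparents = loc$cparents,
           coef = apply(loc$coef, 1L, identity, simplify = FALSE),
           sigma2 = loc$sigma2)
    }
  })
}

params_from_list <- function(lst) {
  nodes <- lapply(lst, function(loc) {
    dpl <- lapply(loc$dparent_levels, as.character)
    if (identical(as.character(unlist(loc$type)), "discrete")) {
      cg_node_discrete(loc$levels, as.character(unlist(loc$dparents)),
                       dpl, do.call(rbind, lapply(loc$cpt, unlist)))
    } else {
      cg_node_gaussian(as.character(unlist(loc$dparents)), dpl,
                       as.character(unlist(loc$cparents)),
                       do.call(rbind, lapply(loc$coef, unlist)),
                       unlist(loc$sigma2))
    }
  })
  cg_params(nodes)
}

#' Serialize parameters to JSON (full precision) and back
#' @param params a `pabn_params` object.
#' @param path file path.
#' @return `write_parameters`: `path` invisibly; `read_parameters`: params.
#' @export
write_parameters <- function(params, path) {
  jsonlite::write_json(params_to_list(params), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  params_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
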