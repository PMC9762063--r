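# Decomposable BIC for conditional-Gaussian networks.
#
# Convention: score = maximized log-likelihood - (k/2) * ln(n), higher is
# better, where k counts the free parameters (per discrete node
# (r-1) * n_configs; per continuous node (p + 2) * n_configs for intercept,
# p slopes and a variance in each discrete-parent configuration).  Scoring
# always uses maximum-likelihood (unsmoothed) estimates; the penalty is
# applied locally, which is equivalent to a global penalty because k adds up.

local_bic <- function(cols, n, child, parents, cov = NULL) {
  pt <- tryCatch(split_parent_types(cols, parents, child),
                 error = function(e) NULL)
  if (is.null(pt)) return(-Inf)            # type-invalid parent set
  cfg <- row_configs(cols, pt$dparents)
  dpl <- lapply(cols[pt$dparents], `[[`, "levels")
  q <- n_configs(dpl)
  idx <- cfg$idx %||% rep(1L, n)

  if (cols[[child]]$disc) {
    r <- length(cols[[child]]$levels)
    tab <- table(idx, cols[[child]]$code)
    nij <- rowSums(tab)
    tv <- as.numeric(tab)
    ll <- sum(tv[tv > 0] * log(tv[tv > 0])) - sum(nij[nij > 0] * log(nij[nij > 0]))
    k <- (r - 1) * q
  } else {
    y <- cols[[child]]$value
    p <- length(pt$cparents)
    X <- cbind(rep(1, n), if (p) do.call(cbind, lapply(cols[pt$cparents], `[[`, "value")))
    vars <- c(pt$cparents, child)
    ll <- 0
    for (g in seq_len(q)) {
      rows <- if (is.null(cfg$idx)) seq_len(n) else which(idx == g)
      ng <- length(rows)
      if (ng == 0L) next                    # unobserved configuration
      if (ng < p + 2L) return(-Inf)         # unestimable local model
      if (is.null(cov)) {
        fit <- stats::lm.fit(X[rows, , drop = FALSE], y[rows])
        if (fit$rank < p + 1L) return(-Inf)
        s2 <- sum(fit$residuals^2) / ng
      } else {
        # expected-sufficient-statistics path: normal equations on the
        # completed-data cross-moments plus the conditional-covariance sum
        fit <- moment_lsq(X, y, rows, vars, cov, p)
        if (is.null(fit)) return(-Inf)
        s2 <- fit$s2
      }
      if (s2 <= 1e-300) return(-Inf)        # degenerate fit
      ll <- ll - ng / 2 * (log(2 * pi * s2) + 1)
    }
    k <- (p + 2) * q
  }
  ll - k / 2 * log(n)
}

# least squares from expected second moments: A = [1 X y]'[1 X y] with the
# quadratic block corrected by the summed conditional covariances of the
# rows involved; returns NULL when the system is singular
moment_lsq <- function(X, y, rows, vars, cov, p) {
  A <- crossprod(cbind(X[rows, , drop = FALSE], y[rows]))
  pa <- length(cov$vnames)
  vi <- match(vars, cov$vnames)
  idx <- as.vector(outer(vi, vi, function(a, b) (b - 1L) * pa + a))
  V <- matrix(colSums(cov$flat[cov$group[rows], idx, drop = FALSE]),
              length(vars), length(vars))
  A[-1L, -1L] <- A[-1L, -1L] + V
  pred <- seq_len(p + 1L)
  beta <- tryCatch(solve(A[pred, pred, drop = FALSE], A[pred, p + 2L]),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rss <- A[p + 2L, p + 2L] - sum(A[pred, p + 2L] * beta)
  list(beta = beta, s2 = max(rss, 0) / length(rows))
}

# package per-record conditional covariances for the moment path: `flat`
# holds each group's p x p matrix as a row (column-major)
make_cov_stats <- function(group, mats) {
  vnames <- rownames(mats[[1L]])
  list(group = group,
       flat = do.call(rbind, lapply(mats, as.numeric)),
       vnames = vnames)
}

#' Local BIC contribution of one node given a parent set
#'
#' Exposed so decomposability can be verified directly; [bic_score()] is the
#' sum of these over nodes.
#'
#' @param data complete data.frame.
#' @param child node name.
#' @param parents character vector of parent names.
#' @return a single number (`-Inf` when the local model is not estimable).
#' @export
bic_local_score <- function(data, child, parents = character(0)) {
  cols <- prepare_columns(data[unique(c(child, parents))])
  local_bic(cols, nrow(data), child, parents)
}

#' BIC network score (higher is better)
#'
#' @param structure a `pabn_network`.
#' @param data complete data.frame covering every node.
#' @param cov optional expected-sufficient-statistics correction (as
#'   produced by the soft E-step of [structural_em()]): a list with
#'   per-record conditional-covariance group indices (`group`) and the
#'   matrices themselves (`mats`).  Used internally by the soft EM; leave
#'   `NULL` for ordinary complete data.
#' @return maximized log-likelihood minus `(k/2) ln(n)`.
#' @export
bic_score <- function(structure, data, cov = NULL) {
  abort_if(anyNA(data), "bic_score needs complete data")
  abort_if(!all(structure$nodes %in% names(data)), "data lacks some nodes")
  cols <- prepare_columns(data[structure$nodes])
  pl <- parent_list(structure)
  sum(vapply(structure$nodes, function(nd)
    local_bic(cols, nrow(data), nd, pl[[nd]], cov), 0))
}

# memoised local score used by the search: cache key is child|sorted parents
make_score_cache <- function(cols, n, cov = NULL) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(child, parents) {
    key <- paste0(child, "|", paste(sort(parents), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- local_bic(cols, n, child, parents, cov)
      cache[[key]] <- val
    }
    val
  }
}
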