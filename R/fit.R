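# Maximum-likelihood fitting of CG parameters and the joint log-likelihood.
#
# Tables are plain data.frames: discrete variables are factors (their factor
# levels define the multinomial support), continuous variables are numeric.

# precompute integer codes / doubles once per table
prepare_columns <- function(data) {
  cols <- lapply(data, function(x) {
    if (is.factor(x)) list(disc = TRUE, code = as.integer(x), levels = levels(x))
    else if (is.numeric(x)) list(disc = FALSE, value = as.double(x))
    else stop("columns must be factor (discrete) or numeric (continuous)", call. = FALSE)
  })
  names(cols) <- names(data)
  cols
}

split_parent_types <- function(cols, parents, child) {
  disc <- vapply(cols[parents], `[[`, TRUE, "disc")
  if (!all(disc) && cols[[child]]$disc)
    stop(sprintf("discrete node '%s' cannot have continuous parents", child), call. = FALSE)
  list(dparents = parents[disc], cparents = parents[!disc])
}

row_configs <- function(cols, dparents) {
  if (!length(dparents)) return(list(idx = NULL, sizes = integer(0)))
  codes <- do.call(cbind, lapply(cols[dparents], `[[`, "code"))
  sizes <- vapply(cols[dparents], function(c) length(c$levels), 0L)
  list(idx = config_index_from_codes(codes, sizes), sizes = sizes)
}

fit_local <- function(cols, child, parents, pseudo_count, cov = NULL) {
  pt <- split_parent_types(cols, parents, child)
  dpl <- lapply(cols[pt$dparents], `[[`, "levels")
  cfg <- row_configs(cols, pt$dparents)
  q <- n_configs(dpl)
  idx <- cfg$idx %||% rep(1L, length(cols[[child]][[2L]]))

  if (cols[[child]]$disc) {
    lev <- cols[[child]]$levels
    counts <- matrix(0, q, length(lev), dimnames = list(NULL, lev))
    tab <- table(factor(idx, levels = seq_len(q)), factor(cols[[child]]$code,
                 levels = seq_along(lev)))
    counts[] <- as.numeric(tab)
    cpt <- counts + pseudo_count
    rs <- rowSums(cpt)
    empty <- rs == 0
    cpt[empty, ] <- 1 / length(lev)   # unobserved configuration: uniform
    cpt[!empty, ] <- cpt[!empty, , drop = FALSE] / rs[!empty]
    cg_node_discrete(lev, pt$dparents, dpl, cpt)
  } else {
    y <- cols[[child]]$value
    p <- length(pt$cparents)
    X <- cbind(`(Intercept)` = rep(1, length(y)),
               if (p) do.call(cbind, lapply(cols[pt$cparents], `[[`, "value")))
    coef <- matrix(NA_real_, q, p + 1L)
    sigma2 <- rep(NA_real_, q)
    vars <- c(pt$cparents, child)
    for (k in seq_len(q)) {
      rows <- if (is.null(cfg$idx)) seq_along(y) else which(idx == k)
      if (length(rows) < p + 2L)
        stop(sprintf("insufficient observations for '%s' (configuration %d: %d rows, need >= %d)",
                     child, k, length(rows), p + 2L), call. = FALSE)
      if (is.null(cov)) {
        fit <- stats::lm.fit(X[rows, , drop = FALSE], y[rows])
        if (fit$rank < p + 1L)
          stop(sprintf("collinear continuous parents for '%s'", child), call. = FALSE)
        coef[k, ] <- fit$coefficients
        sigma2[k] <- sum(fit$residuals^2) / length(rows)
      } else {
        fit <- moment_lsq(X, y, rows, vars, cov, p)
        if (is.null(fit))
          stop(sprintf("collinear continuous parents for '%s'", child), call. = FALSE)
        coef[k, ] <- fit$beta
        sigma2[k] <- max(fit$s2, 1e-12)
      }
    }
    cg_node_gaussian(pt$dparents, dpl, pt$cparents, coef, sigma2)
  }
}

#' Fit conditional-Gaussian parameters by maximum likelihood
#'
#' Conditional probability tables are empirical frequencies with an additive
#' pseudo-count (default 1, keeping EM iterations away from zero
#' probabilities); continuous local models are per-configuration
#' least-squares fits with the maximum-likelihood variance.
#'
#' @param structure a `pabn_network`.
#' @param data complete data.frame (factors = discrete, numerics = continuous).
#' @param pseudo_count additive CPT smoothing (0 gives pure ML frequencies).
#' @param cov optional expected-sufficient-statistics correction (see
#'   [bic_score()]); used by the soft E-step of [structural_em()].
#' @return a `pabn_params` object.
#' @export
fit_parameters <- function(structure, data, pseudo_count = 1, cov = NULL) {
  abort_if(anyNA(data), "fit_parameters needs complete data")
  abort_if(!all(structure$nodes %in% names(data)), "data lacks some nodes")
  cols <- prepare_columns(data[structure$nodes])
  pl <- parent_list(structure)
  cg_params(lapply(stats::setNames(structure$nodes, structure$nodes),
                   function(nd) fit_local(cols, nd, pl[[nd]], pseudo_count, cov)))
}

local_loglik_from_params <- function(cols, child, loc) {
  cfg <- row_configs(cols, loc$dparents)
  n <- length(if (cols[[child]]$disc) cols[[child]]$code else cols[[child]]$value)
  idx <- cfg$idx %||% rep(1L, n)
  if (loc$type == "discrete") {
    code <- match(cols[[child]]$levels[cols[[child]]$code], loc$levels)
    sum(log(loc$cpt[cbind(idx, code)]))
  } else {
    y <- cols[[child]]$value
    X <- cbind(rep(1, length(y)), if (length(loc$cparents))
      do.call(cbind, lapply(cols[loc$cparents], `[[`, "value")))
    mu <- rowSums(loc$coef[idx, , drop = FALSE] * X)
    s2 <- loc$sigma2[idx]
    if (any(s2 == 0)) {           # degenerate (noise-free) local models
      det_ok <- abs(y - mu) < 1e-12
      out <- ifelse(s2 == 0, ifelse(det_ok, 0, -Inf),
                    stats::dnorm(y, mu, sqrt(pmax(s2, .Machine$double.xmin)), log = TRUE))
      sum(out)
    } else {
      sum(stats::dnorm(y, mu, sqrt(s2), log = TRUE))
    }
  }
}

#' Joint log-likelihood of complete data under CG parameters
#'
#' Factorizes over nodes: the sum of each record's local log density/mass.
#' A zero-probability discrete observation yields `-Inf`.
#'
#' @param params a `pabn_params` object.
#' @param data complete data.frame covering every parameterized node.
#' @return a single number.
#' @export
log_likelihood <- function(params, data) {
  abort_if(anyNA(data), "log_likelihood needs complete data")
  abort_if(!all(names(params) %in% names(data)), "data lacks some nodes")
  cols <- prepare_columns(data[names(params)])
  sum(vapply(names(params), function(nd)
    local_loglik_from_params(cols, nd, params[[nd]]), 0))
}
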