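# Exact conditional inference in a CG network, used to complete records with
# missing cells.  For each configuration of the discrete nodes the continuous
# nodes are jointly Gaussian; a record's missing cells are completed from the
# mixture over discrete configurations compatible with its observed discrete
# cells, weighted by prior configuration probability times the Gaussian
# density of the observed continuous cells.  Feasible here because the
# models have few discrete nodes (gender, education, intervention).

build_cg_joint <- function(structure, params) {
  ord <- topo_sort(structure)
  types <- vapply(params[ord], `[[`, "", "type")
  dnodes <- ord[types == "discrete"]
  cnodes <- ord[types == "continuous"]
  dlev <- lapply(params[dnodes], `[[`, "levels")
  names(dlev) <- dnodes
  ncfg <- n_configs(dlev)
  abort_if(ncfg > 10000L, "too many discrete configurations for exact inference")
  grid <- config_grid(dlev)

  logp <- numeric(ncfg)
  for (nd in dnodes) {
    loc <- params[[nd]]
    gidx <- if (length(loc$dparents)) {
      codes <- do.call(cbind, lapply(loc$dparents, function(p)
        match(grid[[p]], loc$dparent_levels[[p]])))
      config_index_from_codes(codes, vapply(loc$dparent_levels, length, 0L))
    } else rep(1L, ncfg)
    logp <- logp + log(loc$cpt[cbind(gidx, match(grid[[nd]], loc$levels))])
  }

  p <- length(cnodes)
  gaussians <- vector("list", max(ncfg, 1L))
  for (k in seq_len(ncfg)) {
    B <- matrix(0, p, p, dimnames = list(cnodes, cnodes))
    b0 <- numeric(p); d <- numeric(p)
    for (j in seq_len(p)) {
      loc <- params[[cnodes[j]]]
      gidx <- if (length(loc$dparents))
        config_index_from_codes(
          matrix(vapply(loc$dparents, function(q) match(grid[k, q], loc$dparent_levels[[q]]), 0L), 1L),
          vapply(loc$dparent_levels, length, 0L))
      else 1L
      b0[j] <- loc$coef[gidx, 1L]
      d[j] <- loc$sigma2[gidx]
      if (length(loc$cparents)) B[cnodes[j], loc$cparents] <- loc$coef[gidx, -1L]
    }
    A <- solve(diag(p) - B)
    mu <- as.numeric(A %*% b0)
    Sigma <- A %*% diag(d, p) %*% t(A)
    gaussians[[k]] <- list(mu = stats::setNames(mu, cnodes),
                           Sigma = Sigma, dimnames = cnodes)
  }
  list(dnodes = dnodes, cnodes = cnodes, dlev = dlev, grid = grid,
       logp = logp, gaussians = gaussians)
}

# record-grouping key: missingness pattern + observed discrete values
pattern_key <- function(miss_d, miss_c, dobs, n) {
  dmat <- if (ncol(miss_d)) replace(as.matrix(dobs), miss_d, "?")
          else matrix(character(0), n, 0L)
  apply(cbind(miss_d, miss_c, dmat), 1L, paste, collapse = "\r")
}

# marginal (mixture) means / modes for the degenerate fallback
joint_marginals <- function(joint) {
  w <- exp(joint$logp - max(joint$logp)); w <- w / sum(w)
  cmean <- 0
  for (k in seq_along(w)) cmean <- cmean + w[k] * joint$gaussians[[k]]$mu
  dmode <- lapply(joint$dnodes, function(nd) {
    pr <- tapply(w, joint$grid[[nd]], sum)[joint$dlev[[nd]]]
    joint$dlev[[nd]][which.max(pr)]
  })
  names(dmode) <- joint$dnodes
  list(cmean = cmean, dmode = dmode)
}

#' Complete a table with missing cells under a CG model
#'
#' Missing cells are filled from the exact conditional distribution given
#' each record's observed cells: conditional means and modes in
#' `"expectation"` mode, a draw from the conditional in `"draw"` mode.
#' Observed cells are never touched; columns that are not network nodes
#' pass through unchanged.  Records whose conditional degenerates
#' numerically fall back to the model marginals.
#'
#' @param structure a `pabn_network`.
#' @param params matching `pabn_params`.
#' @param data data.frame with `NA`s marking missing cells.
#' @param mode `"expectation"` (deterministic) or `"draw"`.
#' @param seed integer seed (used in `"draw"` mode).
#' @return the completed data.frame.
#' @export
impute_table <- function(structure, params, data,
                         mode = c("expectation", "draw"), seed = 0L) {
  mode <- match.arg(mode)
  abort_if(!all(structure$nodes %in% names(data)), "data lacks some nodes")
  if (!anyNA(data[structure$nodes])) return(data)
  if (mode == "draw") set.seed(derive_seed(seed, 1L))
  joint <- build_cg_joint(structure, params)
  marg <- joint_marginals(joint)
  out <- data
  ncfg <- length(joint$logp)

  dn <- joint$dnodes; cn <- joint$cnodes
  dobs <- as.data.frame(lapply(data[dn], as.character),
                        optional = TRUE, stringsAsFactors = FALSE)
  X <- as.matrix(as.data.frame(data[cn], optional = TRUE))
  miss_d <- is.na(as.matrix(dobs)); dim(miss_d) <- c(nrow(data), length(dn))
  miss_c <- is.na(X); dim(miss_c) <- c(nrow(data), length(cn))
  incomplete <- rowSums(miss_d) + rowSums(miss_c) > 0
  if (!any(incomplete)) return(out)

  # group records by missingness pattern + observed discrete values
  key <- pattern_key(miss_d, miss_c, dobs, nrow(data))
  for (grp in split(which(incomplete), key[incomplete])) {
    r1 <- grp[1L]
    od <- which(!miss_d[r1, ]); md <- which(miss_d[r1, ])
    oc <- which(!miss_c[r1, ]); mc <- which(miss_c[r1, ])
    # configurations compatible with the observed discrete cells
    compat <- seq_len(ncfg)
    for (j in od)
      compat <- compat[joint$grid[compat, dn[j]] == dobs[r1, j]]
    if (!length(compat)) compat <- seq_len(ncfg)   # impossible evidence: marginals
    ng <- length(grp); q <- length(oc); m <- length(mc)
    logw <- matrix(-Inf, ng, length(compat))
    condm <- if (m) array(NA_real_, c(ng, m, length(compat)))
    condS <- vector("list", length(compat))
    for (ki in seq_along(compat)) {
      k <- compat[ki]
      g <- joint$gaussians[[k]]
      lw <- rep(joint$logp[k], ng)
      if (q) {
        Soo <- g$Sigma[oc, oc, drop = FALSE]
        K <- tryCatch(solve(Soo), error = function(e) MASS::ginv(Soo))
        ld <- determinant(Soo, logarithm = TRUE)
        ld <- if (ld$sign > 0) as.numeric(ld$modulus) else NA_real_
        Xc <- sweep(X[grp, oc, drop = FALSE], 2L, g$mu[oc])
        quad <- rowSums((Xc %*% K) * Xc)
        lw <- if (is.na(ld)) rep(-Inf, ng)
              else lw - 0.5 * (quad + ld + q * log(2 * pi))
        if (m) {
          Smo <- g$Sigma[mc, oc, drop = FALSE]
          condm[, , ki] <- rep(g$mu[mc], each = ng) + Xc %*% t(Smo %*% K)
          condS[[ki]] <- g$Sigma[mc, mc, drop = FALSE] - Smo %*% K %*% t(Smo)
        }
      } else if (m) {
        condm[, , ki] <- matrix(g$mu[mc], ng, m, byrow = TRUE)
        condS[[ki]] <- g$Sigma[mc, mc, drop = FALSE]
      }
      logw[, ki] <- lw
    }
    mx <- apply(logw, 1L, max)
    bad <- !is.finite(mx)
    w <- exp(logw - ifelse(is.finite(mx), mx, 0))
    sw <- rowSums(w)
    w <- w / ifelse(sw > 0, sw, 1)

    if (mode == "expectation") {
      if (m) {
        fill <- matrix(0, ng, m)
        for (ki in seq_along(compat)) fill <- fill + w[, ki] * condm[, , ki, drop = TRUE]
        dim(fill) <- c(ng, m)
        fill[bad, ] <- rep(marg$cmean[cn[mc]], each = sum(bad))
        for (j in seq_len(m)) out[grp, cn[mc[j]]] <- fill[, j]
      }
      for (j in md) {
        lev <- joint$dlev[[dn[j]]]
        pl <- vapply(lev, function(lv)
          rowSums(w[, joint$grid[compat, dn[j]] == lv, drop = FALSE]), numeric(ng))
        dim(pl) <- c(ng, length(lev))
        pick <- lev[max.col(pl, ties.method = "first")]
        pick[bad] <- marg$dmode[[dn[j]]]
        out[grp, dn[j]] <- factor(pick, levels = levels(data[[dn[j]]]) %||% lev)
      }
    } else {
      for (i in seq_len(ng)) {
        ki <- if (bad[i]) which.max(joint$logp[compat])
              else sample.int(length(compat), 1L, prob = w[i, ])
        k <- compat[ki]
        for (j in md)
          out[grp[i], dn[j]] <- joint$grid[k, dn[j]]
        if (m) {
          S <- condS[[ki]]
          L <- tryCatch(chol(S + diag(1e-12, m)), error = function(e) NULL)
          mu_i <- condm[i, , ki]
          out[grp[i], cn[mc]] <-
            if (is.null(L)) mu_i else mu_i + as.numeric(t(L) %*% stats::rnorm(m))
        }
      }
    }
  }
  out
}

#' Complete one record with missing cells
#'
#' Per-record form of [impute_table()]: a fully observed record is returned
#' unchanged; a fully missing record is completed from the model marginals.
#'
#' @inheritParams impute_table
#' @param record a one-row data.frame.
#' @return the completed one-row data.frame.
#' @export
impute_record <- function(structure, params, record,
                          mode = c("expectation", "draw"), seed = 0L) {
  abort_if(nrow(record) != 1L, "record must be a one-row data.frame")
  impute_table(structure, params, record, mode = match.arg(mode), seed = seed)
}

# E-step with expected sufficient statistics: expectation-mode completion
# plus, per record, the conditional covariance of its missing continuous
# cells given the observed ones.  Records sharing a missingness pattern and
# a single compatible discrete configuration share a covariance matrix;
# records with missing discrete cells get a per-record mixture covariance.
# Returns list(completed, cov_group, cov_list): cov_list[[cov_group[i]]] is
# record i's conditional covariance over all continuous nodes (zero rows
# and columns for observed cells; entry 1 is the all-zero matrix used by
# complete records).
estep_moments <- function(structure, params, data) {
  joint <- build_cg_joint(structure, params)
  marg <- joint_marginals(joint)
  dn <- joint$dnodes; cn <- joint$cnodes
  p <- length(cn)
  out <- data
  dobs <- as.data.frame(lapply(data[dn], as.character),
                        optional = TRUE, stringsAsFactors = FALSE)
  X <- as.matrix(as.data.frame(data[cn], optional = TRUE))
  miss_d <- is.na(as.matrix(dobs)); dim(miss_d) <- c(nrow(data), length(dn))
  miss_c <- is.na(X); dim(miss_c) <- c(nrow(data), p)
  zero <- matrix(0, p, p, dimnames = list(cn, cn))
  cov_group <- rep(1L, nrow(data))
  cov_list <- list(zero)
  incomplete <- rowSums(miss_d) + rowSums(miss_c) > 0
  if (!any(incomplete))
    return(list(completed = out, cov_group = cov_group, cov_list = cov_list))

  # marginal mixture covariance (fallback for degenerate records)
  wmix <- exp(joint$logp - max(joint$logp)); wmix <- wmix / sum(wmix)
  mixS <- zero; mixm <- rep(0, p)
  for (k in seq_along(wmix)) mixm <- mixm + wmix[k] * joint$gaussians[[k]]$mu
  for (k in seq_along(wmix)) {
    dm <- joint$gaussians[[k]]$mu - mixm
    mixS <- mixS + wmix[k] * (joint$gaussians[[k]]$Sigma + outer(dm, dm))
  }

  key <- pattern_key(miss_d, miss_c, dobs, nrow(data))
  ncfg <- length(joint$logp)
  for (grp in split(which(incomplete), key[incomplete])) {
    r1 <- grp[1L]
    od <- which(!miss_d[r1, ]); md <- which(miss_d[r1, ])
    oc <- which(!miss_c[r1, ]); mc <- which(miss_c[r1, ])
    compat <- seq_len(ncfg)
    for (j in od)
      compat <- compat[joint$grid[compat, dn[j]] == dobs[r1, j]]
    if (!length(compat)) compat <- seq_len(ncfg)
    ng <- length(grp); q <- length(oc); m <- length(mc)
    logw <- matrix(-Inf, ng, length(compat))
    condm <- if (m) array(NA_real_, c(ng, m, length(compat)))
    condS <- vector("list", length(compat))
    for (ki in seq_along(compat)) {
      k <- compat[ki]
      g <- joint$gaussians[[k]]
      lw <- rep(joint$logp[k], ng)
      if (q) {
        Soo <- g$Sigma[oc, oc, drop = FALSE]
        K <- tryCatch(solve(Soo), error = function(e) MASS::ginv(Soo))
        ld <- determinant(Soo, logarithm = TRUE)
        ld <- if (ld$sign > 0) as.numeric(ld$modulus) else NA_real_
        Xc <- sweep(X[grp, oc, drop = FALSE], 2L, g$mu[oc])
        quad <- rowSums((Xc %*% K) * Xc)
        lw <- if (is.na(ld)) rep(-Inf, ng)
              else lw - 0.5 * (quad + ld + q * log(2 * pi))
        if (m) {
          Smo <- g$Sigma[mc, oc, drop = FALSE]
          condm[, , ki] <- rep(g$mu[mc], each = ng) + Xc %*% t(Smo %*% K)
          condS[[ki]] <- g$Sigma[mc, mc, drop = FALSE] - Smo %*% K %*% t(Smo)
        }
      } else if (m) {
        condm[, , ki] <- matrix(g$mu[mc], ng, m, byrow = TRUE)
        condS[[ki]] <- g$Sigma[mc, mc, drop = FALSE]
      }
      logw[, ki] <- lw
    }
    mx <- apply(logw, 1L, max)
    bad <- !is.finite(mx)
    w <- exp(logw - ifelse(is.finite(mx), mx, 0))
    sw <- rowSums(w)
    w <- w / ifelse(sw > 0, sw, 1)

    single <- length(compat) == 1L
    if (m) {
      fill <- matrix(0, ng, m)
      for (ki in seq_along(compat)) fill <- fill + w[, ki] * condm[, , ki, drop = TRUE]
      dim(fill) <- c(ng, m)
      fill[bad, ] <- rep(mixm[mc], each = sum(bad))
      for (j in seq_len(m)) out[grp, cn[mc[j]]] <- fill[, j]
    }
    for (j in md) {
      lev <- joint$dlev[[dn[j]]]
      pl <- vapply(lev, function(lv)
        rowSums(w[, joint$grid[compat, dn[j]] == lv, drop = FALSE]), numeric(ng))
      dim(pl) <- c(ng, length(lev))
      pick <- lev[max.col(pl, ties.method = "first")]
      pick[bad] <- marg$dmode[[dn[j]]]
      out[grp, dn[j]] <- factor(pick, levels = levels(data[[dn[j]]]) %||% lev)
    }
    if (m) {
      if (single && !any(bad)) {
        C <- zero
        C[mc, mc] <- condS[[1L]]
        cov_list[[length(cov_list) + 1L]] <- C
        cov_group[grp] <- length(cov_list)
      } else {
        for (i in seq_len(ng)) {
          C <- zero
          if (bad[i]) {
            C[mc, mc] <- mixS[mc, mc]
          } else {
            mbar <- rep(0, m)
            for (ki in seq_along(compat)) mbar <- mbar + w[i, ki] * condm[i, , ki]
            S <- matrix(0, m, m)
            for (ki in seq_along(compat)) {
              dmn <- condm[i, , ki] - mbar
              S <- S + w[i, ki] * (condS[[ki]] + outer(dmn, dmn))
            }
            C[mc, mc] <- S
          }
          cov_list[[length(cov_list) + 1L]] <- C
          cov_group[grp[i]] <- length(cov_list)
        }
      }
    }
  }
  list(completed = out, cov_group = cov_group, cov_list = cov_list)
}
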