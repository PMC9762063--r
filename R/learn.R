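# Constrained search-and-score structure learning.
#
# Greedy hill-climbing over single-arc moves (add / delete / reverse),
# restricted to arcs admissible under the temporal/type/role constraint set,
# scored by the decomposable BIC.  Ties between equal-score moves are broken
# lexicographically by (child, parent, move type) so runs are deterministic;
# optional random restarts perturb the optimum and keep the best result.

#' Hill-climbing structure search under constraints
#'
#' @param data complete data.frame over the constraint set's variables.
#' @param constraints a `pabn_constraints` object ([build_constraints()]).
#' @param seed integer seed (only consumed by random restarts).
#' @param restarts number of random restarts after the greedy climb
#'   (default 0: pure greedy; bootstrap averaging supplies robustness).
#' @param start optional `pabn_network` to start from (default: empty graph).
#' @param epsilon minimal score improvement for a move to be accepted.
#' @param cov optional expected-sufficient-statistics correction (see
#'   [bic_score()]); used by the soft E-step of [structural_em()].
#' @return a `pabn_network` with attributes `score` (its BIC) and `moves`
#'   (data.frame log of accepted moves, for monotonicity diagnostics).
#' @export
hill_climb <- function(data, constraints, seed = 0L, restarts = 0L,
                       start = NULL, epsilon = 1e-6, cov = NULL) {
  nodes <- rownames(constraints$allowed)
  abort_if(!all(nodes %in% names(data)), "data lacks some constraint variables")
  abort_if(anyNA(data[nodes]), "hill_climb needs complete data")
  cols <- prepare_columns(data[nodes])
  n <- nrow(data)
  local_score <- make_score_cache(cols, n, cov)
  allowed <- constraints$allowed
  snodes <- sort(nodes)

  climb <- function(pl) {
    moves <- list()
    cur <- vapply(nodes, function(v) local_score(v, pl[[v]]), 0)
    names(cur) <- nodes
    repeat {
      children <- stats::setNames(vector("list", length(nodes)), nodes)
      for (v in nodes) for (u in pl[[v]]) children[[u]] <- c(children[[u]], v)
      best <- list(delta = epsilon)
      for (v in snodes) for (u in snodes) {
        if (u == v) next
        if (u %in% pl[[v]]) {
          # delete u -> v
          d_del <- local_score(v, setdiff(pl[[v]], u)) - cur[[v]]
          if (d_del > best$delta + 1e-12)
            best <- list(delta = d_del, op = "delete", from = u, to = v)
          # reverse to v -> u (if legal and acyclic once u -> v is dropped)
          if (allowed[v, u]) {
            ch2 <- children
            ch2[[u]] <- setdiff(ch2[[u]], v)
            if (!has_path_pl(ch2, u, v)) {
              d_rev <- (local_score(v, setdiff(pl[[v]], u)) - cur[[v]]) +
                       (local_score(u, c(pl[[u]], v)) - cur[[u]])
              if (d_rev > best$delta + 1e-12)
                best <- list(delta = d_rev, op = "reverse", from = u, to = v)
            }
          }
        } else if (allowed[u, v] && !(v %in% pl[[u]])) {
          # add u -> v unless it closes a cycle
          if (!has_path_pl(children, v, u)) {
            d_add <- local_score(v, c(pl[[v]], u)) - cur[[v]]
            if (d_add > best$delta + 1e-12)
              best <- list(delta = d_add, op = "add", from = u, to = v)
          }
        }
      }
      if (is.null(best$op)) break
      if (best$op == "add") {
        pl[[best$to]] <- c(pl[[best$to]], best$from)
        cur[[best$to]] <- local_score(best$to, pl[[best$to]])
      } else if (best$op == "delete") {
        pl[[best$to]] <- setdiff(pl[[best$to]], best$from)
        cur[[best$to]] <- local_score(best$to, pl[[best$to]])
      } else {
        pl[[best$to]] <- setdiff(pl[[best$to]], best$from)
        pl[[best$from]] <- c(pl[[best$from]], best$to)
        cur[[best$to]] <- local_score(best$to, pl[[best$to]])
        cur[[best$from]] <- local_score(best$from, pl[[best$from]])
      }
      moves[[length(moves) + 1L]] <-
        data.frame(op = best$op, from = best$from, to = best$to,
                   score = sum(cur), stringsAsFactors = FALSE)
    }
    list(pl = pl, score = sum(cur), moves = moves)
  }

  pl0 <- stats::setNames(lapply(nodes, function(x) character(0)), nodes)
  if (!is.null(start)) {
    abort_if(!satisfies_constraints(start, constraints),
             "start structure violates the constraints")
    pl0[names(parent_list(start))] <- parent_list(start)
  }
  res <- climb(pl0)

  if (restarts > 0L) {
    legal <- which(allowed, arr.ind = TRUE)
    for (r in seq_len(restarts)) {
      set.seed(derive_seed(seed, 1000L + r))
      pl <- res$pl
      # perturb: try to insert a few random legal arcs, then re-climb
      for (i in sample(nrow(legal), min(4L, nrow(legal)))) {
        u <- nodes[legal[i, 1L]]; v <- nodes[legal[i, 2L]]
        if (u %in% pl[[v]]) next
        ch <- stats::setNames(vector("list", length(nodes)), nodes)
        for (w in nodes) for (x in pl[[w]]) ch[[x]] <- c(ch[[x]], w)
        if (!has_path_pl(ch, v, u)) pl[[v]] <- c(pl[[v]], u)
      }
      cand <- climb(pl)
      if (cand$score > res$score + 1e-12) res <- cand
    }
  }

  net <- parent_list_to_network(res$pl, validate = TRUE)
  attr(net, "score") <- res$score
  attr(net, "moves") <- if (length(res$moves)) do.call(rbind, res$moves)
                        else data.frame(op = character(0), from = character(0),
                                        to = character(0), score = numeric(0))
  net
}

#' Structural EM for datasets with missing values
#'
#' Iterates E-steps that complete the data under the current model with
#' M-steps (hill-climbing plus parameter fitting on the completed data),
#' starting from the empty-graph model (marginal means/modes), until the
#' completed-data BIC improves by less than `score_tol` or `max_iter`
#' cycles are reached.  A step that would lower the completed-data score
#' terminates the loop and the previous model is kept, so the reported
#' score trajectory is non-decreasing.
#'
#' Two E-step flavours are available.  `"soft"` (the default) carries
#' expected sufficient statistics: missing continuous cells enter the score
#' through their conditional means *and* conditional covariances, so an
#' imputed mediator keeps its full variance and correctly screens its
#' ancestors.  `"hard"` uses plain expectation-mode completion
#' ([impute_table()]); it is simpler but deterministically-imputed
#' mediators have shrunken variance, which is known to induce spurious
#' chain-skipping arcs at higher missingness rates.
#'
#' @inheritParams hill_climb
#' @param data data.frame with `NA` missing markers.
#' @param max_iter maximum number of E/M cycles.
#' @param score_tol convergence tolerance on the completed-data BIC.
#' @param pseudo_count CPT smoothing used when fitting parameters.
#' @param min_obs_frac minimal observed fraction required per variable.
#' @param estep `"soft"` (expected sufficient statistics) or `"hard"`
#'   (expectation-mode completion only).
#' @return a `pabn_sem` list: `structure`, `params`, `completed` (the final
#'   completed table), `scores` (BIC per iteration, non-decreasing),
#'   `iterations`, `converged`.
#' @export
structural_em <- function(data, constraints, max_iter = 25L, score_tol = 1e-4,
                          seed = 0L, pseudo_count = 1, min_obs_frac = 0.05,
                          restarts = 0L, estep = c("soft", "hard")) {
  estep <- match.arg(estep)
  nodes <- rownames(constraints$allowed)
  abort_if(!all(nodes %in% names(data)), "data lacks some constraint variables")
  obs_frac <- vapply(data[nodes], function(x) mean(!is.na(x)), 0)
  abort_if(any(obs_frac == 0),
           sprintf("variable(s) entirely missing: %s",
                   paste(nodes[obs_frac == 0], collapse = ", ")))
  abort_if(any(obs_frac < min_obs_frac),
           sprintf("variable(s) observed in under %.0f%% of records: %s",
                   100 * min_obs_frac,
                   paste(nodes[obs_frac < min_obs_frac], collapse = ", ")))

  # initial completion: marginal means / modes (empty-graph expectation step)
  completed <- data
  for (v in nodes) {
    x <- data[[v]]
    if (!anyNA(x)) next
    fill <- if (is.factor(x)) {
      tab <- table(x)
      factor(names(tab)[which.max(tab)], levels = levels(x))
    } else mean(x, na.rm = TRUE)
    completed[[v]][is.na(x)] <- fill
  }
  cov <- if (estep == "soft" && anyNA(data[nodes])) initial_moments(data, nodes)

  best <- NULL
  scores <- numeric(0)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    struct <- hill_climb(completed, constraints,
                         seed = derive_seed(seed, i), restarts = restarts,
                         cov = cov)
    params <- fit_parameters(struct, completed, pseudo_count, cov = cov)
    score <- bic_score(struct, completed, cov = cov)
    if (!is.null(best) && score < best$score) { converged <- TRUE; break }
    improved <- is.null(best) || score - best$score >= score_tol
    best <- list(structure = struct, params = params,
                 completed = completed, score = score)
    scores <- c(scores, score)
    if (i > 1L && !improved) { converged <- TRUE; break }
    if (i == max_iter) break
    if (estep == "soft") {
      em <- estep_moments(struct, params, data)
      completed <- em$completed
      cov <- make_cov_stats(em$cov_group, em$cov_list)
    } else {
      completed <- impute_table(struct, params, data, mode = "expectation")
    }
  }
  structure(list(structure = best$structure, params = best$params,
                 completed = best$completed, scores = scores,
                 iterations = length(scores), converged = converged),
            class = "pabn_sem")
}

# empty-graph expected sufficient statistics: marginal-mean completion with
# diagonal conditional covariances (the observed marginal variances)
initial_moments <- function(data, nodes) {
  cont <- nodes[vapply(data[nodes], is.numeric, TRUE)]
  miss <- vapply(data[cont], is.na, logical(nrow(data)))
  dim(miss) <- c(nrow(data), length(cont))
  vars <- vapply(data[cont], function(x) stats::var(x, na.rm = TRUE), 0)
  zero <- matrix(0, length(cont), length(cont), dimnames = list(cont, cont))
  group <- rep(1L, nrow(data))
  mats <- list(zero)
  if (any(miss)) {
    key <- apply(miss, 1L, paste, collapse = "")
    for (rows in split(which(rowSums(miss) > 0), key[rowSums(miss) > 0])) {
      C <- zero
      mc <- which(miss[rows[1L], ])
      diag(C)[mc] <- vars[mc]
      mats[[length(mats) + 1L]] <- C
      group[rows] <- length(mats)
    }
  }
  make_cov_stats(group, mats)
}

#' @export
print.pabn_sem <- function(x, ...) {
  cat(sprintf("Structural EM: %d iteration(s), %s, final BIC %.2f\n",
              x$iterations, if (x$converged) "converged" else "iteration limit",
              x$scores[length(x$scores)]))
  print(x$structure)
  invisible(x)
}
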