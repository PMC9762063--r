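# Shared fixtures: small variable tables, random legal ground truths and a
# brute-force DAG-space enumerator used as scoring oracle.

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal tiered, all-continuous variable table (plus the intervention)
tiered_variables <- function(t1 = c("x1", "x2"), t2 = c("y1", "y2"),
                             t3 = "pa_T3", intervention = TRUE) {
  specs <- list()
  if (intervention)
    specs[[1L]] <- variable_spec("intervention", "intervention", "static",
                                 "intervention", "discrete",
                                 levels = c("control", "intervention"))
  for (v in t1) specs[[length(specs) + 1L]] <-
    variable_spec(v, v, "T1", "determinant", "continuous")
  for (v in t2) specs[[length(specs) + 1L]] <-
    variable_spec(v, v, "T2", "determinant", "continuous")
  for (v in t3) specs[[length(specs) + 1L]] <-
    variable_spec(v, v, "T3", "outcome", "continuous")
  do.call(variable_table, specs)
}

# random constraint-satisfying truth over a mixed inventory; exercises
# demographics, baseline, intervention, determinants and both node types
random_legal_truth <- function(seed, arc_prob = 0.25) {
  set.seed(seed)
  specs <- list(
    variable_spec("age", "age", "static", "demographic", "continuous"),
    variable_spec("gender", "gender", "static", "demographic", "discrete",
                  levels = c("m", "f")),
    variable_spec("intervention", "intervention", "static", "intervention",
                  "discrete", levels = c("c", "i")),
    variable_spec("base1", "base1", "T0", "baseline", "continuous"),
    variable_spec("base2", "base2", "T0", "baseline", "continuous"),
    variable_spec("d1_T1", "d1", "T1", "determinant", "continuous"),
    variable_spec("d2_T1", "d2", "T1", "determinant", "continuous"),
    variable_spec("d1_T2", "d1", "T2", "determinant", "continuous"),
    variable_spec("pa_T2", "pa", "T2", "outcome", "continuous"))
  variables <- do.call(variable_table, specs)
  cons <- build_constraints(variables)
  legal <- which(cons$allowed, arr.ind = TRUE)
  legal <- legal[sample.int(nrow(legal)), , drop = FALSE]
  nm <- variables$name
  pl <- stats::setNames(lapply(nm, function(x) character(0)), nm)
  for (i in seq_len(nrow(legal))) {
    if (stats::runif(1) > arc_prob) next
    u <- nm[legal[i, 1L]]; v <- nm[legal[i, 2L]]
    ch <- stats::setNames(lapply(nm, function(x) character(0)), nm)
    for (w in nm) for (x in pl[[w]]) ch[[x]] <- c(ch[[x]], w)
    if (!pabn:::has_path_pl(ch, v, u)) pl[[v]] <- c(pl[[v]], u)
  }
  dag <- pabn:::parent_list_to_network(pl, validate = TRUE)
  nodes <- lapply(stats::setNames(nm, nm), function(nd) {
    row <- variables[match(nd, variables$name), ]
    par <- pl[[nd]]
    disc <- par[vapply(par, function(p)
      variables$vtype[match(p, variables$name)] == "discrete", TRUE)]
    cont <- setdiff(par, disc)
    dpl <- lapply(stats::setNames(disc, disc), function(p)
      variables$levels[[match(p, variables$name)]])
    q <- pabn:::n_configs(dpl)
    if (row$vtype == "discrete") {
      pr <- matrix(stats::runif(q * 2, 0.2, 0.8), q, 2)
      cg_node_discrete(row$levels[[1L]], disc, dpl, pr / rowSums(pr))
    } else {
      coef <- cbind(stats::rnorm(q, 0, 0.5),
                    if (length(cont))
                      matrix(rep(stats::runif(length(cont), -0.6, 0.6), each = q),
                             q, length(cont)))
      cg_node_gaussian(disc, dpl, cont, coef, stats::runif(q, 0.5, 1.5))
    }
  })
  list(variables = variables, dag = dag, params = cg_params(nodes),
       constraints = cons)
}

# enumerate every subset of `pairs` (2-column matrix) that forms a DAG and
# score it with the package BIC; memoizes local scores
best_structure_bruteforce <- function(data, nodes, pairs) {
  memo <- new.env(parent = emptyenv())
  local_sc <- function(child, parents) {
    key <- paste0(child, "|", paste(sort(parents), collapse = ","))
    if (is.null(memo[[key]]))
      memo[[key]] <- bic_local_score(data, child, parents)
    memo[[key]]
  }
  best <- list(score = -Inf)
  m <- nrow(pairs)
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    arcs <- pairs[sel, , drop = FALSE]
    net <- tryCatch(network_structure(nodes, arcs), error = function(e) NULL)
    if (is.null(net)) next
    pl <- pabn:::parent_list(net)
    sc <- sum(vapply(nodes, function(nd) local_sc(nd, pl[[nd]]), 0))
    if (sc > best$score) best <- list(score = sc, net = net)
  }
  best
}

# exhaustive simple directed paths (independent of the package's
# reachability-based fragment extraction)
oracle_fragment_arcs <- function(nodes, arcs, source, targets) {
  g <- igraph::graph_from_data_frame(as.data.frame(arcs), directed = TRUE,
                                     vertices = nodes)
  keys <- character(0)
  for (t in intersect(targets, nodes)) {
    if (!source %in% nodes) next
    paths <- igraph::all_simple_paths(g, from = source, to = t, mode = "out")
    for (p in paths) {
      vs <- names(p)
      if (length(vs) > 1L)
        keys <- c(keys, paste(vs[-length(vs)], vs[-1L], sep = "->"))
    }
  }
  sort(unique(keys))
}
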