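# Structural constraints of the temporal hybrid model.
#
# Four rule families restrict which directed arcs are admissible:
#   temporal  - no arc into an earlier measurement wave;
#   type      - no continuous parent of a discrete node (the CG model class);
#   role      - demographics accept only other demographics as parents;
#               baseline (T0) variables accept only demographics and other
#               baseline variables; the intervention indicator accepts only
#               demographics and baseline variables;
#   self      - no self-loops.
# Arc legality is decidable per arc; acyclicity is checked separately by the
# search (and is implied across tiers by the temporal rule anyway).

#' Build the arc-legality constraint set for a variable inventory
#'
#' @param variables a `pabn_variables` table ([variable_table()]).
#' @return a `pabn_constraints` object holding a logical `allowed` matrix
#'   (rows = parent, cols = child), the tier index per variable and the
#'   variable table itself.
#' @export
build_constraints <- function(variables) {
  abort_if(!inherits(variables, "pabn_variables"), "need a pabn_variables table")
  abort_if(any(is.na(variables$tier)) || any(is.na(variables$role)),
           "every variable needs a tier and a role")
  nm <- variables$name
  p <- length(nm)
  tier <- stats::setNames(tier_index(variables$tier), nm)
  role <- stats::setNames(variables$role, nm)
  vtype <- stats::setNames(variables$vtype, nm)

  allowed <- matrix(TRUE, p, p, dimnames = list(parent = nm, child = nm))
  diag(allowed) <- FALSE
  # type rule: continuous -> discrete forbidden
  allowed[vtype == "continuous", vtype == "discrete"] <- FALSE
  # temporal rule: parent tier must not exceed child tier (statics exempt)
  for (u in nm) for (v in nm) {
    if (!is.na(tier[[u]]) && !is.na(tier[[v]]) && tier[[u]] > tier[[v]])
      allowed[u, v] <- FALSE
  }
  # role rules (per child)
  demo <- nm[role == "demographic"]
  base <- nm[role == "baseline"]
  for (v in nm) {
    ok_parents <- switch(role[[v]],
      demographic  = demo,
      baseline     = c(demo, base),
      intervention = c(demo, base),
      nm)
    bad <- setdiff(nm, ok_parents)
    allowed[bad, v] <- FALSE
    allowed[v, v] <- FALSE
  }
  structure(list(allowed = allowed, tier = tier, role = role,
                 vtype = vtype, variables = variables),
            class = "pabn_constraints")
}

#' Is a single arc admissible under the constraint set?
#' @param constraints a `pabn_constraints` object.
#' @param from,to parent and child node names.
#' @return `TRUE`/`FALSE`.
#' @export
arc_allowed <- function(constraints, from, to) {
  abort_if(!all(c(from, to) %in% rownames(constraints$allowed)), "unknown node")
  constraints$allowed[from, to]
}

#' Check a whole structure against a constraint set
#' @param net a `pabn_network`.
#' @param constraints a `pabn_constraints` object.
#' @return `TRUE` if every arc is admissible and the graph is acyclic.
#' @export
satisfies_constraints <- function(net, constraints) {
  if (!is_acyclic(net)) return(FALSE)
  if (nrow(net$arcs) == 0L) return(TRUE)
  all(constraints$allowed[net$arcs])
}

#' @export
print.pabn_constraints <- function(x, ...) {
  cat(sprintf("Constraint set over %d variables: %d of %d ordered pairs admissible\n",
              nrow(x$allowed), sum(x$allowed), length(x$allowed) - nrow(x$allowed)))
  invisible(x)
}
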