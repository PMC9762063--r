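# Directed-acyclic-graph structure of a (hybrid) Bayesian network.
#
# Internally a structure is a character node vector plus a 2-column arc
# matrix (from, to).  The search code works on a parent-list representation
# for speed; this class is the user-facing, validated form.

#' Create a Bayesian-network structure
#'
#' @param nodes character vector of node names.
#' @param arcs two-column character matrix (or data.frame) of directed arcs,
#'   columns `from`, `to`; may have zero rows.
#' @param validate check acyclicity and node membership (default `TRUE`).
#' @return an object of class `pabn_network`.
#' @export
network_structure <- function(nodes, arcs = NULL, validate = TRUE) {
  nodes <- as.character(nodes)
  abort_if(anyDuplicated(nodes) > 0L, "duplicate node names")
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- matrix(character(0), ncol = 2L)
  } else {
    arcs <- as.matrix(arcs)
    abort_if(ncol(arcs) != 2L, "arcs must have two columns (from, to)")
    storage.mode(arcs) <- "character"
  }
  colnames(arcs) <- c("from", "to")
  rownames(arcs) <- NULL
  net <- structure(list(nodes = nodes, arcs = arcs), class = "pabn_network")
  if (validate) {
    abort_if(!all(arcs %in% nodes), "arc endpoint not in node set")
    abort_if(any(arcs[, 1L] == arcs[, 2L]), "self-loops are not allowed")
    abort_if(anyDuplicated(arc_keys(net)) > 0L, "duplicate arcs")
    abort_if(!is_acyclic(net), "structure contains a directed cycle")
  }
  net
}

arc_keys <- function(net) {
  if (nrow(net$arcs) == 0L) return(character(0))
  paste(net$arcs[, 1L], net$arcs[, 2L], sep = "->")
}

# parent-list representation: named list node -> character vector of parents
parent_list <- function(net) {
  pl <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (n in net$nodes) pl[[n]] <- character(0)
  if (nrow(net$arcs)) {
    sp <- split(net$arcs[, 1L], net$arcs[, 2L])
    pl[names(sp)] <- lapply(sp, as.character)
  }
  pl
}

parent_list_to_network <- function(pl, validate = FALSE) {
  arcs <- do.call(rbind, lapply(names(pl), function(ch) {
    if (length(pl[[ch]])) cbind(from = pl[[ch]], to = ch) else NULL
  }))
  network_structure(names(pl), arcs, validate = validate)
}

#' Parents of a node
#' @param net a `pabn_network`.
#' @param node node name.
#' @return character vector of parent names.
#' @export
parents_of <- function(net, node) {
  abort_if(!node %in% net$nodes, sprintf("unknown node '%s'", node))
  as.character(net$arcs[net$arcs[, 2L] == node, 1L])
}

#' Children of a node
#' @inheritParams parents_of
#' @return character vector of child names.
#' @export
children_of <- function(net, node) {
  abort_if(!node %in% net$nodes, sprintf("unknown node '%s'", node))
  as.character(net$arcs[net$arcs[, 1L] == node, 2L])
}

# Kahn's algorithm on a parent list; NULL if cyclic
topo_sort_pl <- function(pl) {
  nodes <- names(pl)
  indeg <- vapply(pl, length, 0L)
  order <- character(0)
  ready <- sort(nodes[indeg == 0L])
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (ch in nodes) for (p in pl[[ch]]) children[[p]] <- c(children[[p]], ch)
  while (length(ready)) {
    n <- ready[1L]; ready <- ready[-1L]
    order <- c(order, n)
    for (ch in children[[n]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

#' Topological order of a structure
#' @param net a `pabn_network`.
#' @return node names, every parent before its children.
#' @export
topo_sort <- function(net) {
  ord <- topo_sort_pl(parent_list(net))
  abort_if(is.null(ord), "structure contains a directed cycle")
  ord
}

#' Is the structure acyclic?
#' @param net a `pabn_network`.
#' @return `TRUE`/`FALSE`.
#' @export
is_acyclic <- function(net) !is.null(topo_sort_pl(parent_list(net)))

# is there a directed path from `from` to `to`?  (children-list DFS)
has_path_pl <- function(children, from, to) {
  if (from == to) return(TRUE)
  seen <- stats::setNames(logical(length(children)), names(children))
  stack <- from
  while (length(stack)) {
    n <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[[n]]) next
    seen[[n]] <- TRUE
    kids <- children[[n]]
    if (to %in% kids) return(TRUE)
    stack <- c(stack, kids)
  }
  FALSE
}

children_list <- function(net) {
  cl <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (n in net$nodes) cl[[n]] <- character(0)
  if (nrow(net$arcs)) {
    sp <- split(net$arcs[, 2L], net$arcs[, 1L])
    cl[names(sp)] <- lapply(sp, as.character)
  }
  cl
}

# all nodes reachable from `from` (inclusive) following directed arcs
reachable_from <- function(children, from) {
  seen <- character(0)
  stack <- from
  while (length(stack)) {
    n <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (n %in% seen) next
    seen <- c(seen, n)
    stack <- c(stack, children[[n]])
  }
  seen
}

#' @export
print.pabn_network <- function(x, ...) {
  cat(sprintf("Bayesian network structure: %d nodes, %d arcs\n",
              length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs)) {
    keys <- sort(arc_keys(x))
    show <- utils::head(keys, 20L)
    cat(paste0("  ", show, collapse = "\n"), "\n")
    if (length(keys) > 20L) cat(sprintf("  ... and %d more\n", length(keys) - 20L))
  }
  invisible(x)
}

#' Write / read a structure as a plain arc-list (DOT-compatible)
#'
#' The file holds one `from -> to;` line per arc inside a `digraph` block,
#' so it is both human-readable and renderable with Graphviz.  Round-trips
#' bit-exactly.
#'
#' @param net a `pabn_network`.
#' @param path file path.
#' @return `write_network`: `path`, invisibly. `read_network`: the structure.
#' @export
write_network <- function(net, path) {
  lines <- c("digraph pabn {",
             paste0('  "', net$nodes, '";'),
             if (nrow(net$arcs))
               paste0('  "', net$arcs[, 1L], '" -> "', net$arcs[, 2L], '";'),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!(lines %in% c("digraph pabn {", "}", ""))]
  arc_lines <- grepl("->", lines, fixed = TRUE)
  nodes <- sub('^"(.*)";$', "\\1", lines[!arc_lines])
  arcs <- NULL
  if (any(arc_lines)) {
    m <- regmatches(lines[arc_lines],
                    regexec('^"(.*)" -> "(.*)";$', lines[arc_lines]))
    arcs <- cbind(from = vapply(m, `[`, "", 2L), to = vapply(m, `[`, "", 3L))
  }
  network_structure(nodes, arcs)
}
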