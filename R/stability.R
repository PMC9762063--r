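# Bootstrap arc-confidence estimation and threshold-based model averaging.
#
# Confidence of a directed arc is the fraction of networks, learnt from
# nonparametric bootstrap resamples of the records, that contain the arc.
# Resampling is stratified by study so no study's design block can drop out
# of a resample of the integrated (heterogeneous) dataset.

boot_structures <- function(data, n_boot, learner, seed = 0L, strata = NULL,
                            max_retries = 3L) {
  n <- nrow(data)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(n))
                    else split(seq_len(n), strata)
  lapply(seq_len(n_boot), function(b) {
    for (try in 0:max_retries) {
      s <- derive_seed(seed, b * 17L + try * 7919L)
      set.seed(s)
      rows <- unlist(lapply(idx_by_stratum, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      net <- tryCatch(learner(data[rows, , drop = FALSE], s),
                      error = function(e) e)
      if (!inherits(net, "error")) return(net)
      message(sprintf("bootstrap %d: learner failed (%s); redrawing", b,
                      conditionMessage(net)))
    }
    stop(sprintf("bootstrap %d: learner failed after %d retries", b, max_retries),
         call. = FALSE)
  })
}

tally_arcs <- function(structures) {
  keys <- unlist(lapply(structures, arc_keys), use.names = FALSE)
  if (!length(keys))
    return(data.frame(from = character(0), to = character(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  tab <- table(keys)
  parts <- strsplit(names(tab), "->", fixed = TRUE)
  out <- data.frame(from = vapply(parts, `[`, "", 1L),
                    to = vapply(parts, `[`, "", 2L),
                    frequency = as.numeric(tab) / length(structures),
                    stringsAsFactors = FALSE)
  out[order(-out$frequency, out$from, out$to), , drop = FALSE]
}

#' Bootstrap confidence in directed arcs
#'
#' @param data data.frame of records (complete or with missing values,
#'   depending on what `learner` handles).
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param learner function `(data, seed) -> pabn_network`; typically a
#'   wrapper around [hill_climb()] (complete data) or [structural_em()].
#' @param seed integer root seed; each resample draws its own sub-seed.
#' @param strata optional factor/vector (e.g. study of origin); resampling
#'   is then stratified so every stratum keeps its original size.
#' @param keep_structures retain the per-bootstrap networks for diagnostics.
#' @param max_retries bounded redraws when the learner fails on a resample.
#' @return a `pabn_arc_confidence` object: `entries` (data.frame `from`,
#'   `to`, `frequency`; absent arcs read as 0), `n_boot`, and optionally
#'   `structures`.
#' @export
bootstrap_confidence <- function(data, n_boot, learner, seed = 0L,
                                 strata = NULL, keep_structures = FALSE,
                                 max_retries = 3L) {
  abort_if(n_boot < 1L, "n_boot must be >= 1")
  structures <- boot_structures(data, n_boot, learner, seed, strata, max_retries)
  structure(list(entries = tally_arcs(structures), n_boot = n_boot,
                 nodes = structures[[1L]]$nodes,
                 structures = if (keep_structures) structures),
            class = "pabn_arc_confidence")
}

#' Confidence of one directed arc (0 when never observed)
#' @param conf a `pabn_arc_confidence` object.
#' @param from,to arc endpoints.
#' @return frequency in `[0, 1]`.
#' @export
arc_confidence <- function(conf, from, to) {
  hit <- conf$entries$from == from & conf$entries$to == to
  if (any(hit)) conf$entries$frequency[hit][1L] else 0
}

#' @export
print.pabn_arc_confidence <- function(x, ...) {
  cat(sprintf("Bootstrap arc confidence: %d arcs observed over %d resamples\n",
              nrow(x$entries), x$n_boot))
  print(utils::head(x$entries, 12L), row.names = FALSE)
  invisible(x)
}

#' Structural Hamming distance between two DAGs
#'
#' The number of arc insertions, deletions and reversals needed to turn one
#' graph into the other; a reversal counts as one edit.
#'
#' @param g1,g2 `pabn_network` objects over the same node set.
#' @return a non-negative integer.
#' @export
shd <- function(g1, g2) {
  abort_if(!setequal(g1$nodes, g2$nodes), "graphs must share the node set")
  k1 <- arc_keys(g1); k2 <- arc_keys(g2)
  rev_key <- function(keys) {
    parts <- strsplit(keys, "->", fixed = TRUE)
    vapply(parts, function(p) paste0(p[2L], "->", p[1L]), "")
  }
  only1 <- setdiff(k1, k2); only2 <- setdiff(k2, k1)
  reversals <- sum(rev_key(only1) %in% only2)
  length(only1) + length(only2) - reversals
}

# locate one directed cycle, returned as a matrix of its arcs (or NULL)
find_cycle <- function(pl) {
  nodes <- names(pl)
  children <- stats::setNames(lapply(nodes, function(x) character(0)), nodes)
  for (v in nodes) for (u in pl[[v]]) children[[u]] <- c(children[[u]], v)
  color <- stats::setNames(integer(length(nodes)), nodes)
  found <- NULL
  visit <- function(u, path) {
    if (!is.null(found)) return()
    color[[u]] <<- 1L
    for (v in children[[u]]) {
      if (!is.null(found)) return()
      if (color[[v]] == 1L) {
        cyc <- c(path[which(path == v):length(path)], u)
        found <<- cbind(from = cyc, to = c(cyc[-1L], v))
      } else if (color[[v]] == 0L) visit(v, c(path, v))
    }
    color[[u]] <<- 2L
  }
  for (u in nodes) if (color[[u]] == 0L) visit(u, u)
  found
}

#' Threshold-averaged consensus network
#'
#' Includes exactly the arcs whose bootstrap confidence meets the threshold
#' (inclusive, so 0.60 survives a 60% threshold).  Should thresholding leave
#' a directed cycle (possible only among same-tier arcs), the
#' lowest-confidence arc of each cycle is removed until the graph is
#' acyclic; removals are recorded.
#'
#' @param conf a `pabn_arc_confidence` object.
#' @param threshold inclusion threshold in `(0, 1]` (default 0.6).
#' @return a `pabn_averaged` object: `structure`, `confidence` (data.frame
#'   for the included arcs), `threshold`, `removed`.
#' @export
average_network <- function(conf, threshold = 0.6) {
  abort_if(!(threshold > 0 && threshold <= 1), "threshold must be in (0, 1]")
  keep <- conf$entries[conf$entries$frequency >= threshold, , drop = FALSE]
  removed <- keep[0, , drop = FALSE]
  repeat {
    net <- network_structure(conf$nodes, keep[, c("from", "to")], validate = FALSE)
    cyc <- find_cycle(parent_list(net))
    if (is.null(cyc)) break
    in_cyc <- paste(keep$from, keep$to, sep = "->") %in%
              paste(cyc[, 1L], cyc[, 2L], sep = "->")
    drop <- which(in_cyc)[which.min(keep$frequency[in_cyc])]
    removed <- rbind(removed, keep[drop, , drop = FALSE])
    keep <- keep[-drop, , drop = FALSE]
  }
  structure(list(structure = network_structure(conf$nodes, keep[, c("from", "to")]),
                 confidence = keep, threshold = threshold, removed = removed),
            class = "pabn_averaged")
}

#' @export
print.pabn_averaged <- function(x, ...) {
  cat(sprintf("Averaged network (threshold %.2f): %d arcs",
              x$threshold, nrow(x$confidence)))
  if (nrow(x$removed)) cat(sprintf(", %d removed in cycle repair", nrow(x$removed)))
  cat("\n")
  print(x$structure)
  invisible(x)
}

#' Choose the number of bootstrap resamples by SHD stabilisation
#'
#' Draws `max(candidates)` bootstrap networks once, forms the thresholded
#' averaged structure from the first `c` resamples for each candidate `c`,
#' and returns the smallest candidate whose averaged structure is identical
#' (SHD 0) to the next candidate's -- or the largest candidate when the
#' series never stabilises.  The SHD-versus-count series is attached for
#' plotting.
#'
#' @inheritParams bootstrap_confidence
#' @param candidates ascending integer vector of bootstrap counts.
#' @param threshold averaging threshold (default 0.6).
#' @return the selected count (integer) with attribute `diagnostic`, a
#'   data.frame of adjacent-candidate SHD values.
#' @export
select_n_boot <- function(data, learner, candidates, threshold = 0.6,
                          seed = 0L, strata = NULL, max_retries = 3L) {
  abort_if(!length(candidates) || is.unsorted(candidates, strictly = TRUE),
           "candidates must be a non-empty ascending integer vector")
  structures <- boot_structures(data, max(candidates), learner, seed,
                                strata, max_retries)
  avg <- lapply(candidates, function(cnt) {
    conf <- structure(list(entries = tally_arcs(structures[seq_len(cnt)]),
                           n_boot = cnt, nodes = structures[[1L]]$nodes),
                      class = "pabn_arc_confidence")
    average_network(conf, threshold)$structure
  })
  series <- data.frame(
    n_from = utils::head(candidates, -1L), n_to = candidates[-1L],
    shd = vapply(seq_len(length(candidates) - 1L), function(i)
      shd(avg[[i]], avg[[i + 1L]]), 0L))
  stable <- series$n_from[series$shd == 0L]
  chosen <- if (length(stable)) as.integer(stable[1L])
            else as.integer(candidates[length(candidates)])
  attr(chosen, "diagnostic") <- series
  chosen
}
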