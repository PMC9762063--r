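# Intervention-to-outcome path fragments.
#
# From an averaged network, the fragment keeps exactly the nodes and arcs
# lying on at least one directed path from the intervention node to a PA
# outcome node (in a DAG, an arc u->v is on such a path iff u is reachable
# from the source and some target is reachable from v).  Arcs are annotated
# with their bootstrap stability (drawn as line thickness, cut at
# 0.7/0.8/0.9) and with jackknife bias-corrected mutual information on
# pairwise complete cases (drawn as 1-3 asterisks, cut at the 33%/67%
# quantiles over the fragment's own arcs).

#' Extract the source-to-targets path fragment of an averaged network
#'
#' @param net a `pabn_averaged` object ([average_network()]).
#' @param source source node (the intervention indicator).
#' @param targets character vector of outcome nodes (e.g. PA at T2 and T3).
#' @param stability_threshold arcs below this confidence are dropped before
#'   path extraction (must be >= the averaging threshold to have an effect).
#' @return a `pabn_fragment`: `structure` (subgraph), `arcs` (data.frame
#'   `from`, `to`, `confidence` plus annotation columns once
#'   [annotate_fragment()] has run), `source`, `targets`, `threshold`.
#' @export
extract_fragment <- function(net, source, targets,
                             stability_threshold = net$threshold) {
  abort_if(!inherits(net, "pabn_averaged"), "need a pabn_averaged network")
  abort_if(source %in% targets, "source must not be one of the targets")
  nodes <- net$structure$nodes
  abort_if(!all(c(source, targets) %in% nodes), "source/target not in network")
  arcs <- net$confidence[net$confidence$frequency >= stability_threshold, ,
                         drop = FALSE]
  sub <- network_structure(nodes, arcs[, c("from", "to")], validate = FALSE)
  ch <- children_list(sub)
  fwd <- reachable_from(ch, source)
  rev_ch <- stats::setNames(lapply(nodes, function(x) character(0)), nodes)
  for (i in seq_len(nrow(arcs)))
    rev_ch[[arcs$to[i]]] <- c(rev_ch[[arcs$to[i]]], arcs$from[i])
  bwd <- unique(unlist(lapply(targets, function(t) reachable_from(rev_ch, t)),
                       use.names = FALSE))
  keep <- arcs$from %in% fwd & arcs$to %in% bwd
  kept <- arcs[keep, , drop = FALSE]
  fnodes <- intersect(nodes, unique(c(kept$from, kept$to)))
  out <- data.frame(from = kept$from, to = kept$to,
                    confidence = kept$frequency,
                    mi = rep(NA_real_, nrow(kept)),
                    mi_band = rep(NA_integer_, nrow(kept)),
                    width_band = rep(NA_integer_, nrow(kept)),
                    stringsAsFactors = FALSE)
  structure(list(structure = network_structure(fnodes, kept[, c("from", "to")]),
                 arcs = out, source = source, targets = targets,
                 threshold = stability_threshold,
                 mi_cutoffs = NULL, mi_range = NULL),
            class = "pabn_fragment")
}

#' @export
print.pabn_fragment <- function(x, ...) {
  cat(sprintf("Fragment %s -> {%s}: %d nodes, %d arcs (stability >= %.2f)\n",
              x$source, paste(x$targets, collapse = ", "),
              length(x$structure$nodes), nrow(x$arcs), x$threshold))
  if (!is.null(x$mi_cutoffs))
    cat(sprintf("  MI cut-offs %.2f (33%%) / %.2f (67%%), range %.2f-%.2f\n",
                x$mi_cutoffs[1L], x$mi_cutoffs[2L],
                x$mi_range[1L], x$mi_range[2L]))
  invisible(x)
}

mi_plugin <- function(x, y) {
  if (is.numeric(x) && is.numeric(y)) {
    r <- stats::cor(x, y)
    -0.5 * log(max(1 - r^2, 1e-300))
  } else if (is.factor(x) && is.factor(y)) {
    tab <- table(x, y); n <- sum(tab)
    p <- tab / n; px <- rowSums(p); py <- colSums(p)
    pos <- p > 0
    sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
  } else {
    if (is.factor(y)) { tmp <- x; x <- y; y <- tmp }   # x discrete, y numeric
    v_all <- mean((y - mean(y))^2)
    lv <- split(y, x)
    h_cond <- sum(vapply(lv, function(g)
      length(g) / length(y) * 0.5 * log(2 * pi * exp(1) *
        max(mean((g - mean(g))^2), 1e-12)), 0))
    0.5 * log(2 * pi * exp(1) * max(v_all, 1e-12)) - h_cond
  }
}

jk_loo_cont <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  m <- n - 1
  vx <- (sxx - x^2) / m - ((sx - x) / m)^2
  vy <- (syy - y^2) / m - ((sy - y) / m)^2
  cxy <- (sxy - x * y) / m - (sx - x) * (sy - y) / m^2
  r2 <- pmin(cxy^2 / pmax(vx * vy, 1e-300), 1 - 1e-12)
  -0.5 * log(1 - r2)
}

jk_loo_mixed <- function(x, y) {        # x factor, y numeric
  n <- length(y); m <- n - 1
  code <- as.integer(x)
  nl <- tabulate(code)
  sl <- vapply(seq_along(nl), function(l) sum(y[code == l]), 0)
  ssl <- vapply(seq_along(nl), function(l) sum(y[code == l]^2), 0)
  sa <- sum(y); ssa <- sum(y^2)
  v_all_i <- (ssa - y^2) / m - ((sa - y) / m)^2
  # within-level variance with record i removed (its own level only changes)
  nl_i <- nl[code] - 1L
  ml_i <- (sl[code] - y) / pmax(nl_i, 1L)
  vl_i <- (ssl[code] - y^2) / pmax(nl_i, 1L) - ml_i^2
  vl <- ssl / nl - (sl / nl)^2
  # sum over unchanged levels of (n_l / m) * 0.5 log(2 pi e v_l)
  hterm <- 0.5 * log(2 * pi * exp(1) * pmax(vl, 1e-12))
  t_all <- sum(nl * hterm)
  h_cond_i <- (t_all - nl[code] * hterm[code] +
               nl_i * 0.5 * log(2 * pi * exp(1) * pmax(vl_i, 1e-12))) / m
  0.5 * log(2 * pi * exp(1) * pmax(v_all_i, 1e-12)) - h_cond_i
}

jk_loo_disc <- function(x, y) {
  tab <- table(x, y); n <- sum(tab)
  cell <- function(tab2, n2) {
    p <- tab2 / n2; px <- rowSums(p); py <- colSums(p)
    pos <- p > 0
    sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
  }
  # leave-one-out value depends only on the removed record's cell
  loo_by_cell <- matrix(NA_real_, nrow(tab), ncol(tab))
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] == 0) next
    t2 <- tab; t2[i, j] <- t2[i, j] - 1
    loo_by_cell[i, j] <- cell(t2, n - 1)
  }
  loo_by_cell[cbind(as.integer(x), as.integer(y))]
}

#' Jackknife bias-corrected mutual information
#'
#' Computes a plug-in mutual-information estimate on pairwise complete
#' cases -- Gaussian MI `-0.5 log(1 - r^2)` for two continuous columns,
#' pooled-minus-conditional Gaussian entropies for a discrete/continuous
#' pair, the contingency-table plug-in for two discrete columns -- and
#' returns the leave-one-out jackknife bias correction
#' `n * I_hat - (n - 1) * mean(I_hat_(-i))`, floored at 0 (nats).
#'
#' @param x,y columns (numeric or factor), possibly containing `NA`.
#' @return a non-negative number.
#' @export
jackknife_mi <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  abort_if(n < 10L, "need at least 10 complete pairs")
  for (v in list(x, y)) if (is.numeric(v))
    abort_if(stats::var(v) == 0, "zero variance in a continuous column")
  i_hat <- mi_plugin(x, y)
  loo <- if (is.numeric(x) && is.numeric(y)) jk_loo_cont(x, y)
         else if (is.factor(x) && is.factor(y)) jk_loo_disc(x, y)
         else if (is.factor(x)) jk_loo_mixed(x, y)
         else jk_loo_mixed(y, x)
  max(n * i_hat - (n - 1) * mean(loo), 0)
}

#' Annotate a fragment with MI bands and stability width bands
#'
#' Per-arc mutual information is the jackknife bias-corrected estimate on
#' pairwise complete cases of the two endpoint columns.  The 33% and 67%
#' quantiles of the fragment's own MI values cut the arcs into bands 1-3
#' (asterisks; a value on a cut-off goes to the higher band); stability cuts
#' arcs into width bands 1-4 at 0.7, 0.8 and 0.9.  The realized cut-off
#' values and the MI min/max are stored on the fragment for reporting.
#'
#' @param frag a `pabn_fragment`.
#' @param data the integrated records (an `pabn_integrated` object or a
#'   plain data.frame) containing both endpoint columns of every arc.
#' @param conf optional `pabn_arc_confidence` to refresh arc confidences;
#'   by default the confidences carried by the fragment are used.
#' @return the annotated `pabn_fragment`.
#' @export
annotate_fragment <- function(frag, data, conf = NULL) {
  abort_if(!inherits(frag, "pabn_fragment"), "need a pabn_fragment")
  records <- if (inherits(data, "pabn_integrated")) data$records else data
  arcs <- frag$arcs
  if (nrow(arcs) == 0L) return(frag)
  abort_if(!all(c(arcs$from, arcs$to) %in% names(records)),
           "arc endpoint missing from data")
  if (!is.null(conf))
    arcs$confidence <- mapply(arc_confidence, from = arcs$from, to = arcs$to,
                              MoreArgs = list(conf = conf))
  arcs$mi <- vapply(seq_len(nrow(arcs)), function(i)
    jackknife_mi(records[[arcs$from[i]]], records[[arcs$to[i]]]), 0)
  cuts <- stats::quantile(arcs$mi, c(0.33, 0.67), names = FALSE, type = 7)
  arcs$mi_band <- 1L + (arcs$mi >= cuts[1L]) + (arcs$mi >= cuts[2L])
  arcs$width_band <- 1L + (arcs$confidence >= 0.7) +
    (arcs$confidence >= 0.8) + (arcs$confidence >= 0.9)
  frag$arcs <- arcs
  frag$mi_cutoffs <- cuts
  frag$mi_range <- range(arcs$mi)
  frag
}
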