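# End-to-end orchestration: simulate (or accept) an integrated cohort,
# learn with structural EM, bootstrap, average, and extract the annotated
# intervention -> PA fragment, for the full population and for strata.

#' Configuration for a full analysis run
#'
#' @param truth a `pabn_truth` defining the cohort to simulate.
#' @param n cohort size (default: the truth's design sizes).
#' @param seed root seed; every stage derives its own sub-seed from it.
#' @param n_boot bootstrap resamples for arc confidence.
#' @param boot_candidates optional ascending counts for the SHD
#'   stabilisation diagnostic ([select_n_boot()]).
#' @param avg_threshold arc-confidence threshold of the averaged model
#'   (default 0.6).
#' @param display_threshold stability threshold of the displayed fragment
#'   (>= `avg_threshold`; default equal).
#' @param source,targets fragment endpoints (defaults: the intervention
#'   node and PA at T2/T3 where present).
#' @param stratify optional demographic to stratify on (e.g. `"gender"`);
#'   one model per level, with the stratifier dropped as a constant.
#' @param sem_max_iter,sem_score_tol,pseudo_count,restarts,min_obs_frac
#'   learner options (see [structural_em()]).
#' @param output_dir directory for run artifacts (`NULL`: nothing written).
#' @return a `pabn_config` list.
#' @export
run_config <- function(truth, n = NULL, seed = 1L, n_boot = 50L,
                       boot_candidates = NULL, avg_threshold = 0.6,
                       display_threshold = avg_threshold,
                       source = "intervention", targets = NULL,
                       stratify = NULL, sem_max_iter = 10L,
                       sem_score_tol = 1e-4, pseudo_count = 1,
                       restarts = 0L, min_obs_frac = 0.05,
                       output_dir = NULL) {
  abort_if(!(avg_threshold > 0 && avg_threshold <= 1), "avg_threshold in (0,1]")
  abort_if(display_threshold < avg_threshold,
           "display threshold must be >= the averaging threshold")
  if (is.null(targets))
    targets <- intersect(c("pa_T2", "pa_T3"), truth$variables$name)
  structure(list(truth = truth, n = n, seed = seed, n_boot = n_boot,
                 boot_candidates = boot_candidates,
                 avg_threshold = avg_threshold,
                 display_threshold = display_threshold, source = source,
                 targets = targets, stratify = stratify,
                 sem_max_iter = sem_max_iter, sem_score_tol = sem_score_tol,
                 pseudo_count = pseudo_count, restarts = restarts,
                 min_obs_frac = min_obs_frac,
                 output_dir = output_dir), class = "pabn_config")
}

model_nodes <- function(variables) variables$name

analyse_population <- function(records, variables, config, label, seed) {
  cons <- build_constraints(variables)
  nodes <- variables$name
  learner <- function(d, s) {
    if (anyNA(d[nodes]))
      structural_em(d, cons, max_iter = config$sem_max_iter,
                    score_tol = config$sem_score_tol, seed = s,
                    pseudo_count = config$pseudo_count,
                    restarts = config$restarts,
                    min_obs_frac = config$min_obs_frac %||% 0.05)$structure
    else hill_climb(d, cons, seed = s, restarts = config$restarts)
  }
  point <- learner(records, derive_seed(seed, 1L))
  strata_col <- records$study_id
  nb_sel <- NULL
  if (!is.null(config$boot_candidates))
    nb_sel <- select_n_boot(records, learner, config$boot_candidates,
                            threshold = config$avg_threshold,
                            seed = derive_seed(seed, 2L), strata = strata_col)
  conf <- bootstrap_confidence(records, config$n_boot, learner,
                               seed = derive_seed(seed, 3L),
                               strata = strata_col)
  avg <- average_network(conf, config$avg_threshold)
  targets <- intersect(config$targets, nodes)
  frag <- extract_fragment(avg, config$source, targets,
                           config$display_threshold)
  frag <- annotate_fragment(frag, records)
  list(label = label, structure = point, confidence = conf, averaged = avg,
       fragment = frag, n_boot_selection = nb_sel,
       n_records = nrow(records),
       stability_summary = if (nrow(avg$confidence)) c(
         mean = mean(avg$confidence$frequency),
         median = stats::median(avg$confidence$frequency)))
}

#' Run the full analysis workflow
#'
#' Simulates the configured cohort with its design and MCAR missingness,
#' learns the general model (structural EM under the temporal/role
#' constraints), estimates bootstrap arc confidence stratified by study,
#' averages at the confidence threshold, and extracts the annotated
#' intervention-to-PA fragment; then repeats per stratum when `stratify`
#' is set (the stratifier leaves the model as a constant).  All artifacts
#' are deterministic functions of the configuration, including its seed.
#'
#' @param config a `pabn_config` from [run_config()].
#' @return a `pabn_run`: `data` (the integrated dataset), `full` and
#'   `strata` analysis results, and `manifest`.
#' @export
run_full_analysis <- function(config) {
  abort_if(!inherits(config, "pabn_config"), "need a pabn_config")
  t0 <- proc.time()[[3L]]
  truth <- config$truth
  cohort <- simulate_cohort(truth, n = config$n, seed = derive_seed(config$seed, 11L))
  cohort <- apply_missingness(cohort, truth, seed = derive_seed(config$seed, 12L))
  data <- structure(list(records = cohort[truth$variables$name],
                         provenance = as.character(cohort$study_id),
                         variables = truth$variables),
                    class = "pabn_integrated")
  records <- cbind(data$records, study_id = cohort$study_id)

  timings <- c(simulate = proc.time()[[3L]] - t0)
  t1 <- proc.time()[[3L]]
  full <- analyse_population(records, truth$variables, config, "all",
                             derive_seed(config$seed, 21L))
  timings <- c(timings, full = proc.time()[[3L]] - t1)

  strata <- list()
  if (!is.null(config$stratify)) {
    lv <- levels(records[[config$stratify]]) %||%
          sort(unique(as.character(records[[config$stratify]])))
    for (k in seq_along(lv)) {
      t2 <- proc.time()[[3L]]
      sub <- filter_subpopulation(data, config$stratify, lv[k])
      sub_rec <- cbind(sub$records,
                       study_id = factor(sub$provenance,
                                         levels = unique(data$provenance)))
      strata[[lv[k]]] <- analyse_population(sub_rec, sub$variables, config,
                                            lv[k],
                                            derive_seed(config$seed, 30L + k))
      timings <- c(timings, stats::setNames(proc.time()[[3L]] - t2, lv[k]))
    }
  }

  manifest <- list(
    seed = config$seed, n_records = nrow(records),
    n_boot = config$n_boot, avg_threshold = config$avg_threshold,
    display_threshold = config$display_threshold,
    source = config$source, targets = config$targets,
    stratify = config$stratify,
    sem = list(max_iter = config$sem_max_iter,
               score_tol = config$sem_score_tol,
               pseudo_count = config$pseudo_count,
               restarts = config$restarts),
    package_version = as.character(utils::packageVersion("pabn")),
    r_version = R.version.string,
    timings_sec = as.list(round(timings, 2)))

  run <- structure(list(data = data, full = full, strata = strata,
                        manifest = manifest), class = "pabn_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.pabn_run <- function(x, ...) {
  cat(sprintf("Analysis run: %d records; full model %d averaged arcs, fragment %d arcs\n",
              x$manifest$n_records, nrow(x$full$averaged$confidence),
              nrow(x$full$fragment$arcs)))
  for (s in x$strata)
    cat(sprintf("  stratum %s: %d records, fragment %d arcs\n",
                s$label, s$n_records, nrow(s$fragment$arcs)))
  invisible(x)
}

write_population <- function(res, dir, label) {
  utils::write.csv(res$confidence$entries,
                   file.path(dir, paste0("confidence_", label, ".csv")),
                   row.names = FALSE)
  write_network(res$averaged$structure,
                file.path(dir, paste0("averaged_", label, ".dot")))
  utils::write.csv(res$fragment$arcs,
                   file.path(dir, paste0("fragment_", label, ".csv")),
                   row.names = FALSE)
  write_fragment_dot(res$fragment, file.path(dir, paste0("fragment_", label, ".dot")))
  if (!is.null(res$n_boot_selection))
    utils::write.csv(attr(res$n_boot_selection, "diagnostic"),
                     file.path(dir, paste0("shd_series_", label, ".csv")),
                     row.names = FALSE)
}

#' Write all artifacts of a run to a directory
#' @param run a `pabn_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_population(run$full, dir, "all")
  for (s in names(run$strata)) write_population(run$strata[[s]], dir, s)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare two fragments
#'
#' Lists arcs unique to each fragment, shared arcs whose stability or MI
#' band differs, and nodes present in only one fragment.
#'
#' @param frag_a,frag_b `pabn_fragment` objects with the same
#'   source/target convention.
#' @return a `pabn_fragment_diff` list.
#' @export
compare_fragments <- function(frag_a, frag_b) {
  ka <- paste(frag_a$arcs$from, frag_a$arcs$to, sep = "->")
  kb <- paste(frag_b$arcs$from, frag_b$arcs$to, sep = "->")
  shared <- intersect(ka, kb)
  band_diff <- do.call(rbind, lapply(shared, function(k) {
    a <- frag_a$arcs[ka == k, ]; b <- frag_b$arcs[kb == k, ]
    if (isTRUE(a$mi_band == b$mi_band) && isTRUE(a$width_band == b$width_band))
      return(NULL)
    data.frame(arc = k, mi_band_a = a$mi_band, mi_band_b = b$mi_band,
               width_band_a = a$width_band, width_band_b = b$width_band,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    arcs_only_a = sort(setdiff(ka, kb)),
    arcs_only_b = sort(setdiff(kb, ka)),
    band_differences = band_diff %||%
      data.frame(arc = character(0), mi_band_a = integer(0),
                 mi_band_b = integer(0), width_band_a = integer(0),
                 width_band_b = integer(0), stringsAsFactors = FALSE),
    nodes_only_a = sort(setdiff(frag_a$structure$nodes, frag_b$structure$nodes)),
    nodes_only_b = sort(setdiff(frag_b$structure$nodes, frag_a$structure$nodes))),
    class = "pabn_fragment_diff")
}

#' @export
print.pabn_fragment_diff <- function(x, ...) {
  cat(sprintf("Fragment comparison: %d arcs only in A, %d only in B, %d band differences\n",
              length(x$arcs_only_a), length(x$arcs_only_b),
              nrow(x$band_differences)))
  if (length(x$arcs_only_a)) cat("  A only:", paste(x$arcs_only_a, collapse = ", "), "\n")
  if (length(x$arcs_only_b)) cat("  B only:", paste(x$arcs_only_b, collapse = ", "), "\n")
  invisible(x)
}

CATEGORY_FILL <- c(
  `pre-motivational` = "#a6cee3", motivational = "#b2df8a",
  `post-motivational` = "#fdbf6f", outcome = "#fb9a99",
  intervention = "#cab2d6", demographic = "#d9d9d9", other = "#ffffff")

node_concept <- function(name) sub("_T[0-3]$", "", name)

#' Export an annotated fragment as a Graphviz DOT file
#'
#' Nodes are filled by determinant category, edge labels carry the MI
#' asterisks (1-3), and edge penwidth encodes the stability band (1-4).
#'
#' @param frag an annotated `pabn_fragment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragment_dot <- function(frag, path) {
  cat_of <- concept_category(node_concept(frag$structure$nodes))
  nodes <- sprintf('  "%s" [style=filled, fillcolor="%s"];',
                   frag$structure$nodes, CATEGORY_FILL[cat_of])
  edges <- if (nrow(frag$arcs)) sprintf(
    '  "%s" -> "%s" [label="%s", penwidth=%d];',
    frag$arcs$from, frag$arcs$to,
    strrep("*", ifelse(is.na(frag$arcs$mi_band), 0L, frag$arcs$mi_band)),
    ifelse(is.na(frag$arcs$width_band), 1L, frag$arcs$width_band))
  writeLines(c("digraph fragment {", "  rankdir=LR;", nodes, edges, "}"), path)
  invisible(path)
}
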