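# Synthetic multi-study cohorts with known ground-truth network structure.
#
# The generator emulates the *statistical shape* of an integrated database
# of five PA intervention trials: the variable inventory (demographics,
# intervention indicator, eleven socio-cognitive determinant concept scales
# over four measurement waves, a minutes-per-week PA outcome), the
# per-study measurement-availability blocks that create design missingness
# on integration, and intervention effects that propagate through
# determinants to PA.  No attempt is made to match the real studies'
# observed moments: determinant scales are linear-Gaussian clipped to their
# 1-5 (intention: 1-10) range, PA is linear-Gaussian truncated at 0.

# measurement availability: concept -> tier -> studies measuring it
TABLE_AVAILABILITY <- list(
  self_efficacy        = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = 5, T3 = 4),
  attitude             = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = 5, T3 = 4),
  intrinsic_motivation = list(T0 = c(1, 2, 5), T1 = c(1, 2), T2 = 5),
  intention            = list(T0 = 1:5, T1 = 1:3, T2 = c(1, 2, 4, 5), T3 = c(1, 2, 4, 5)),
  commitment           = list(T0 = c(1, 2), T1 = c(1, 2), T2 = c(1, 2)),
  strategic_planning   = list(T0 = 1:5, T1 = c(1, 2), T2 = c(1, 2, 5), T3 = c(1, 4)),
  action_planning      = list(T0 = c(1, 2, 5), T1 = c(1, 2), T2 = c(1, 2, 5)),
  coping_planning      = list(T0 = c(1, 2, 5), T1 = c(1, 2), T2 = c(1, 2, 5)),
  habit                = list(T0 = c(1, 2, 4, 5), T2 = c(1, 2, 4, 5), T3 = c(1, 2, 4, 5)),
  social_modelling     = list(T0 = 1:5, T1 = 1:3, T2 = c(1, 3), T3 = 4),
  social_support       = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = c(3, 5), T3 = 4),
  pa                   = list(T0 = 1:5, T1 = c(1, 2, 3, 5), T2 = 1:5, T3 = c(1, 2, 4, 5))
)

STUDY_SIZES <- c(`1` = 1976, `2` = 2140, `3` = 766, `4` = 623, `5` = 478)

#' Determinant category of a concept (for fragment colouring)
#' @param concept concept label(s).
#' @return `"pre-motivational"`, `"motivational"`, `"post-motivational"`,
#'   `"outcome"`, `"intervention"`, `"demographic"` or `"other"`.
#' @export
concept_category <- function(concept) {
  map <- c(age = "demographic", gender = "demographic", education = "demographic",
           intervention = "intervention", pa = "outcome",
           social_modelling = "pre-motivational", social_support = "pre-motivational",
           self_efficacy = "motivational", attitude = "motivational",
           intrinsic_motivation = "motivational", intention = "motivational",
           commitment = "post-motivational", strategic_planning = "post-motivational",
           action_planning = "post-motivational", coping_planning = "post-motivational",
           habit = "post-motivational")
  out <- unname(map[concept])
  out[is.na(out)] <- "other"
  out
}

measured_name <- function(concept, tier) paste0(concept, "_", tier)

# variable inventory shared by both ground truths
demographic_variables <- function() {
  variable_table(
    variable_spec("age", "age", "static", "demographic", "continuous", range = c(34, 98)),
    variable_spec("gender", "gender", "static", "demographic", "discrete",
                  levels = c("male", "female")),
    variable_spec("education", "education", "static", "demographic", "discrete",
                  levels = c("low", "medium", "high")),
    variable_spec("intervention", "intervention", "static", "intervention",
                  "discrete", levels = c("control", "intervention")))
}

inventory_variables <- function(availability = TABLE_AVAILABILITY) {
  specs <- list(demographic_variables())
  for (concept in names(availability)) for (tier in names(availability[[concept]])) {
    role <- if (tier == "T0") "baseline"
            else if (concept == "pa") "outcome" else "determinant"
    rng <- if (concept == "pa") c(0, Inf)
           else if (concept == "intention") c(1, 10) else c(1, 5)
    specs[[length(specs) + 1L]] <-
      variable_spec(measured_name(concept, tier), concept, tier, role,
                    "continuous", range = rng)
  }
  do.call(variable_table, specs)
}

# ---- parameter construction -----------------------------------------------
# node_info: per continuous node a (mean, sd); arcs carry standardized
# weights; discrete parents act as mean shifts in child-SD units.  Residual
# variance keeps the marginal SD near its nominal value down chains.

build_truth_params <- function(variables, arcs, moments, weights, shifts, probs) {
  net <- network_structure(variables$name, arcs)
  pl <- parent_list(net)
  nodes <- lapply(stats::setNames(variables$name, variables$name), function(nd) {
    row <- var_row(variables, nd)
    if (row$vtype == "discrete") {
      lev <- row$levels[[1L]]
      abort_if(length(pl[[nd]]) > 0L, "discrete truth nodes must be roots here")
      cg_node_discrete(lev, cpt = matrix(probs[[nd]], 1L))
    } else {
      m <- moments[[nd]][1L]; s <- moments[[nd]][2L]
      par <- pl[[nd]]
      disc <- par[vapply(par, function(p) is_discrete_var(variables, p), TRUE)]
      cont <- setdiff(par, disc)
      dpl <- lapply(stats::setNames(disc, disc),
                    function(p) var_row(variables, p)$levels[[1L]])
      grid <- config_grid(dpl)
      q <- n_configs(dpl)
      w <- vapply(cont, function(p) weights[[paste0(p, "->", nd)]], 0)
      coef_c <- if (length(cont))
        w * s / vapply(cont, function(p) moments[[p]][2L], 0) else numeric(0)
      base_int <- m - if (length(cont))
        sum(coef_c * vapply(cont, function(p) moments[[p]][1L], 0)) else 0
      coef <- matrix(0, q, 1L + length(cont))
      shift_var <- 0
      intercepts <- rep(base_int, q)
      for (p in disc) {
        sh <- shifts[[paste0(p, "->", nd)]]          # per-level shift, SD units
        intercepts <- intercepts + s * sh[match(grid[[p]], names(sh))]
        pr <- probs[[p]]
        shift_var <- shift_var + s^2 * (sum(pr * sh^2) - sum(pr * sh)^2)
      }
      coef[, 1L] <- intercepts
      if (length(cont)) coef[, -1L] <- matrix(coef_c, q, length(cont), byrow = TRUE)
      par_var <- if (length(cont)) sum(coef_c^2 *
        vapply(cont, function(p) moments[[p]][2L], 0)^2) else 0
      sigma2 <- max(s^2 - par_var - shift_var, (0.45 * s)^2)
      cg_node_gaussian(disc, dpl, cont, coef, sigma2)
    }
  })
  cg_params(nodes)
}

new_truth <- function(variables, arcs, parameters, study_designs,
                      extra_missing_rate) {
  dag <- network_structure(variables$name, arcs)
  cons <- build_constraints(variables)
  abort_if(!satisfies_constraints(dag, cons),
           "ground-truth DAG violates the constraint system")
  for (d in study_designs)
    abort_if(!all(variables$name[variables$role %in% c("demographic", "intervention")]
                  %in% d$measured),
             "availability masks must keep demographics and the intervention")
  structure(list(variables = variables, true_dag = dag, parameters = parameters,
                 study_designs = study_designs,
                 extra_missing_rate = extra_missing_rate),
            class = "pabn_truth")
}

#' @export
print.pabn_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d variables, %d true arcs, %d studies, extra MCAR %.0f%%\n",
              nrow(x$variables), nrow(x$true_dag$arcs),
              length(x$study_designs), 100 * x$extra_missing_rate))
  invisible(x)
}

#' Default multi-study ground truth
#'
#' Builds the full synthetic-study specification: the complete variable
#' inventory (3 demographics, the intervention indicator, 11 determinant
#' concepts at the waves where any study measured them, PA at all four
#' waves), a constraint-respecting ground-truth DAG in which the
#' intervention influences determinants which influence PA (with multi-arc
#' mediation paths into PA at both T2 and T3), conditional-Gaussian
#' parameters, and five study designs whose availability masks and relative
#' sizes reproduce the multi-study measurement pattern.  Deterministic: the
#' seed is recorded for downstream stages but the specification itself is a
#' fixed design.
#'
#' @param seed non-negative integer seed recorded in the spec.
#' @param scale factor applied to the five studies' nominal sizes
#'   (default 0.2, keeping desk-scale runtimes).
#' @param extra_missing_rate record-level MCAR rate added on top of the
#'   design missingness (default 0.05).
#' @return a `pabn_truth` object.
#' @export
build_default_truth <- function(seed = 0L, scale = 0.2,
                                extra_missing_rate = 0.05) {
  abort_if(!(seed >= 0), "seed must be a non-negative integer")
  variables <- inventory_variables()
  nm <- variables$name

  auto_arcs <- do.call(rbind, lapply(names(TABLE_AVAILABILITY), function(cpt) {
    tiers <- names(TABLE_AVAILABILITY[[cpt]])
    if (length(tiers) < 2L) return(NULL)
    cbind(from = measured_name(cpt, utils::head(tiers, -1L)),
          to = measured_name(cpt, tiers[-1L]))
  }))
  extra_arcs <- rbind(
    c("education", "self_efficacy_T0"),
    c("age", "pa_T0"),
    c("gender", "habit_T0"),
    c("attitude_T0", "intention_T0"),
    c("self_efficacy_T0", "intention_T0"),
    c("intention_T0", "pa_T0"),
    c("habit_T0", "pa_T0"),
    c("social_modelling_T0", "social_support_T0"),
    c("intervention", "self_efficacy_T1"),
    c("intervention", "attitude_T1"),
    c("intervention", "action_planning_T1"),
    c("intervention", "social_support_T1"),
    c("intervention", "intrinsic_motivation_T1"),
    c("intervention", "intention_T2"),
    c("intervention", "habit_T2"),
    c("intervention", "pa_T2"),
    c("intervention", "pa_T3"),
    c("social_modelling_T1", "social_support_T1"),
    c("social_support_T2", "intrinsic_motivation_T2"),
    c("intrinsic_motivation_T2", "strategic_planning_T2"),
    c("action_planning_T2", "strategic_planning_T2"),
    c("coping_planning_T2", "strategic_planning_T2"),
    c("self_efficacy_T2", "intention_T2"),
    c("attitude_T2", "intention_T2"),
    c("commitment_T2", "intention_T2"),
    c("strategic_planning_T2", "habit_T2"),
    c("intention_T2", "pa_T2"),
    c("habit_T2", "pa_T2"),
    c("attitude_T2", "pa_T3"),
    c("commitment_T2", "intention_T3"),
    c("intention_T3", "pa_T3"))
  colnames(extra_arcs) <- c("from", "to")
  arcs <- unique(rbind(auto_arcs, extra_arcs))

  moments <- lapply(stats::setNames(nm, nm), function(v) {
    cpt <- var_row(variables, v)$concept
    switch(cpt,
           age = c(65, 9.32),
           pa = c(500, 250),
           intention = c(6, 1.8),
           c(3.4, 0.7))
  })
  weights <- lapply(stats::setNames(paste0(arcs[, 1L], "->", arcs[, 2L]),
                                    paste0(arcs[, 1L], "->", arcs[, 2L])),
                    function(k) 0.30)
  for (k in paste0(auto_arcs[, 1L], "->", auto_arcs[, 2L])) weights[[k]] <- 0.55
  weights[["age->pa_T0"]] <- -0.15
  for (k in c("intention_T0->pa_T0", "habit_T0->pa_T0", "intention_T2->pa_T2",
              "habit_T2->pa_T2", "intention_T3->pa_T3", "attitude_T2->pa_T3"))
    weights[[k]] <- 0.25
  shifts <- list(
    `education->self_efficacy_T0` = c(low = 0, medium = 0.15, high = 0.3),
    `gender->habit_T0` = c(male = 0, female = 0.2))
  for (k in grep("^intervention->", names(weights), value = TRUE))
    shifts[[k]] <- c(control = 0, intervention = 0.35)
  shifts[["intervention->pa_T2"]] <- c(control = 0, intervention = 0.30)
  shifts[["intervention->pa_T3"]] <- c(control = 0, intervention = 0.20)
  probs <- list(gender = c(0.45, 0.55), education = c(0.35, 0.40, 0.25),
                intervention = c(1570, 4405) / 5975)

  params <- build_truth_params(variables, arcs, moments, weights, shifts, probs)

  static_vars <- nm[variables$role %in% c("demographic", "intervention")]
  designs <- lapply(names(STUDY_SIZES), function(s) {
    meas <- c(static_vars, unlist(lapply(names(TABLE_AVAILABILITY), function(cpt) {
      tiers <- names(TABLE_AVAILABILITY[[cpt]])
      tiers <- tiers[vapply(tiers, function(t)
        as.integer(s) %in% TABLE_AVAILABILITY[[cpt]][[t]], TRUE)]
      measured_name(cpt, tiers)
    }), use.names = FALSE))
    list(study_id = s,
         n_participants = max(1L, as.integer(round(STUDY_SIZES[[s]] * scale))),
         measured = meas)
  })
  truth <- new_truth(variables, arcs, params, designs, extra_missing_rate)
  truth$seed <- as.integer(seed)
  truth
}

#' Compact tiered ground truth for methodological experiments
#'
#' A 14-node truth -- intervention, four determinant concepts (attitude,
#' self-efficacy, intention, habit) over waves T1-T3, and PA at T1-T3 --
#' with moderate standardized effects (autoregressive 0.55, cross-concept
#' 0.40, intervention shifts 0.35-0.5 SD) and a single full-availability
#' study, so structure-recovery and bootstrap experiments run at desk
#' scale.  Includes multi-arc mediation paths from the intervention into PA
#' at T2 and T3.
#'
#' @inheritParams build_default_truth
#' @param extra_missing_rate record-level MCAR rate (default 0.2, the
#'   missing-data stress level used in the EM degradation experiments).
#' @return a `pabn_truth` object.
#' @export
build_compact_truth <- function(seed = 0L, extra_missing_rate = 0.2) {
  specs <- list(variable_spec("intervention", "intervention", "static",
                              "intervention", "discrete",
                              levels = c("control", "intervention")))
  for (cpt in c("attitude", "self_efficacy", "intention", "habit"))
    for (t in c("T1", "T2", if (cpt %in% c("intention", "habit")) "T3"))
      specs[[length(specs) + 1L]] <-
        variable_spec(measured_name(cpt, t), cpt, t, "determinant",
                      "continuous", range = if (cpt == "intention") c(1, 10) else c(1, 5))
  for (t in c("T1", "T2", "T3"))
    specs[[length(specs) + 1L]] <-
      variable_spec(measured_name("pa", t), "pa", t, "outcome",
                    "continuous", range = c(0, Inf))
  variables <- do.call(variable_table, specs)

  arcs <- rbind(
    c("intervention", "attitude_T1"), c("intervention", "self_efficacy_T1"),
    c("intervention", "habit_T1"), c("intervention", "pa_T2"),
    c("attitude_T1", "intention_T1"), c("self_efficacy_T1", "intention_T1"),
    c("intention_T1", "pa_T1"),
    c("attitude_T1", "attitude_T2"), c("self_efficacy_T1", "self_efficacy_T2"),
    c("intention_T1", "intention_T2"), c("habit_T1", "habit_T2"),
    c("pa_T1", "pa_T2"),
    c("attitude_T2", "intention_T2"), c("intention_T2", "pa_T2"),
    c("habit_T2", "pa_T2"),
    c("intention_T2", "intention_T3"), c("habit_T2", "habit_T3"),
    c("intention_T3", "pa_T3"), c("habit_T3", "pa_T3"), c("pa_T2", "pa_T3"))
  colnames(arcs) <- c("from", "to")

  nm <- variables$name
  moments <- lapply(stats::setNames(nm, nm), function(v) {
    cpt <- var_row(variables, v)$concept
    switch(cpt, pa = c(500, 250), intention = c(6, 1.8), c(3.4, 0.7))
  })
  keys <- paste0(arcs[, 1L], "->", arcs[, 2L])
  weights <- lapply(stats::setNames(keys, keys), function(k) 0.40)
  auto <- vapply(strsplit(keys, "->", fixed = TRUE), function(p) {
    sub("_T[0-9]$", "", p[1L]) == sub("_T[0-9]$", "", p[2L])
  }, TRUE)
  for (k in keys[auto]) weights[[k]] <- 0.55
  shifts <- list()
  for (k in grep("^intervention->", keys, value = TRUE))
    shifts[[k]] <- c(control = 0, intervention = 0.5)
  shifts[["intervention->pa_T2"]] <- c(control = 0, intervention = 0.35)
  probs <- list(intervention = c(1570, 4405) / 5975)

  params <- build_truth_params(variables, arcs, moments, weights, shifts, probs)
  designs <- list(list(study_id = "1", n_participants = 2000L, measured = nm))
  truth <- new_truth(variables, arcs, params, designs, extra_missing_rate)
  truth$seed <- as.integer(seed)
  truth
}

#' Simulate a complete cohort from a ground truth
#'
#' Ancestral sampling from the truth's DAG and parameters; continuous
#' determinant scales are clipped to their declared range afterwards and PA
#' is truncated at 0 (its declared lower bound).  Records are allocated to
#' studies proportionally to the design sizes and carry a `study_id`
#' column.  Exactly reproducible from `(spec, n, seed)`.
#'
#' @param spec a `pabn_truth`.
#' @param n number of records (default: the sum of the design sizes).
#' @param seed integer seed.
#' @return a complete data.frame with a trailing `study_id` factor column.
#' @export
simulate_cohort <- function(spec, n = NULL, seed = 0L) {
  abort_if(!inherits(spec, "pabn_truth"), "need a pabn_truth")
  sizes <- vapply(spec$study_designs, `[[`, 0L, "n_participants")
  ids <- vapply(spec$study_designs, `[[`, "", "study_id")
  if (is.null(n)) n <- sum(sizes)
  abort_if(n < 1L, "n must be >= 1")
  alloc <- floor(n * sizes / sum(sizes))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  tab <- sample_network(spec$true_dag, spec$parameters, n,
                        seed = derive_seed(seed, 101L))
  for (v in spec$variables$name[spec$variables$vtype == "continuous"]) {
    rng <- var_row(spec$variables, v)$range[[1L]]
    tab[[v]] <- pmin(pmax(tab[[v]], rng[1L]), rng[2L])
  }
  tab$study_id <- factor(rep(ids, alloc), levels = ids)
  tab
}

#' Apply design-block and extra MCAR missingness
#'
#' Every cell whose variable the record's study never measured is set
#' missing; each remaining determinant/outcome/baseline cell is
#' additionally masked independently with probability
#' `spec$extra_missing_rate`.  Demographics and the intervention indicator
#' are never masked.
#'
#' @param table a cohort with a `study_id` column ([simulate_cohort()]).
#' @param spec the `pabn_truth` whose study designs apply.
#' @param seed integer seed for the MCAR layer.
#' @return the table with `NA` missing markers.
#' @export
apply_missingness <- function(table, spec, seed = 0L) {
  abort_if(!"study_id" %in% names(table), "table needs a study_id column")
  ids <- vapply(spec$study_designs, `[[`, "", "study_id")
  unknown <- setdiff(unique(as.character(table$study_id)), ids)
  abort_if(length(unknown) > 0L,
           sprintf("unknown study_id: %s", paste(unknown, collapse = ", ")))
  set.seed(derive_seed(seed, 202L))
  protected <- spec$variables$name[spec$variables$role %in%
                                     c("demographic", "intervention")]
  for (d in spec$study_designs) {
    rows <- which(as.character(table$study_id) == d$study_id)
    if (!length(rows)) next
    for (v in setdiff(spec$variables$name, union(d$measured, protected)))
      table[rows, v] <- NA
  }
  if (spec$extra_missing_rate > 0) {
    eligible <- setdiff(spec$variables$name, protected)
    for (v in eligible) {
      obs <- which(!is.na(table[[v]]))
      mask <- obs[stats::runif(length(obs)) < spec$extra_missing_rate]
      if (length(mask)) table[mask, v] <- NA
    }
  }
  table
}

#' Write a cohort as CSV with its ground-truth sidecar
#'
#' The CSV uses an empty field as the missing marker; the JSON sidecar
#' stores the full `pabn_truth` (variables, arcs, parameters, study
#' designs) so test oracles can be rebuilt from disk.
#'
#' @param table cohort data.frame.
#' @param spec the generating `pabn_truth`.
#' @param csv_path,spec_path output paths.
#' @return `csv_path`, invisibly.
#' @export
write_cohort <- function(table, spec, csv_path, spec_path) {
  utils::write.csv(table, csv_path, row.names = FALSE, na = "")
  write_truth(spec, spec_path)
  invisible(csv_path)
}

#' Serialize a ground truth to JSON and back
#' @param spec a `pabn_truth`.
#' @param path file path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the `pabn_truth`.
#' @export
write_truth <- function(spec, path) {
  lst <- list(
    variables = lapply(seq_len(nrow(spec$variables)), function(i) {
      v <- spec$variables[i, ]
      list(name = v$name, concept = v$concept, tier = v$tier, role = v$role,
           vtype = v$vtype, levels = v$levels[[1L]], range = v$range[[1L]])
    }),
    arcs = apply(spec$true_dag$arcs, 1L, as.list),
    parameters = params_to_list(spec$parameters),
    study_designs = spec$study_designs,
    extra_missing_rate = spec$extra_missing_rate,
    seed = spec$seed %||% 0L)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  variables <- do.call(variable_table, lapply(lst$variables, function(v) {
    if (identical(v$vtype, "discrete"))
      variable_spec(v$name, v$concept, v$tier, v$role, v$vtype,
                    levels = as.character(unlist(v$levels)))
    else
      variable_spec(v$name, v$concept, v$tier, v$role, v$vtype,
                    range = as.numeric(unlist(v$range)))
  }))
  arcs <- do.call(rbind, lapply(lst$arcs, function(a)
    c(from = a$from, to = a$to)))
  designs <- lapply(lst$study_designs, function(d)
    list(study_id = d$study_id, n_participants = as.integer(d$n_participants),
         measured = as.character(unlist(d$measured))))
  truth <- new_truth(variables, arcs, params_from_list(lst$parameters),
                     designs, as.numeric(lst$extra_missing_rate))
  truth$seed <- as.integer(lst$seed)
  truth
}
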