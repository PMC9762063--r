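# Synthetic-cohort generator: ground truths, sampling, missingness.

test_that("the default truth matches the multi-study measurement design", {
  tr <- build_default_truth(seed = 0)
  cons <- build_constraints(tr$variables)
  expect_true(satisfies_constraints(tr$true_dag, cons))
  # no arc ever points to an earlier wave
  tier <- stats::setNames(pabn:::tier_index(tr$variables$tier), tr$variables$name)
  from_t <- tier[tr$true_dag$arcs[, 1]]
  to_t <- tier[tr$true_dag$arcs[, 2]]
  both <- !is.na(from_t) & !is.na(to_t)
  expect_true(all(from_t[both] <= to_t[both]))
  # the intervention node's parents are demographics/baseline only (here: none)
  expect_true(all(parents_of(tr$true_dag, "intervention") %in%
                  tr$variables$name[tr$variables$role %in% c("demographic", "baseline")]))
  # mediation paths: intervention reaches PA at T2 and T3 via >= 2 arcs
  ch <- pabn:::children_list(tr$true_dag)
  reach <- pabn:::reachable_from(ch, "intervention")
  expect_true(all(c("pa_T2", "pa_T3") %in% reach))
  kids <- children_of(tr$true_dag, "intervention")
  expect_true(any(vapply(setdiff(kids, c("pa_T2", "pa_T3")), function(k)
    any(c("pa_T2", "pa_T3") %in% pabn:::reachable_from(ch, k)), TRUE)))
  # five studies; masks never hide demographics or the intervention
  expect_length(tr$study_designs, 5L)
  prot <- c("age", "gender", "education", "intervention")
  for (d in tr$study_designs) expect_true(all(prot %in% d$measured))
  # study 3 has no 12-month wave
  s3 <- tr$study_designs[[3]]
  expect_false(any(grepl("_T3$", s3$measured)))
  # study-indexed availability: habit unmeasured at baseline in study 3 only
  habit0 <- vapply(tr$study_designs, function(d) "habit_T0" %in% d$measured, TRUE)
  expect_identical(habit0, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # determinism
  expect_identical(build_default_truth(seed = 0), build_default_truth(seed = 0))
})

test_that("every variable appears exactly once and concepts are categorised", {
  tr <- build_default_truth()
  expect_false(anyDuplicated(tr$variables$name) > 0)
  expect_setequal(unique(tr$variables$concept[tr$variables$role == "determinant"]),
                  setdiff(names(pabn:::TABLE_AVAILABILITY), "pa"))
  expect_equal(concept_category(c("habit", "intention", "social_support", "pa")),
               c("post-motivational", "motivational", "pre-motivational", "outcome"))
})

test_that("cohort simulation is reproducible and respects declared ranges", {
  tr <- build_default_truth(scale = 0.05)
  d1 <- simulate_cohort(tr, 400, seed = 1)
  d2 <- simulate_cohort(tr, 400, seed = 1)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 400L)
  expect_false(anyNA(d1))
  expect_true(all(d1$intention_T0 >= 1 & d1$intention_T0 <= 10))
  expect_true(all(d1$habit_T0 >= 1 & d1$habit_T0 <= 5))
  expect_true(all(d1$pa_T2 >= 0))
  one <- simulate_cohort(tr, 1, seed = 7)
  expect_equal(nrow(one), 1L)
  expect_false(anyNA(one))
})

test_that("root moments and graph independences hold in large samples", {
  tr <- build_compact_truth()
  d <- simulate_cohort(tr, 5000, seed = 1)
  # attitude_T1 given control: mean 3.4 - 0.5*0.7*P? no: control config mean is
  # the nominal mean minus nothing; check within 3 SE of the parameterized value
  ctrl <- d$attitude_T1[d$intervention == "control"]
  mu <- tr$parameters$attitude_T1$coef[1, 1]
  s <- sqrt(tr$parameters$attitude_T1$sigma2[1])
  expect_lt(abs(mean(ctrl) - mu), 3 * s / sqrt(length(ctrl)) + 0.01)

  # arc-free roots are empirically uncorrelated at n = 10000
  net <- network_structure(c("u", "v"))
  params <- cg_params(list(u = cg_node_gaussian(coef = 0, sigma2 = 1),
                           v = cg_node_gaussian(coef = 0, sigma2 = 1)))
  big <- sample_network(net, params, 10000, seed = 2)
  expect_lt(abs(cor(big$u, big$v)), 0.05)
})

test_that("a deterministic arc copies its parent column", {
  vars <- variable_table(
    variable_spec("x", "x", "T1", "determinant", "continuous", range = c(-99, 99)),
    variable_spec("y", "y", "T2", "determinant", "continuous", range = c(-99, 99)))
  dag <- network_structure(c("x", "y"), rbind(c("x", "y")))
  params <- cg_params(list(
    x = cg_node_gaussian(coef = 0, sigma2 = 1),
    y = cg_node_gaussian(cparents = "x", coef = c(0, 1), sigma2 = 0)))
  truth <- structure(list(variables = vars, true_dag = dag, parameters = params,
                          study_designs = list(list(study_id = "1",
                                                    n_participants = 10L,
                                                    measured = vars$name)),
                          extra_missing_rate = 0, seed = 0L),
                     class = "pabn_truth")
  d <- simulate_cohort(truth, 50, seed = 3)
  expect_identical(d$x, d$y)
})

test_that("missingness follows the study design plus the MCAR layer", {
  tr <- build_default_truth(scale = 0.05)
  d <- simulate_cohort(tr, 500, seed = 4)
  dm <- apply_missingness(d, tr, seed = 5)
  # design blocks: variables a study never measured are fully missing there
  for (des in tr$study_designs) {
    rows <- dm$study_id == des$study_id
    if (!any(rows)) next
    unmeasured <- setdiff(tr$variables$name, des$measured)
    for (v in utils::head(unmeasured, 5))
      expect_true(all(is.na(dm[rows, v])))
  }
  # demographics and the intervention are never masked
  expect_false(anyNA(dm[c("age", "gender", "education", "intervention")]))
  expect_error(apply_missingness(transform(d, study_id = factor("9")), tr),
               "unknown study_id")
})

test_that("zero extra missingness under full availability leaves data unchanged", {
  tr <- build_compact_truth(extra_missing_rate = 0)
  d <- simulate_cohort(tr, 200, seed = 6)
  expect_identical(apply_missingness(d, tr, seed = 7), d)
})

test_that("the MCAR layer masks eligible cells at the configured rate", {
  tr <- build_compact_truth(extra_missing_rate = 0.2)
  d <- simulate_cohort(tr, 10000, seed = 8)
  dm <- apply_missingness(d, tr, seed = 9)
  eligible <- setdiff(tr$variables$name, "intervention")
  frac <- mean(is.na(as.matrix(dm[eligible])))
  expect_lt(abs(frac - 0.2), 0.01)
})

test_that("cohorts and their ground truth round-trip through CSV + JSON", {
  tr <- build_compact_truth()
  d <- apply_missingness(simulate_cohort(tr, 60, seed = 10), tr, seed = 11)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cohort(d, tr, csv, js)
  tr2 <- read_truth(js)
  expect_identical(pabn:::arc_keys(tr2$true_dag), pabn:::arc_keys(tr$true_dag))
  expect_equal(tr2$parameters, tr$parameters, tolerance = 1e-12)
  expect_identical(vapply(tr2$study_designs, `[[`, "", "study_id"),
                   vapply(tr$study_designs, `[[`, "", "study_id"))
  back <- utils::read.csv(csv, na.strings = "", stringsAsFactors = FALSE)
  expect_equal(nrow(back), 60L)
  expect_equal(back$attitude_T1, d$attitude_T1, tolerance = 1e-10)
})
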