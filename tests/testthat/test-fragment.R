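# Path-fragment extraction and mutual-information annotation.

avg_from <- function(entries, nodes, threshold = 0.6) {
  conf <- structure(list(entries = entries, n_boot = 100L, nodes = nodes),
                    class = "pabn_arc_confidence")
  average_network(conf, threshold)
}

test_that("the fragment keeps exactly the arcs on source-target paths", {
  entries <- data.frame(from = c("I", "X", "I", "Z"),
                        to = c("X", "PA2", "PA2", "PA2"),
                        frequency = c(0.9, 0.9, 0.9, 0.9),
                        stringsAsFactors = FALSE)
  frag <- extract_fragment(avg_from(entries, c("I", "X", "Z", "PA2")),
                           "I", "PA2")
  expect_setequal(paste(frag$arcs$from, frag$arcs$to, sep = "->"),
                  c("I->X", "X->PA2", "I->PA2"))
  expect_false("Z" %in% frag$structure$nodes)
  expect_error(extract_fragment(avg_from(entries, c("I", "X", "Z", "PA2")),
                                "I", c("I", "PA2")), "source")
})

test_that("an unreachable target yields the empty fragment", {
  entries <- data.frame(from = "X", to = "PA2", frequency = 0.9,
                        stringsAsFactors = FALSE)
  frag <- extract_fragment(avg_from(entries, c("I", "X", "PA2")), "I", "PA2")
  expect_equal(nrow(frag$arcs), 0L)
  expect_equal(length(frag$structure$nodes), 0L)
})

test_that("fragment extraction matches exhaustive path enumeration on random tiered DAGs", {
  set.seed(1)
  for (trial in 1:100) {
    k1 <- sample(2:4, 1); k2 <- sample(2:4, 1)
    t1 <- paste0("a", seq_len(k1)); t2 <- paste0("b", seq_len(k2))
    nodes <- c("I", t1, t2, "PA")
    # tier-ordered random DAG: arcs only from earlier to later groups or
    # lexicographically forward within a group (guarantees acyclicity)
    ord <- c("I", t1, t2, "PA")
    arcs <- NULL
    for (i in seq_along(ord)) for (j in seq_along(ord)) {
      if (i < j && runif(1) < 0.3) arcs <- rbind(arcs, c(ord[i], ord[j]))
    }
    freq <- runif(NROW(arcs) %||% 0, 0.6, 1)
    entries <- if (is.null(arcs))
      data.frame(from = character(0), to = character(0), frequency = numeric(0))
    else data.frame(from = arcs[, 1], to = arcs[, 2], frequency = freq,
                    stringsAsFactors = FALSE)
    frag <- extract_fragment(avg_from(entries, nodes), "I", "PA")
    got <- sort(paste(frag$arcs$from, frag$arcs$to, sep = "->"))
    want <- oracle_fragment_arcs(nodes, arcs %||% matrix(character(0), 0, 2),
                                 "I", "PA")
    expect_identical(got, want, info = sprintf("trial %d", trial))
  }
})

test_that("fragment extraction is idempotent and monotone in the threshold", {
  set.seed(2)
  entries <- data.frame(
    from = c("I", "I", "X", "Y", "X", "I"),
    to = c("X", "Y", "PA", "PA", "Y", "PA"),
    frequency = c(0.65, 0.72, 0.85, 0.95, 0.61, 0.78),
    stringsAsFactors = FALSE)
  nodes <- c("I", "X", "Y", "PA")
  frag6 <- extract_fragment(avg_from(entries, nodes), "I", "PA", 0.6)
  # re-extract from the fragment's own arcs: same graph
  re <- extract_fragment(
    avg_from(frag6$arcs[c("from", "to", "confidence")] |>
               stats::setNames(c("from", "to", "frequency")), nodes),
    "I", "PA", 0.6)
  expect_setequal(paste(re$arcs$from, re$arcs$to, sep = "->"),
                  paste(frag6$arcs$from, frag6$arcs$to, sep = "->"))
  frag7 <- extract_fragment(avg_from(entries, nodes), "I", "PA", 0.7)
  expect_true(all(paste(frag7$arcs$from, frag7$arcs$to, sep = "->") %in%
                  paste(frag6$arcs$from, frag6$arcs$to, sep = "->")))
})

test_that("jackknife MI matches the analytic Gaussian value and is symmetric", {
  set.seed(3)
  x <- rnorm(2000); y <- 0.6 * x + 0.8 * rnorm(2000)
  expect_equal(jackknife_mi(x, y), jackknife_mi(y, x))
  expect_lt(abs(jackknife_mi(x, y) - (-0.5 * log(1 - 0.36))), 0.03)
  xi <- rnorm(2000); yi <- rnorm(2000)
  expect_lt(jackknife_mi(xi, yi), 0.01)
  expect_gte(jackknife_mi(xi, yi), 0)
})

test_that("jackknife MI handles discrete pairs and input errors", {
  set.seed(4)
  x <- factor(sample(c("a", "b"), 400, TRUE))
  expect_equal(pabn:::mi_plugin(x, x), -sum(prop.table(table(x)) *
                                            log(prop.table(table(x)))) * 1)
  expect_gt(jackknife_mi(x, x), 0.5)   # near ln 2 for near-balanced x
  g <- factor(sample(c("a", "b"), 2000, TRUE))
  z <- rnorm(2000) + 2 * (g == "b")
  expect_gt(jackknife_mi(g, z), 0.2)
  expect_equal(jackknife_mi(g, z), jackknife_mi(z, g))
  expect_error(jackknife_mi(rnorm(5), rnorm(5)), "at least 10")
  expect_error(jackknife_mi(rep(1, 50), rnorm(50)), "zero variance")
  # pairwise complete-case deletion happens before the n check
  xm <- c(rnorm(12), NA, NA); ym <- c(rnorm(12), 1, NA)
  expect_silent(jackknife_mi(xm, ym))
})

test_that("the jackknife correction reduces small-sample bias", {
  true_mi <- -0.5 * log(1 - 0.36)
  res <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    x <- rnorm(50); y <- 0.6 * x + 0.8 * rnorm(50)
    c(jk = jackknife_mi(x, y), plug = pabn:::mi_plugin(x, y))
  }, c(jk = 0, plug = 0))
  expect_lte(abs(mean(res["jk", ]) - true_mi),
             abs(mean(res["plug", ]) - true_mi))
})

test_that("annotation assigns MI bands at the 33/67% quantiles and width bands at 0.7/0.8/0.9", {
  entries <- data.frame(from = c("I", "I", "I", "X"),
                        to = c("X", "Y", "Z", "PA"),
                        frequency = c(0.65, 0.75, 0.85, 0.95),
                        stringsAsFactors = FALSE)
  nodes <- c("I", "X", "Y", "Z", "PA")
  # make Y, Z reach PA so all four arcs are in the fragment
  entries <- rbind(entries,
                   data.frame(from = c("Y", "Z"), to = c("PA", "PA"),
                              frequency = c(0.99, 0.99)))
  set.seed(5)
  n <- 600
  I <- rnorm(n)
  d <- data.frame(I = I,
                  X = 0.9 * I + 0.5 * rnorm(n),   # high MI
                  Y = 0.5 * I + rnorm(n),          # medium
                  Z = 0.1 * I + rnorm(n))          # low
  d$PA <- d$X + 0.3 * d$Y + 0.1 * d$Z + rnorm(n)
  frag <- extract_fragment(avg_from(entries, nodes), "I", "PA")
  frag <- annotate_fragment(frag, d)
  a <- frag$arcs
  expect_equal(a$width_band[match(c("X", "Y", "Z", "PA"), a$to)][1:4],
               c(1L, 2L, 3L, 4L))
  key <- paste(a$from, a$to, sep = "->")
  expect_equal(a$mi_band[key == "I->Z"], 1L)
  expect_equal(a$mi_band[key == "I->X"], 3L)
  expect_true(all(a$mi_band %in% 1:3))
  expect_length(frag$mi_cutoffs, 2L)
  expect_equal(frag$mi_range, range(a$mi))
  # report carries the realized cut-offs: quantiles of the fragment's MIs
  expect_equal(unname(frag$mi_cutoffs),
               unname(quantile(a$mi, c(0.33, 0.67))))
})

test_that("annotation refreshes confidence from a supplied table and bands exactly-on-cutoff values upward", {
  mi_vals <- c(0.05, 0.20, 0.40)
  # synthetic fragment with known MIs via deterministic band check
  entries <- data.frame(from = c("I", "A", "B"), to = c("A", "B", "PA"),
                        frequency = c(0.9, 0.9, 0.9), stringsAsFactors = FALSE)
  nodes <- c("I", "A", "B", "PA")
  frag <- extract_fragment(avg_from(entries, nodes), "I", "PA")
  frag$arcs$mi <- mi_vals
  cuts <- unname(quantile(mi_vals, c(0.33, 0.67)))
  bands <- 1L + (mi_vals >= cuts[1]) + (mi_vals >= cuts[2])
  expect_equal(bands, c(1L, 2L, 3L))
  # a value exactly on a cut-off goes to the higher band
  expect_equal(1L + (cuts[1] >= cuts[1]) + (cuts[1] >= cuts[2]), 2L)
})

test_that("DOT export writes one styled edge per fragment arc", {
  entries <- data.frame(from = c("I", "X"), to = c("X", "pa_T2"),
                        frequency = c(0.95, 0.72), stringsAsFactors = FALSE)
  frag <- extract_fragment(avg_from(entries, c("I", "X", "pa_T2")), "I", "pa_T2")
  set.seed(6)
  d <- data.frame(I = rnorm(100), X = rnorm(100), pa_T2 = rnorm(100))
  frag <- annotate_fragment(frag, d)
  path <- withr::local_tempfile(fileext = ".dot")
  write_fragment_dot(frag, path)
  lines <- readLines(path)
  expect_length(grep("->", lines, fixed = TRUE), 2L)
  expect_length(grep("penwidth", lines), 2L)
  expect_length(grep("fillcolor", lines), 3L)
})
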