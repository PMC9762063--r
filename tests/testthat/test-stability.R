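# Bootstrap arc confidence, structural Hamming distance, stabilisation
# diagnostics and threshold averaging.

make_conf <- function(entries, nodes, n_boot = 100L) {
  structure(list(entries = entries, n_boot = n_boot, nodes = nodes),
            class = "pabn_arc_confidence")
}

test_that("SHD counts insertions, deletions and reversals", {
  g1 <- network_structure(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(shd(g1, g1), 0L)
  g2 <- network_structure(c("a", "b", "c"),
                          rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(shd(g1, g2), 1L)
  g3 <- network_structure(c("a", "b", "c"), rbind(c("b", "a"), c("b", "c")))
  expect_equal(shd(g1, g3), 1L)
  expect_error(shd(g1, network_structure(c("a", "b"))), "node set")
})

test_that("SHD equals the brute-force minimal edit distance on tiny graphs", {
  # breadth-first search over graph space using single-arc edits
  edit_distance <- function(g1, g2) {
    nodes <- g1$nodes
    key <- function(net) paste(sort(pabn:::arc_keys(net)), collapse = ";")
    target <- key(g2)
    if (key(g1) == target) return(0L)
    seen <- key(g1)
    frontier <- list(g1)
    dist <- 0L
    repeat {
      nxt <- list()
      for (g in frontier) {
        for (u in nodes) for (v in nodes) {
          if (u == v) next
          ka <- pabn:::arc_keys(g)
          cand <- NULL
          if (paste0(u, "->", v) %in% ka) {
            rest <- g$arcs[!(g$arcs[, 1] == u & g$arcs[, 2] == v), , drop = FALSE]
            cand <- list(network_structure(nodes, rest),
                         tryCatch(network_structure(nodes, rbind(rest, c(v, u))),
                                  error = function(e) NULL))
          } else {
            cand <- list(tryCatch(network_structure(nodes, rbind(g$arcs, c(u, v))),
                                  error = function(e) NULL))
          }
          for (cnd in cand) {
            if (is.null(cnd)) next
            k <- key(cnd)
            if (k == target) return(dist + 1L)
            if (!k %in% seen) { seen <- c(seen, k); nxt[[length(nxt) + 1L]] <- cnd }
          }
        }
      }
      frontier <- nxt
      dist <- dist + 1L
      if (dist > 10L) stop("edit search exceeded depth 10")
    }
  }
  set.seed(1)
  nodes <- c("a", "b", "c", "d")
  pairs <- t(combn(nodes, 2))
  for (trial in 1:12) {
    rand_dag <- function() {
      sel <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
      flip <- runif(nrow(sel)) < 0.5
      arcs <- cbind(ifelse(flip, sel[, 2], sel[, 1]),
                    ifelse(flip, sel[, 1], sel[, 2]))
      tryCatch(network_structure(nodes, arcs), error = function(e) NULL)
    }
    g1 <- rand_dag(); g2 <- rand_dag()
    if (is.null(g1) || is.null(g2)) next
    expect_equal(shd(g1, g2), edit_distance(g1, g2),
                 info = sprintf("trial %d", trial))
  }
})

test_that("SHD is a metric on random DAG triples", {
  set.seed(2)
  for (trial in 1:200) {
    tr <- lapply(1:3, function(i) {
      nodes <- letters[1:6]
      sel <- t(combn(nodes, 2))
      sel <- sel[runif(nrow(sel)) < 0.3, , drop = FALSE]
      network_structure(nodes, sel)   # upper-triangular orientation: acyclic
    })
    d12 <- shd(tr[[1]], tr[[2]]); d13 <- shd(tr[[1]], tr[[3]])
    d23 <- shd(tr[[2]], tr[[3]])
    expect_equal(shd(tr[[1]], tr[[1]]), 0L)
    expect_equal(d12, shd(tr[[2]], tr[[1]]))
    expect_lte(d13, d12 + d23)
  }
})

test_that("bootstrap frequencies are valid and contain no illegal arc", {
  tr <- random_legal_truth(41)
  d <- sample_network(tr$dag, tr$params, 200, seed = 1)
  learner <- function(dd, s) hill_climb(dd, tr$constraints, seed = s)
  one <- bootstrap_confidence(d, 1L, learner, seed = 2)
  expect_true(all(one$entries$frequency %in% c(0, 1)))
  conf <- bootstrap_confidence(d, 20L, learner, seed = 3)
  expect_true(all(conf$entries$frequency >= 0 & conf$entries$frequency <= 1))
  for (i in seq_len(nrow(conf$entries)))
    expect_true(arc_allowed(tr$constraints, conf$entries$from[i],
                            conf$entries$to[i]))
  expect_equal(arc_confidence(conf, "pa_T2", "base1"), 0)
})

test_that("a strong tier-forced arc is found in nearly every resample", {
  vars <- tiered_variables(t1 = "a", t2 = "b", t3 = character(0),
                           intervention = FALSE)
  cons <- build_constraints(vars)
  set.seed(4)
  a <- rnorm(1000)
  d <- data.frame(a = a, b = 1.2 * a + rnorm(1000))
  conf <- bootstrap_confidence(d, 100L,
                               function(dd, s) hill_climb(dd, cons, seed = s),
                               seed = 5)
  expect_gte(arc_confidence(conf, "a", "b"), 0.9)
})

test_that("learner failures trigger bounded redraws", {
  fails <- new.env(); fails$left <- 2L
  flaky <- function(dd, s) {
    if (fails$left > 0L) { fails$left <- fails$left - 1L; stop("boom") }
    network_structure(names(dd))
  }
  expect_message(
    conf <- bootstrap_confidence(data.frame(x = rnorm(20)), 3L, flaky, seed = 6),
    "redrawing")
  expect_equal(conf$n_boot, 3L)
  always <- function(dd, s) stop("boom")
  expect_error(
    suppressMessages(bootstrap_confidence(data.frame(x = rnorm(20)), 1L,
                                          always, seed = 7, max_retries = 2L)),
    "after 2 retries")
})

test_that("averaging keeps the inclusive 0.60 boundary and repairs cycles", {
  entries <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
                        frequency = c(0.95, 0.60, 0.59),
                        stringsAsFactors = FALSE)
  avg <- average_network(make_conf(entries, c("A", "B", "C")), 0.6)
  expect_setequal(pabn:::arc_keys(avg$structure), c("A->B", "B->C"))

  cyc <- data.frame(from = c("A", "B"), to = c("B", "A"),
                    frequency = c(0.7, 0.65), stringsAsFactors = FALSE)
  avg2 <- average_network(make_conf(cyc, c("A", "B")), 0.6)
  expect_identical(pabn:::arc_keys(avg2$structure), "A->B")
  expect_equal(nrow(avg2$removed), 1L)
  expect_equal(avg2$removed$frequency, 0.65)

  uni <- average_network(make_conf(entries, c("A", "B", "C")), 1)
  expect_equal(nrow(uni$confidence), 0L)
})

test_that("raising the averaging threshold never adds an arc", {
  tr <- random_legal_truth(51)
  d <- sample_network(tr$dag, tr$params, 300, seed = 8)
  conf <- bootstrap_confidence(d, 25L,
                               function(dd, s) hill_climb(dd, tr$constraints, seed = s),
                               seed = 9)
  prev <- NULL
  for (thr in c(0.4, 0.6, 0.8, 1.0)) {
    arcs <- pabn:::arc_keys(average_network(conf, thr)$structure)
    if (!is.null(prev)) expect_true(all(arcs %in% prev))
    prev <- arcs
  }
})

test_that("bootstrap-count selection stabilises and reports its series", {
  vars <- tiered_variables(t1 = "a", t2 = "b", t3 = character(0),
                           intervention = FALSE)
  cons <- build_constraints(vars)
  set.seed(10)
  a <- rnorm(800)
  d <- data.frame(a = a, b = 1.3 * a + rnorm(800))
  learner <- function(dd, s) hill_climb(dd, cons, seed = s)
  sel <- select_n_boot(d, learner, c(5L, 10L, 20L), seed = 11)
  expect_equal(as.integer(sel), 5L)   # every resample yields the same graph
  diag <- attr(sel, "diagnostic")
  expect_equal(nrow(diag), 2L)
  expect_true(all(diag$shd == 0L))
  expect_true(all(diag$shd >= 0L))
})
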