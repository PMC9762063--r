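# Conditional-Gaussian parameterisation: fitting, likelihood, BIC,
# sampling and exact conditional imputation.

test_that("CPT fitting matches empirical frequencies", {
  d <- data.frame(x = factor(c("1", "1", "0", "1"), levels = c("0", "1")))
  net <- network_structure("x")
  p0 <- fit_parameters(net, d, pseudo_count = 0)
  expect_equal(as.numeric(p0$x$cpt), c(0.25, 0.75))
  p1 <- fit_parameters(net, d, pseudo_count = 1)
  expect_equal(as.numeric(p1$x$cpt), c(2, 4) / 6)
})

test_that("continuous locals recover exact and noisy linear dependence", {
  set.seed(1)
  x <- rnorm(200)
  d <- data.frame(x = x, y = 2 * x)
  net <- network_structure(c("x", "y"), rbind(c("x", "y")))
  p <- fit_parameters(net, d)
  expect_equal(unname(p$y$coef[1, ]), c(0, 2), tolerance = 1e-10)
  expect_lt(p$y$sigma2, 1e-20)

  set.seed(2)
  n <- 5000
  x <- rnorm(n)
  d <- data.frame(x = x, y = 1 + 0.5 * x + rnorm(n))
  p <- fit_parameters(net, d)
  se <- 1 / sqrt(n)   # both SEs are ~ sigma/sqrt(n) with sigma = 1, var(x) = 1
  expect_lt(abs(p$y$coef[1, 1] - 1), 3 * se)
  expect_lt(abs(p$y$coef[1, 2] - 0.5), 3 * se)
})

test_that("fitting fails on incomplete data or unpopulated configurations", {
  d <- data.frame(x = c(1, NA), y = c(2, 3))
  net <- network_structure(c("x", "y"), rbind(c("x", "y")))
  expect_error(fit_parameters(net, d), "complete")
  d2 <- data.frame(g = factor(c("a", "a", "a"), levels = c("a", "b")),
                   y = c(1, 2, 3))
  expect_error(fit_parameters(network_structure(c("g", "y"), rbind(c("g", "y"))), d2),
               "insufficient")
})

test_that("log-likelihood matches closed forms and factorization", {
  coin <- cg_params(list(x = cg_node_discrete(c("h", "t"), cpt = c(0.5, 0.5))))
  d <- data.frame(x = factor(c("h", "t", "h", "h"), levels = c("h", "t")))
  expect_equal(log_likelihood(coin, d), 4 * log(0.5))

  std <- cg_params(list(z = cg_node_gaussian(coef = 0, sigma2 = 1)))
  expect_equal(log_likelihood(std, data.frame(z = 0)), -0.5 * log(2 * pi))

  # factorized likelihood equals a directly computed joint density
  set.seed(3)
  net <- network_structure(c("g", "x", "y"), rbind(c("g", "x"), c("x", "y")))
  params <- cg_params(list(
    g = cg_node_discrete(c("a", "b"), cpt = c(0.3, 0.7)),
    x = cg_node_gaussian(dparents = "g", dparent_levels = list(g = c("a", "b")),
                         coef = rbind(c(1), c(-1)), sigma2 = c(1, 2)),
    y = cg_node_gaussian(cparents = "x", coef = c(0.5, 1.5), sigma2 = 0.8)))
  d <- sample_network(net, params, 50, seed = 4)
  direct <- sum(log(ifelse(d$g == "a", 0.3, 0.7)) +
                dnorm(d$x, ifelse(d$g == "a", 1, -1),
                      ifelse(d$g == "a", 1, sqrt(2)), log = TRUE) +
                dnorm(d$y, 0.5 + 1.5 * d$x, sqrt(0.8), log = TRUE))
  expect_equal(log_likelihood(params, d), direct, tolerance = 1e-10)
})

test_that("BIC matches the closed form for a binary root", {
  x <- factor(c(rep("1", 60), rep("0", 40)), levels = c("0", "1"))
  score <- bic_score(network_structure("x"), data.frame(x = x))
  expect_equal(score, 60 * log(0.6) + 40 * log(0.4) - 0.5 * log(100))
})

test_that("BIC decomposes into local scores and is invariant to reordering", {
  set.seed(5)
  tr <- random_legal_truth(11)
  d <- sample_network(tr$dag, tr$params, 300, seed = 6)
  total <- bic_score(tr$dag, d)
  pl <- pabn:::parent_list(tr$dag)
  locals <- vapply(tr$dag$nodes, function(nd)
    bic_local_score(d, nd, pl[[nd]]), 0)
  expect_equal(total, sum(locals), tolerance = 1e-9)
  perm <- sample(nrow(d))
  expect_equal(bic_score(tr$dag, d[perm, rev(names(d))]), total, tolerance = 1e-9)
})

test_that("BIC prefers the generating arc over the empty graph", {
  set.seed(7)
  x <- rnorm(2000); d <- data.frame(x = x, y = 1.2 * x + rnorm(2000))
  arc <- network_structure(c("x", "y"), rbind(c("x", "y")))
  empty <- network_structure(c("x", "y"))
  expect_gt(bic_score(arc, d), bic_score(empty, d))
})

test_that("sampling is reproducible, typed and respects independence", {
  net <- network_structure(c("x", "y"))
  params <- cg_params(list(x = cg_node_gaussian(coef = 0, sigma2 = 1),
                           y = cg_node_gaussian(coef = 0, sigma2 = 1)))
  expect_equal(nrow(sample_network(net, params, 0, seed = 1)), 0)
  d1 <- sample_network(net, params, 10000, seed = 2)
  d2 <- sample_network(net, params, 10000, seed = 2)
  expect_identical(d1, d2)
  expect_lt(abs(cor(d1$x, d1$y)), 0.05)
})

test_that("imputation reproduces exact and analytic conditional means", {
  net <- network_structure(c("x", "y"), rbind(c("x", "y")))
  exact <- cg_params(list(x = cg_node_gaussian(coef = 0, sigma2 = 1),
                          y = cg_node_gaussian(cparents = "x", coef = c(0, 2),
                                               sigma2 = 0)))
  rec <- data.frame(x = 3, y = NA_real_)
  expect_equal(impute_record(net, exact, rec)$y, 6)
  full <- data.frame(x = 1, y = 2)
  expect_identical(impute_record(net, exact, full), full)

  # bivariate normal: impute the PARENT from the child, against the
  # closed-form conditional mean mu_x + rho * (sx / sy) * (y - mu_y)
  b <- 0.8; s2 <- 0.5; mux <- 2; sx2 <- 1.5
  joint <- cg_params(list(
    x = cg_node_gaussian(coef = mux, sigma2 = sx2),
    y = cg_node_gaussian(cparents = "x", coef = c(1, b), sigma2 = s2)))
  sy2 <- b^2 * sx2 + s2
  muy <- 1 + b * mux
  yobs <- 4.2
  expected <- mux + (b * sx2 / sy2) * (yobs - muy)
  got <- impute_record(net, joint, data.frame(x = NA_real_, y = yobs))$x
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("imputation handles missing discrete cells by posterior mode", {
  net <- network_structure(c("g", "x"), rbind(c("g", "x")))
  params <- cg_params(list(
    g = cg_node_discrete(c("a", "b"), cpt = c(0.5, 0.5)),
    x = cg_node_gaussian(dparents = "g", dparent_levels = list(g = c("a", "b")),
                         coef = rbind(c(-2), c(2)), sigma2 = c(1, 1))))
  rec <- data.frame(g = factor(NA, levels = c("a", "b")), x = 2.5)
  expect_equal(as.character(impute_record(net, params, rec)$g), "b")
  rec2 <- data.frame(g = factor(NA, levels = c("a", "b")), x = -2.5)
  expect_equal(as.character(impute_record(net, params, rec2)$g), "a")
})

test_that("fitted parameters maximize the likelihood locally", {
  set.seed(8)
  tr <- random_legal_truth(21)
  d <- sample_network(tr$dag, tr$params, 400, seed = 9)
  fit <- fit_parameters(tr$dag, d, pseudo_count = 0)
  base <- log_likelihood(fit, d)
  for (r in 1:5) {
    pert <- fit
    for (nd in names(pert)) {
      if (pert[[nd]]$type == "continuous") {
        pert[[nd]]$coef <- pert[[nd]]$coef + rnorm(length(pert[[nd]]$coef), 0, 0.05)
      } else {
        cpt <- pmax(pert[[nd]]$cpt + rnorm(length(pert[[nd]]$cpt), 0, 0.03), 1e-3)
        pert[[nd]]$cpt <- cpt / rowSums(cpt)
      }
    }
    expect_lte(base, base)  # anchor
    expect_gte(base, log_likelihood(pert, d))
  }
})

test_that("parameter JSON serialization round-trips to full precision", {
  tr <- random_legal_truth(31)
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(tr$params, path)
  back <- read_parameters(path)
  expect_equal(back, tr$params, tolerance = 1e-12)
})

test_that("sample-then-fit recovers generating parameters within 3 SE", {
  net <- network_structure(c("i", "a", "b"), rbind(c("i", "a"), c("a", "b")))
  truth <- cg_params(list(
    i = cg_node_discrete(c("c", "t"), cpt = c(0.4, 0.6)),
    a = cg_node_gaussian(dparents = "i", dparent_levels = list(i = c("c", "t")),
                         coef = rbind(3, 3.5), sigma2 = c(0.49, 0.49)),
    b = cg_node_gaussian(cparents = "a", coef = c(1, 0.6), sigma2 = 0.25)))
  d <- sample_network(net, truth, 5000, seed = 10)
  fit <- fit_parameters(net, d, pseudo_count = 0)
  expect_lt(abs(fit$i$cpt[1, "t"] - 0.6), 3 * sqrt(0.24 / 5000))
  n_c <- sum(d$i == "c")
  expect_lt(abs(fit$a$coef[1, 1] - 3), 3 * 0.7 / sqrt(n_c))
  se_slope <- 0.5 / (sd(d$a) * sqrt(5000))
  expect_lt(abs(fit$b$coef[1, 2] - 0.6), 3 * se_slope)
})
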