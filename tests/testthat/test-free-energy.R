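test_that("work files parse directions, comments and units", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# fast-growth work samples",
               sprintf("work_f %.3f", c(4, 6, 5)),
               sprintf("work_b %.3f", c(-4, -6))), path)
  ws <- read_work_file(path)
  expect_s3_class(ws, "work_set")
  expect_equal(ws$forward, c(4, 6, 5))
  expect_equal(ws$backward, c(-4, -6))

  # kcal/mol header converts on read
  writeLines(c("units=kcal/mol", "work_f 1.0", "work_f 2.0",
               "work_b -1.0", "work_b -2.0"), path)
  expect_equal(read_work_file(path)$forward, c(4.184, 8.368))

  # a single direction cannot support a bidirectional estimator
  writeLines(sprintf("work_f %.1f", 1:5), path)
  expect_error(read_work_file(path), "each direction")

  # unlabeled rows are rejected
  writeLines(c("work_f 1", "work_f 2", "oops 3", "work_b -1", "work_b -2"), path)
  expect_error(read_work_file(path), "unlabeled|not recognised")
})

test_that("pmx-like paired files read as forward and backward works", {
  fw <- withr::local_tempfile(fileext = ".dat")
  bw <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%d %.3f", 1:4, c(5.1, 5.3, 4.9, 5.0)), fw)
  writeLines(sprintf("%d %.3f", 1:4, c(-4.8, -5.2, -5.1, -4.9)), bw)
  ws <- read_work_file(c(fw, bw), dialect = "pmx_like")
  expect_equal(length(ws$forward), 4L)
  expect_equal(ws$backward[2], -5.2)
  expect_error(read_work_file(fw, dialect = "pmx_like"), "forward_file")
})

test_that("gaussian moments use the unbiased estimator and negate backward works", {
  ws <- work_set(c(4, 6), c(-4, -6))
  g <- fit_gaussians(ws)
  expect_equal(g$forward$mu, 5)
  expect_equal(g$forward$sd, sqrt(2))
  expect_equal(g$reverse$mu, 5)   # negation applied
  expect_equal(g$reverse$n, 2L)
  const <- work_set(c(5, 5, 5), c(-5, -5))
  expect_equal(fit_gaussians(const)$forward$sd, 0)
  expect_equal(tidy(g)$mu, c(5, 5))
})

test_that("zero-dissipation delta works give dG equal to the common value", {
  ws <- work_set(rep(5, 10), rep(-5, 10))
  est <- cgi_estimate(ws, n_boot = 200, seed = 1)
  expect_equal(est$dg, 5)
  expect_equal(est$stderr, 0)
  expect_equal(bar_estimate(ws, n_boot = 0)$dg, 5)
})

test_that("equal variances give the closed-form midpoint of the means", {
  # construct samples with exactly matching variances
  base <- c(-1, 0, 1)
  ws <- work_set(8 + base, -(2 + base))
  g <- fit_gaussians(ws)
  expect_equal(g$forward$sd, g$reverse$sd)
  expect_equal(cgi_estimate(ws, n_boot = 0)$dg, 5)
})

test_that("the unequal-variance root matches a bisection oracle on large samples", {
  withr::with_seed(31, {
    fw <- rnorm(1e4, 10, 2)
    bw <- -rnorm(1e4, 2, 1)
  })
  ws <- work_set(fw, bw)
  est <- cgi_estimate(ws, n_boot = 0)
  g <- fit_gaussians(ws)
  oracle <- cgi_bisection_oracle(g$forward$mu, g$forward$sd,
                                 g$reverse$mu, g$reverse$sd)
  expect_equal(est$dg, oracle, tolerance = 1e-9)
  expect_gt(est$dg, 2); expect_lt(est$dg, 10)
})

test_that("CGI is antisymmetric under exchange of the end states", {
  ws <- simulate_work(6.14, 3, seed = 42)
  swapped <- work_set(ws$backward, ws$forward, temperature = ws$temperature)
  expect_equal(cgi_estimate(swapped, n_boot = 0)$dg,
               -cgi_estimate(ws, n_boot = 0)$dg, tolerance = 1e-9)
  expect_equal(bar_estimate(swapped, n_boot = 0)$dg,
               -bar_estimate(ws, n_boot = 0)$dg, tolerance = 1e-6)
})

test_that("CGI and BAR agree within 0.2 kJ/mol on large Crooks-consistent samples", {
  ws <- simulate_work(6.14, 3, n_forward = 1e4, n_backward = 1e4, seed = 3)
  cgi <- cgi_estimate(ws, n_boot = 0)$dg
  bar <- bar_estimate(ws, n_boot = 0)$dg
  expect_lt(abs(cgi - bar), 0.2)
  expect_equal(cgi, 6.14, tolerance = 0.1)
})

test_that("CGI and BAR bias at n = 100 stays below 0.5 kJ/mol for d <= 3", {
  for (d in c(1, 3)) {
    cgi_err <- mean(vapply(1:20, function(s) {
      ws <- simulate_work(5, d, seed = 1000 + s)
      cgi_estimate(ws, n_boot = 0)$dg - 5
    }, numeric(1)))
    expect_lt(abs(cgi_err), 0.5)
  }
  bar_err <- mean(vapply(1:20, function(s) {
    ws <- simulate_work(5, 3, seed = 2000 + s)
    bar_estimate(ws, n_boot = 0)$dg - 5
  }, numeric(1)))
  expect_lt(abs(bar_err), 0.5)
})

test_that("bootstrap errors are seeded, reproducible, and scale with sigma", {
  ws <- simulate_work(5, 3, seed = 7)
  b1 <- bootstrap_error(ws, "cgi", n_boot = 300, seed = 11)
  b2 <- bootstrap_error(ws, "cgi", n_boot = 300, seed = 11)
  expect_identical(b1$stderr, b2$stderr)
  expect_identical(b1$ci95, b2$ci95)
  expect_error(bootstrap_error(ws, "cgi", n_boot = 50), "at least 100")

  # doubling sigma at fixed n roughly doubles the bootstrap stderr
  ratio <- mean(vapply(1:5, function(s) {
    w1 <- simulate_work(5, 3, sigma = 2, crooks_consistent = FALSE, seed = 300 + s)
    w2 <- simulate_work(5, 3, sigma = 4, crooks_consistent = FALSE, seed = 300 + s)
    bootstrap_error(w2, "cgi", n_boot = 300, seed = s)$stderr /
      bootstrap_error(w1, "cgi", n_boot = 300, seed = s)$stderr
  }, numeric(1)))
  expect_equal(ratio, 2, tolerance = 0.25)
})

test_that("the bootstrap CI covers the planted truth in at least 85% of replications", {
  hits <- vapply(1:200, function(s) {
    ws <- simulate_work(5, 2, seed = s)
    est <- cgi_estimate(ws, n_boot = 100, seed = s)
    est$ci95[1] <= 5 && 5 <= est$ci95[2]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("double differences follow ddG = dG1 - dG2 with quadrature errors", {
  mk <- function(dg, se) structure(
    list(dg = dg, stderr = se, ci95 = dg + c(-2, 2) * se, method = "CGI",
         n_forward = 100, n_backward = 100, temperature = 298.15, label = "",
         diagnostics = list()), class = "free_energy_estimate")
  dd <- double_difference(mk(4, 1), mk(1, 1))
  expect_equal(dd$ddg, 3)
  expect_equal(dd$stderr, sqrt(2))
  expect_equal(dd$interpretation, "destabilizing")
  expect_true(dd$ci95[1] <= dd$ddg && dd$ddg <= dd$ci95[2])
})

test_that("single-box work sets measure the binding ddG directly with the stated sign rule", {
  ws <- work_set(rep(6.14, 10), rep(-6.14, 10))
  dd <- double_difference(ws, n_boot = 200, seed = 1)
  expect_equal(dd$ddg, 6.14)
  expect_equal(dd$interpretation, "destabilizing")  # ddG > 0 hampers binding
  stab <- double_difference(work_set(rep(-10.80, 10), rep(10.80, 10)),
                            n_boot = 200, seed = 1)
  expect_equal(stab$ddg, -10.80)
  expect_equal(stab$interpretation, "stabilizing")
  expect_error(double_difference(ws, cgi_estimate(ws, n_boot = 0)), "mix")
})

test_that("estimates carry diagnostics: overlap coefficient and root-selection notes", {
  # well-separated distributions trigger the overlap warning but still return
  withr::with_seed(5, { fw <- rnorm(50, 100, 0.5); bw <- -rnorm(50, 0, 1) })
  ws <- work_set(fw, bw)
  expect_warning(est <- cgi_estimate(ws, n_boot = 0), "overlap")
  expect_lt(est$diagnostics$overlap, 0.01)
  expect_true(is.finite(est$dg))
  g <- glance(est)
  expect_equal(g$method, "CGI")
  expect_equal(g$dg, est$dg)
})
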