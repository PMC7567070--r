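#' Crooks-Gaussian-Intersection free-energy estimate
#'
#' Fits Gaussians to the forward work and the negated backward work and takes
#' the free-energy difference as the abscissa where the two densities cross
#' (by the Crooks fluctuation relation the crossing of the exact densities
#' lies at Delta G). Numerical policy: with (near-)equal standard deviations
#' the crossing is the midpoint of the means; otherwise the quadratic from
#' equating log-densities is solved and, among the real roots, the one lying
#' between the two means is taken (if none is, the root nearest the midpoint
#' is used and a diagnostic recorded). If both directions have zero variance
#' with a common mean, that value is returned (delta-function limit).
#' The Bhattacharyya coefficient of the two fitted Gaussians is recorded as
#' an overlap diagnostic; below 0.01 the intersection is flagged as poorly
#' supported by the data.
#'
#' @param ws a [work_set()].
#' @param n_boot bootstrap replicates for the error estimate (0 skips it).
#' @param seed seed for the bootstrap; default 1.
#' @param equal_var_tol relative tolerance under which standard deviations
#'   are treated as equal; default 1e-8.
#' @return a `free_energy_estimate`: list with `dg`, `stderr`, `ci95`
#'   (kJ/mol), `method = "CGI"`, sample sizes, `temperature`, and
#'   `diagnostics` (`overlap`, `notes`).
#' @export
cgi_estimate <- function(ws, n_boot = 1000, seed = 1, equal_var_tol = 1e-8) {
  stopifnot(inherits(ws, "work_set"))
  g <- fit_gaussians(ws)
  pt <- cgi_point(g$forward$mu, g$forward$sd, g$reverse$mu, g$reverse$sd,
                  equal_var_tol = equal_var_tol)
  diag <- list(overlap = bhattacharyya(g$forward, g$reverse), notes = pt$notes)
  if (diag$overlap < 0.01) {
    diag$notes <- c(diag$notes,
                    "work distributions barely overlap; intersection is an extrapolation")
    warning("forward/backward work distributions barely overlap (Bhattacharyya < 0.01)")
  }
  finish_estimate(pt$dg, ws, "CGI", diag, n_boot, seed,
                  equal_var_tol = equal_var_tol)
}

cgi_point <- function(mu_f, sd_f, mu_r, sd_r, equal_var_tol = 1e-8) {
  notes <- character(0)
  smax <- max(sd_f, sd_r)
  if (smax < 1e-12) {
    if (abs(mu_f - mu_r) < 1e-9) {
      return(list(dg = mu_f, notes = "delta-function limit"))
    }
    return(list(dg = (mu_f + mu_r) / 2,
                notes = "zero-variance directions with unequal means; midpoint used"))
  }
  if (abs(sd_f - sd_r) < equal_var_tol * smax) {
    return(list(dg = (mu_f + mu_r) / 2, notes = "equal-variance midpoint"))
  }
  a <- 1 / sd_r^2 - 1 / sd_f^2
  b <- -2 * (mu_r / sd_r^2 - mu_f / sd_f^2)
  cc <- mu_r^2 / sd_r^2 - mu_f^2 / sd_f^2 + 2 * log(sd_r / sd_f)
  disc <- b^2 - 4 * a * cc
  mid <- (mu_f + mu_r) / 2
  if (disc < 0) {
    return(list(dg = mid,
                notes = "no real intersection of log-densities; midpoint used"))
  }
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  lo <- min(mu_f, mu_r); hi <- max(mu_f, mu_r)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside)) {
    dg <- inside[which.min(abs(inside - mid))]
  } else {
    dg <- roots[which.min(abs(roots - mid))]
    notes <- "no intersection between the means; root nearest the midpoint used"
  }
  list(dg = dg, notes = notes)
}

bhattacharyya <- function(f, r) {
  if (max(f$sd, r$sd) < 1e-12) return(as.numeric(abs(f$mu - r$mu) < 1e-9))
  s2 <- f$sd^2 + r$sd^2
  if (min(f$sd, r$sd) < 1e-12) return(0)
  sqrt(2 * f$sd * r$sd / s2) * exp(-(f$mu - r$mu)^2 / (4 * s2))
}

#' Bennett acceptance-ratio estimate
#'
#' Solves the self-consistent maximum-likelihood equation for Delta G from
#' bidirectional work samples by a bracketing root-finder. Serves as an
#' independent cross-check on [cgi_estimate()]: both converge to the same
#' value on work distributions satisfying the Crooks relation.
#'
#' @inheritParams cgi_estimate
#' @param max_iter maximum root-finder iterations; default 200.
#' @return a `free_energy_estimate` with `method = "BAR"`.
#' @export
bar_estimate <- function(ws, n_boot = 1000, seed = 1, max_iter = 200) {
  stopifnot(inherits(ws, "work_set"))
  dg <- bar_point(ws$forward, -ws$backward, ws$temperature, max_iter)
  g <- fit_gaussians(ws)
  finish_estimate(dg, ws, "BAR",
                  list(overlap = bhattacharyya(g$forward, g$reverse),
                       notes = character(0)),
                  n_boot, seed, max_iter = max_iter)
}

bar_point <- function(wf, wr, temperature, max_iter = 200) {
  beta <- 1 / (KB_KJ * temperature)
  if (sd(wf) < 1e-12 && sd(wr) < 1e-12 && abs(mean(wf) - mean(wr)) < 1e-9)
    return(mean(wf))  # delta-function limit; the ML equation is degenerate
  lm <- log(length(wf) / length(wr))
  g <- function(x) {
    mean(stats::plogis(-(lm + beta * (wf - x)))) * length(wf) -
      mean(stats::plogis(lm + beta * (wr - x))) * length(wr)
  }
  lo <- min(wf, wr) - 1; hi <- max(wf, wr) + 1
  it <- 0
  while (g(lo) > 0 && it < max_iter) { lo <- lo - 2 * (hi - lo); it <- it + 1 }
  while (g(hi) < 0 && it < max_iter) { hi <- hi + 2 * (hi - lo); it <- it + 1 }
  if (g(lo) > 0 || g(hi) < 0) stopf("BAR root bracketing failed")
  sol <- tryCatch(
    uniroot(g, c(lo, hi), tol = 1e-10, maxiter = max_iter),
    error = function(e) stopf("BAR did not converge: %s", conditionMessage(e)))
  sol$root
}

finish_estimate <- function(dg, ws, method, diagnostics, n_boot, seed, ...) {
  if (n_boot > 0) {
    be <- bootstrap_error(ws, estimator = tolower(method), n_boot = n_boot,
                          seed = seed, ...)
    stderr <- be$stderr
    ci95 <- c(min(be$ci95[1], dg), max(be$ci95[2], dg))
    diagnostics$n_boot_failed <- be$n_failed
  } else {
    stderr <- NA_real_
    ci95 <- c(NA_real_, NA_real_)
  }
  structure(list(dg = dg, stderr = stderr, ci95 = ci95, method = method,
                 n_forward = length(ws$forward), n_backward = length(ws$backward),
                 temperature = ws$temperature, label = ws$label,
                 diagnostics = diagnostics),
            class = "free_energy_estimate")
}

#' Bootstrap error of a work-based free-energy estimator
#'
#' Resamples each direction with replacement, re-estimates, and reports the
#' standard deviation of the replicates and the 2.5/97.5 percentile interval.
#' Fully seeded and reproducible.
#'
#' @param ws a [work_set()].
#' @param estimator `"cgi"` or `"bar"`.
#' @param n_boot number of replicates (>= 100).
#' @param seed integer seed.
#' @param ... passed to the point estimator.
#' @return list with `stderr`, `ci95`, `n_failed`.
#' @export
bootstrap_error <- function(ws, estimator = c("cgi", "bar"), n_boot = 1000,
                            seed = 1, ...) {
  stopifnot(inherits(ws, "work_set"))
  estimator <- match.arg(estimator)
  if (n_boot < 100) stopf("n_boot must be at least 100")
  nf <- length(ws$forward); nb <- length(ws$backward)
  reps <- with_op_seed(seed, "bootstrap_error", {
    vapply(seq_len(n_boot), function(i) {
      fw <- ws$forward[sample.int(nf, nf, replace = TRUE)]
      bw <- ws$backward[sample.int(nb, nb, replace = TRUE)]
      tryCatch({
        if (estimator == "cgi") {
          rv <- -bw
          cgi_point(mean(fw), sd(fw), mean(rv), sd(rv), ...)$dg
        } else {
          bar_point(fw, -bw, ws$temperature, ...)
        }
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.1 * n_boot)
    stopf("estimator failed on %d of %d bootstrap replicates", n_failed, n_boot)
  reps <- reps[!is.na(reps)]
  list(stderr = sd(reps),
       ci95 = unname(quantile(reps, c(0.025, 0.975))),
       n_failed = n_failed)
}

#' Double free-energy difference of binding
#'
#' Two modes. \emph{Single-box}: a double-system/single-box work set already
#' measures the double difference, so `ddg` is the CGI estimate itself.
#' \emph{Two-leg}: `ddg = dg1 - dg2` from a bound-leg and a free-leg estimate,
#' with errors combined in quadrature. By the sign convention used throughout,
#' positive `ddg` destabilises binding and negative `ddg` stabilises it.
#'
#' @param x a [work_set()] (single-box mode) or a `free_energy_estimate`
#'   (bound leg, Delta G1).
#' @param y in two-leg mode, the free-leg `free_energy_estimate` (Delta G2).
#' @param ... passed to [cgi_estimate()] in single-box mode.
#' @return a `ddg_estimate`: list with `ddg`, `stderr`, `ci95` (kJ/mol),
#'   `mode`, `interpretation` (`"destabilizing"`, `"stabilizing"` or
#'   `"neutral"`), and `legs`.
#' @export
double_difference <- function(x, y = NULL, ...) {
  if (inherits(x, "work_set")) {
    if (!is.null(y))
      stopf("single-box mode takes one work_set; do not mix modes")
    est <- cgi_estimate(x, ...)
    return(new_ddg(est$dg, est$stderr, est$ci95, mode = "single_box",
                   legs = list(single = est), label = x$label))
  }
  if (inherits(x, "free_energy_estimate") && inherits(y, "free_energy_estimate")) {
    ddg <- x$dg - y$dg
    se <- sqrt(x$stderr^2 + y$stderr^2)
    return(new_ddg(ddg, se, ddg + c(-1, 1) * 1.96 * se, mode = "two_leg",
                   legs = list(dg1 = x, dg2 = y), label = x$label))
  }
  stopf("supply either one work_set or two free_energy_estimate objects")
}

new_ddg <- function(ddg, stderr, ci95, mode, legs, label = "") {
  interpretation <- if (ddg > 0) "destabilizing" else if (ddg < 0) "stabilizing" else "neutral"
  structure(list(ddg = ddg, stderr = stderr, ci95 = ci95, mode = mode,
                 interpretation = interpretation, legs = legs, label = label),
            class = "ddg_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate> %s: dG = %.3f +/- %s kJ/mol (n_f = %d, n_b = %d, T = %g K)\n",
              x$method, x$dg,
              if (is.na(x$stderr)) "NA" else sprintf("%.3f", x$stderr),
              x$n_forward, x$n_backward, x$temperature))
  invisible(x)
}

#' @export
print.ddg_estimate <- function(x, ...) {
  cat(sprintf("<ddg_estimate>%s ddG = %.3f +/- %s kJ/mol [%s, %s]\n",
              if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
              x$ddg, if (is.na(x$stderr)) "NA" else sprintf("%.3f", x$stderr),
              x$mode, x$interpretation))
  invisible(x)
}
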