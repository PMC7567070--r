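#' Construct a bidirectional nonequilibrium work set
#'
#' Holds the work samples of forward (coupling parameter lambda 0 -> 1) and
#' backward (1 -> 0) fast-switching simulations, in kJ/mol, together with the
#' temperature at which they were collected.
#'
#' @param forward forward work values, kJ/mol (lambda 0 -> 1).
#' @param backward backward work values, kJ/mol (lambda 1 -> 0).
#' @param temperature temperature in K; default 298.15.
#' @param label optional system name.
#' @return a `work_set`.
#' @export
work_set <- function(forward, backward, temperature = 298.15, label = "") {
  forward <- as.numeric(forward); backward <- as.numeric(backward)
  if (length(forward) < 2L || !all(is.finite(forward)))
    stopf("need at least 2 finite forward work values")
  if (length(backward) < 2L || !all(is.finite(backward)))
    stopf("need at least 2 finite backward work values")
  if (!is_scalar_number(temperature) || temperature <= 0)
    stopf("temperature must be a positive number (K)")
  structure(list(forward = forward, backward = backward,
                 temperature = temperature, label = label),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set>%s n_f = %d, n_b = %d, T = %g K\n",
              if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
              length(x$forward), length(x$backward), x$temperature))
  invisible(x)
}

#' Read work samples from a plain-text file
#'
#' Two dialects:
#' \describe{
#'   \item{`two_column`}{rows `work_f <value>` / `work_b <value>`; `#` starts
#'     a comment; an optional `units=kJ/mol` or `units=kcal/mol` line (bare or
#'     in a comment) declares the unit, default kJ/mol.}
#'   \item{`pmx_like`}{`path` is a pair of files (forward then backward), each
#'     with whitespace columns `index work`, mirroring the output of
#'     fast-growth integration tools.}
#' }
#' kcal/mol values are converted to kJ/mol on read (x 4.184).
#'
#' @param path file path (length 2 for `pmx_like`).
#' @param dialect `"two_column"` (default) or `"pmx_like"`.
#' @param temperature temperature in K stored on the result; default 298.15.
#' @param label optional system name.
#' @return a [work_set()].
#' @export
read_work_file <- function(path, dialect = c("two_column", "pmx_like"),
                           temperature = 298.15, label = "") {
  dialect <- match.arg(dialect)
  if (dialect == "pmx_like") {
    if (length(path) != 2L)
      stopf("pmx_like dialect needs c(forward_file, backward_file)")
    fw <- read_indexed_work(path[1])
    bw <- read_indexed_work(path[2])
    return(work_set(fw, bw, temperature = temperature, label = label))
  }
  lines <- readLines(path, warn = FALSE)
  unit <- 1
  um <- regmatches(lines, regexpr("units\\s*=\\s*\\S+", lines))
  if (length(unlist(um))) {
    u <- tolower(sub("units\\s*=\\s*", "", unlist(um)[1]))
    unit <- switch(u, "kj/mol" = 1, "kcal/mol" = KCAL_TO_KJ,
                   stopf("unknown work unit '%s'", u))
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("units\\s*=", lines)]
  toks <- strsplit(lines, "\\s+")
  fw <- numeric(0); bw <- numeric(0)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) != 2L)
      stopf("cannot parse work row %d: '%s'", i, lines[i])
    v <- suppressWarnings(as.numeric(tk[2]))
    if (!is.finite(v)) stopf("non-numeric work value in row %d", i)
    switch(tolower(tk[1]),
           work_f = , forward = , f = { fw <- c(fw, v) },
           work_b = , backward = , b = { bw <- c(bw, v) },
           stopf("unlabeled work row %d: direction '%s' not recognised", i, tk[1]))
  }
  if (length(fw) < 2L || length(bw) < 2L)
    stopf("need at least 2 work values in each direction (got %d forward, %d backward)",
          length(fw), length(bw))
  work_set(fw * unit, bw * unit, temperature = temperature, label = label)
}

read_indexed_work <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(d) < 2L) stopf("expected columns 'index work' in %s", path)
  as.numeric(d[[2]])
}

#' Gaussian moments of a work set
#'
#' Sample mean and unbiased (n - 1) standard deviation of the forward work
#' and of the \emph{negated} backward work, the two densities whose crossing
#' the Crooks-Gaussian-Intersection estimator locates.
#'
#' @param ws a [work_set()].
#' @return a `gaussian_fit_pair`: list with `forward` and `reverse`, each
#'   `(mu, sd, n)`.
#' @export
fit_gaussians <- function(ws) {
  stopifnot(inherits(ws, "work_set"))
  fw <- ws$forward; rv <- -ws$backward
  structure(list(
    forward = list(mu = mean(fw), sd = sd(fw), n = length(fw)),
    reverse = list(mu = mean(rv), sd = sd(rv), n = length(rv))
  ), class = "gaussian_fit_pair")
}

#' @export
print.gaussian_fit_pair <- function(x, ...) {
  cat(sprintf("<gaussian_fit_pair> forward N(%.3f, %.3f^2) n=%d | reverse N(%.3f, %.3f^2) n=%d\n",
              x$forward$mu, x$forward$sd, x$forward$n,
              x$reverse$mu, x$reverse$sd, x$reverse$n))
  invisible(x)
}
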