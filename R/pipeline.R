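#' Describe one system for the comparative pipeline
#'
#' A system bundles everything [run_pipeline()] needs for one simulated or
#' measured variant: a trajectory (given directly or as a synthetic
#' fluctuation spec), an optional pseudo-dihedral source (a series, a
#' von Mises spec, or the trajectory itself), and an optional work-sample
#' source for the free-energy stage.
#'
#' @param label unique system name, e.g. `"WT"` or `"G12D+K104Q"`.
#' @param trajectory an `md_trajectory`, or `NULL`.
#' @param angles a `dihedral_series`, or a list
#'   `list(mu =, kappa =, n_frames =, dt =, seed =)` passed to
#'   [simulate_angle_trajectory()], or `NULL` to derive angles from the
#'   trajectory via [compute_pseudo_dihedral()].
#' @param work a [work_set()], a work-file path, or a list of arguments to
#'   [simulate_work()]; `NULL` skips the free-energy stage for this system.
#' @param selection selection expression for RMSD; default `"backbone"`.
#' @param rmsf_selection selection for the RMSF profile; default `"calpha"`.
#' @param quadruple a [dihedral_quadruple()] used when angles come from the
#'   trajectory.
#' @param angle_window,rmsf_window,rmsd_mean_window optional `c(t0, t1)` ps
#'   windows; `NULL` uses the trailing 60% of the series for angles, the
#'   trailing 4% for the RMSF reference (mirroring last-30-ns and last-2-ns
#'   conventions for a 50-ns run) and the full series for the RMSD mean.
#' @param bin_width histogram bin width, degrees.
#' @param temperature temperature (K) for free-energy estimation.
#' @param seed integer seed for this system's synthetic stages.
#' @return a `system_config` list.
#' @export
system_config <- function(label, trajectory = NULL, angles = NULL, work = NULL,
                          selection = "backbone", rmsf_selection = "calpha",
                          quadruple = dihedral_quadruple(),
                          angle_window = NULL, rmsf_window = NULL,
                          rmsd_mean_window = NULL, bin_width = 1,
                          temperature = 298.15, seed = 1) {
  if (!nzchar(label)) stopf("system label must be non-empty")
  structure(list(label = label, trajectory = trajectory, angles = angles,
                 work = work, selection = selection,
                 rmsf_selection = rmsf_selection, quadruple = quadruple,
                 angle_window = angle_window, rmsf_window = rmsf_window,
                 rmsd_mean_window = rmsd_mean_window, bin_width = bin_width,
                 temperature = temperature, seed = seed),
            class = "system_config")
}

trailing_window <- function(times, fraction) {
  t1 <- max(times); t0 <- t1 - fraction * diff(range(times))
  c(t0, t1)
}

#' Run the comparative trajectory/free-energy pipeline
#'
#' For every configured system: RMSD mean over its window, RMSF and B-factor
#' profile, windowed angle distribution; then pairwise distribution shifts of
#' every system against the designated reference, and a Delta Delta G table
#' (single-box CGI) for systems that carry work samples. Deterministic given
#' the configs and their seeds. When `out_dir` is given, per-system TSV
#' tables and one run-level JSON summary are written there.
#'
#' @param systems list of [system_config()] objects with unique labels.
#' @param reference_label label of the reference system for pairwise shifts.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @param n_boot bootstrap replicates for free-energy errors.
#' @return a `comparative_report`: list with tibbles `metrics`, `shifts`,
#'   `ddg`, plus per-system result objects in `details`.
#' @export
run_pipeline <- function(systems, reference_label, out_dir = NULL,
                         n_boot = 1000) {
  labels <- vapply(systems, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stopf("system labels must be unique")
  if (!reference_label %in% labels)
    stopf("reference label '%s' is not among the systems", reference_label)

  details <- lapply(systems, run_system, n_boot = n_boot)
  names(details) <- labels

  metrics <- dplyr::bind_rows(lapply(details, function(d) {
    tibble::tibble(
      label = d$label,
      rmsd_mean = if (is.null(d$rmsd)) NA_real_ else d$rmsd$mean_value,
      rmsf_mean = if (is.null(d$rmsf)) NA_real_ else mean(d$rmsf$data$rmsf),
      bfactor_mean = if (is.null(d$bfactor)) NA_real_ else mean(d$bfactor$data$bfactor),
      angle_circular_mean = if (is.null(d$angle_dist)) NA_real_ else d$angle_dist$circular_mean,
      angle_circular_sd = if (is.null(d$angle_dist)) NA_real_ else d$angle_dist$circular_sd,
      angle_mode = if (is.null(d$angle_dist)) NA_real_ else d$angle_dist$mode_bin_center
    )
  }))

  ref <- details[[reference_label]]
  shifts <- dplyr::bind_rows(lapply(details, function(d) {
    if (d$label == reference_label || is.null(d$angle_dist) || is.null(ref$angle_dist))
      return(NULL)
    s <- compare_distributions(d$angle_dist, ref$angle_dist)
    tibble::tibble(label = d$label, reference = reference_label,
                   delta_circular_mean = s$delta_circular_mean,
                   delta_mode = s$delta_mode, sd_ratio = s$sd_ratio,
                   overlap = s$overlap, left_shifted = s$left_shifted)
  }))

  ddg <- dplyr::bind_rows(lapply(details, function(d) {
    if (is.null(d$ddg)) return(NULL)
    tibble::tibble(label = d$label, ddg = d$ddg$ddg, stderr = d$ddg$stderr,
                   ci_lo = d$ddg$ci95[1], ci_hi = d$ddg$ci95[2],
                   interpretation = d$ddg$interpretation)
  }))

  report <- structure(list(metrics = metrics, shifts = shifts, ddg = ddg,
                           reference = reference_label, details = details),
                      class = "comparative_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

run_system <- function(cfg, n_boot = 1000) {
  stopifnot(inherits(cfg, "system_config"))
  out <- list(label = cfg$label, rmsd = NULL, rmsf = NULL, bfactor = NULL,
              angle_series = NULL, angle_dist = NULL, ddg = NULL)

  if (!is.null(cfg$trajectory)) {
    traj <- cfg$trajectory
    out$rmsd <- compute_rmsd(traj, selection = cfg$selection,
                             mean_window = cfg$rmsd_mean_window)
    rwin <- cfg$rmsf_window %||% trailing_window(traj$times, 0.04)
    if (sum(traj$times >= rwin[1] & traj$times <= rwin[2]) < 2L)
      rwin <- range(traj$times)
    out$rmsf <- compute_rmsf(traj, selection = cfg$rmsf_selection, window = rwin)
    out$bfactor <- rmsf_to_bfactor(out$rmsf)
  }

  series <- NULL
  if (inherits(cfg$angles, "dihedral_series")) {
    series <- cfg$angles
  } else if (is.list(cfg$angles)) {
    a <- cfg$angles
    series <- simulate_angle_trajectory(mu = a$mu, kappa = a$kappa,
                                        n_frames = a$n_frames %||% 3000,
                                        dt = a$dt %||% 10,
                                        seed = a$seed %||% cfg$seed)
  } else if (!is.null(cfg$trajectory)) {
    series <- tryCatch(compute_pseudo_dihedral(cfg$trajectory, cfg$quadruple),
                       error = function(e) NULL)
  }
  if (!is.null(series)) {
    awin <- cfg$angle_window %||% trailing_window(series$data$time, 0.6)
    out$angle_series <- series
    out$angle_dist <- summarize_angles(series, window = awin,
                                       bin_width = cfg$bin_width)
  }

  ws <- NULL
  if (inherits(cfg$work, "work_set")) {
    ws <- cfg$work
  } else if (is.character(cfg$work)) {
    ws <- read_work_file(cfg$work, temperature = cfg$temperature,
                         label = cfg$label)
  } else if (is.list(cfg$work) && !is.null(cfg$work$dg_true)) {
    w <- cfg$work
    ws <- simulate_work(dg_true = w$dg_true, dissipation = w$dissipation %||% 3,
                        n_forward = w$n_forward %||% 100,
                        n_backward = w$n_backward %||% 100,
                        temperature = cfg$temperature,
                        seed = w$seed %||% cfg$seed)
  }
  if (!is.null(ws)) {
    ws$label <- cfg$label
    out$ddg <- double_difference(ws, n_boot = n_boot, seed = cfg$seed)
  }
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv0 <- function(d, file) {
    utils::write.table(d, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv0(report$metrics, "metrics.tsv")
  if (nrow(report$shifts %||% tibble::tibble()) > 0)
    write_tsv0(report$shifts, "shifts.tsv")
  if (nrow(report$ddg %||% tibble::tibble()) > 0)
    write_tsv0(report$ddg, "ddg.tsv")
  for (d in report$details) {
    slug <- gsub("[^A-Za-z0-9]+", "_", d$label)
    if (!is.null(d$rmsd)) write_tsv0(d$rmsd$data, paste0(slug, "_rmsd.tsv"))
    if (!is.null(d$bfactor)) write_tsv0(d$bfactor$data, paste0(slug, "_bfactor.tsv"))
    if (!is.null(d$angle_series))
      write_tsv0(d$angle_series$data, paste0(slug, "_dihedral.tsv"))
    if (!is.null(d$angle_dist))
      write_tsv0(d$angle_dist$data, paste0(slug, "_angle_hist.tsv"))
  }
  summary <- list(
    reference = report$reference,
    metrics = report$metrics,
    shifts = report$shifts,
    ddg = report$ddg
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read a pipeline configuration file
#'
#' A flat, line-oriented `key = value` format, diff-friendly by design. Keys
#' before the first section header are run-level (`reference`, `seed`,
#' `n_boot`); each `[system LABEL]` section then describes one system:
#' \itemize{
#'   \item `trajectory` (multi-MODEL PDB path) or `xyz_table` (plain-text
#'     trajectory table path);
#'   \item `angle_mu`, `angle_kappa`, `angle_n`, `angle_dt`, `angle_seed` for
#'     a synthetic von Mises angle ensemble;
#'   \item `work_file` (two-column work file) or `work_dg`,
#'     `work_dissipation`, `work_n`, `work_seed` for synthetic work samples;
#'   \item `selection`, `bin_width`, `temperature`, `seed` overrides.
#' }
#' Lines starting with `#` are comments.
#'
#' @param path configuration file path.
#' @return list with `systems` (list of [system_config()]), `reference`,
#'   `n_boot`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  run <- list(); sections <- list(); current <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\[system\\s+(.+)\\]$", ln))[[1]]
    if (length(m) == 2L) {
      current <- m[2]
      sections[[current]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stopf("cannot parse config line: '%s'", ln)
    val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    val <- if (!is.na(num)) num else val
    if (is.null(current)) run[[kv[2]]] <- val else sections[[current]][[kv[2]]] <- val
  }
  if (!length(sections)) stopf("config declares no [system ...] sections")
  systems <- lapply(names(sections), function(label) {
    s <- sections[[label]]
    traj <- NULL
    if (!is.null(s$trajectory)) traj <- read_pdb(s$trajectory, model_policy = "all")
    if (!is.null(s$xyz_table)) traj <- read_xyz_table(s$xyz_table)
    angles <- NULL
    if (!is.null(s$angle_mu))
      angles <- list(mu = s$angle_mu, kappa = s$angle_kappa %||% 50,
                     n_frames = s$angle_n %||% 3000, dt = s$angle_dt %||% 10,
                     seed = s$angle_seed %||% s$seed %||% run$seed %||% 1)
    work <- NULL
    if (!is.null(s$work_file)) work <- s$work_file
    if (!is.null(s$work_dg))
      work <- list(dg_true = s$work_dg, dissipation = s$work_dissipation %||% 3,
                   n_forward = s$work_n %||% 100, n_backward = s$work_n %||% 100,
                   seed = s$work_seed %||% s$seed %||% run$seed %||% 1)
    system_config(
      label = label, trajectory = traj, angles = angles, work = work,
      selection = s$selection %||% "backbone",
      bin_width = s$bin_width %||% 1,
      temperature = s$temperature %||% 298.15,
      seed = as.integer(s$seed %||% run$seed %||% 1)
    )
  })
  list(systems = systems,
       reference = run$reference %||% systems[[1]]$label,
       n_boot = as.integer(run$n_boot %||% 1000))
}

#' @export
print.comparative_report <- function(x, ...) {
  cat(sprintf("<comparative_report> %d systems, reference '%s'\n",
              nrow(x$metrics), x$reference))
  print(x$metrics)
  if (!is.null(x$ddg) && nrow(x$ddg)) print(x$ddg)
  invisible(x)
}
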