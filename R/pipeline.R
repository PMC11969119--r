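# Experiment orchestration: plaque-model, bifurcation-angle and
# inlet-velocity suites, per-run summaries, and suite-level statistics.

#' Define an experiment suite
#'
#' Convenience constructors for the three standard suites: the plaque
#' configuration suite (NONE + A1..A5), the bifurcation-angle sweep
#' (25--45 degrees) and the inlet-velocity sweep (waveform rescaled to peak
#' 0.3--0.7 m/s).
#'
#' @param suite One of `"PLAQUE_MODELS"`, `"ANGLE_SWEEP"`, `"INLET_SWEEP"`,
#'   `"SINGLE"`.
#' @param configs List of [bifurcation_config()] (required for `"SINGLE"`,
#'   derived otherwise).
#' @param angles Angles (degrees) for the angle sweep.
#' @param peaks Peak inlet velocities (m/s) for the inlet sweep.
#' @param models Plaque models for the plaque suite.
#' @param mesh_size Characteristic mesh size (m).
#' @param solver A [solver_settings()].
#' @param props A [fluid_props()].
#' @param waveform An [inlet_waveform()].
#' @param particles Optional [particle_params()] to run particle tracking
#'   per configuration.
#' @param seed Integer seed (propagated to particle seeding).
#' @export
experiment_spec <- function(suite = c("SINGLE", "PLAQUE_MODELS",
                                      "ANGLE_SWEEP", "INLET_SWEEP"),
                            configs = NULL,
                            angles = c(25, 30, 35, 40, 45),
                            peaks = seq(0.3, 0.7, by = 0.1),
                            models = c("NONE", "A1", "A2", "A3", "A4", "A5"),
                            mesh_size = 6e-4,
                            solver = solver_settings(dt = 2e-3),
                            props = fluid_props(),
                            waveform = inlet_waveform(),
                            particles = NULL,
                            seed = 1L) {
  suite <- match.arg(suite)
  waveforms <- NULL
  if (is.null(configs)) {
    configs <- switch(suite,
      SINGLE = stop("SINGLE suite requires explicit configs"),
      PLAQUE_MODELS = lapply(models, function(m)
        bifurcation_config(plaque_model = m)),
      ANGLE_SWEEP = lapply(angles, function(a)
        bifurcation_config(bifurcation_angle = a)),
      INLET_SWEEP = rep(list(bifurcation_config()), length(peaks)))
  }
  if (!length(configs)) stop("empty config list")
  ids <- switch(suite,
    PLAQUE_MODELS = vapply(configs, function(cf) cf$plaque_model, ""),
    ANGLE_SWEEP = paste0("angle_", vapply(configs, function(cf)
      cf$bifurcation_angle, 0)),
    INLET_SWEEP = paste0("peak_", peaks),
    paste0("run_", seq_along(configs)))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  if (suite == "INLET_SWEEP")
    waveforms <- lapply(peaks, function(p) scale_waveform_peak(waveform, p))
  structure(list(suite = suite, configs = configs, ids = ids,
                 waveforms = waveforms, mesh_size = mesh_size,
                 solver = solver, props = props, waveform = waveform,
                 particles = particles, seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Run an experiment suite
#'
#' For each configuration: build the outline, mesh it, run the pulsatile
#' solve, post-process wall metrics, site summaries, section extrema,
#' dimensionless numbers, risk-tier wall fractions and (optionally)
#' particle statistics. Failures are isolated per run and reported in the
#' summary with their cause.
#'
#' @param spec An [experiment_spec()].
#' @param verbose Print per-run progress.
#' @return List of run summaries (class `run_summary`), one per config.
#' @export
run_suite <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  lapply(seq_along(spec$configs), function(k) {
    cfg <- spec$configs[[k]]
    wf <- if (!is.null(spec$waveforms)) spec$waveforms[[k]] else spec$waveform
    id <- spec$ids[k]
    if (verbose) message("run ", id)
    res <- tryCatch(
      .run_single(cfg, wf, spec, id),
      error = function(e) {
        structure(list(id = id, config = cfg, failed = TRUE,
                       error = conditionMessage(e)),
                  class = "run_summary")
      })
    res
  })
}

.run_single <- function(cfg, wf, spec, id) {
  outline <- build_outline(cfg)
  mesh <- generate_mesh(outline, spec$mesh_size)
  field <- solve_pulsatile(mesh, wf, spec$props, spec$solver)
  wm <- compute_wall_metrics(field)
  ss <- site_summary(wm)
  bre <- branch_peak_reynolds(field)
  bb <- section_profile(field, "B_B")
  cc <- section_profile(field, "C_C")
  g <- outline$geom
  # curvature radius of the branch take-off represented by the fillet arc
  rc <- g$fillet / max(sin(g$th_i), 1e-6)
  re_cca <- bre$reynolds[bre$branch == "CCA"]
  tier_frac <- prop.table(table(wm$tier))
  parts <- NULL
  if (!is.null(spec$particles)) {
    pp <- spec$particles
    pp$seed <- spec$seed + which(spec$ids == id)[1]
    seeds <- seed_particles(pp, mesh, wf)
    ens <- advect(seeds, field, pp)
    parts <- residence_statistics(ens)
    parts$stagnation <- NULL
  }
  structure(list(
    id = id, config = cfg, failed = FALSE,
    n_nodes = nrow(mesh$nodes),
    dimensionless = list(
      reynolds = stats::setNames(bre$reynolds, bre$branch),
      womersley = womersley_number(cfg$d_cca, wf$period, spec$props),
      dean_ica = dean_number(re_cca, cfg$d_cca, rc),
      vft = vortex_formation_time(wf, cfg$d_cca)),
    site_summary = ss,
    risk_fractions = tier_frac,
    wall_metrics = wm,
    sections = list(
      B_B_max = max(bb$speed), C_C_max = max(cc$speed)),
    ridge_flank_peak_wss = ridge_flank_peak_wss(field),
    particles = parts,
    diagnostics = field$diagnostics),
    class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("run", x$id, "FAILED:", x$error, "\n")
  } else {
    cat("run", x$id, ":", x$n_nodes, "nodes; Re(CCA) =",
        round(x$dimensionless$reynolds["CCA"]),
        "; ridge-flank peak WSS =",
        signif(x$ridge_flank_peak_wss, 3), "Pa\n")
  }
  invisible(x)
}

#' Spearman correlation of a metric against bifurcation angle
#'
#' Rank correlation (average ranks for ties) with a Fisher-transform 95%
#' confidence interval.
#'
#' @param summaries List of run summaries from an angle sweep.
#' @param metric Function mapping a run summary to a scalar, or the name of
#'   a built-in selector: `"ridge_flank_peak_wss"`, `"bb_max_velocity"`,
#'   `"cc_max_velocity"`.
#' @return List with `rho`, `ci` (95%), `n`, `p_value`.
#' @export
spearman_angle_correlation <- function(summaries,
                                       metric = "ridge_flank_peak_wss") {
  f <- if (is.function(metric)) metric else switch(
    metric,
    ridge_flank_peak_wss = function(s) s$ridge_flank_peak_wss,
    bb_max_velocity = function(s) s$sections$B_B_max,
    cc_max_velocity = function(s) s$sections$C_C_max,
    stop("unknown metric selector: ", metric))
  ok <- !vapply(summaries, function(s) isTRUE(s$failed), TRUE)
  summaries <- summaries[ok]
  ang <- vapply(summaries, function(s) s$config$bifurcation_angle, 0)
  val <- vapply(summaries, function(s) f(s), 0)
  n <- length(val)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(val) == 0)
    return(list(rho = NA_real_, ci = c(NA, NA), n = n, p_value = NA_real_,
                note = "metric constant across runs; rho undefined"))
  ct <- suppressWarnings(stats::cor.test(ang, val, method = "spearman"))
  rho <- unname(ct$estimate)
  # Fisher transform CI (Fieller-Hartley-Pearson variance for Spearman)
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- sqrt(1.06 / (n - 3))
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(rho = rho, ci = ci, n = n, p_value = ct$p.value)
}

#' Non-parametric location tests across wall sites
#'
#' Kruskal-Wallis omnibus test over the site groups followed by pairwise
#' Wilcoxon rank-sum tests with Holm adjustment, with group medians for the
#' effect direction. The sampling unit is the wall-node metric value within
#' a site window (values along a wall are spatially autocorrelated; treat
#' p-values as descriptive).
#'
#' @param samples Named list (one element per site) of numeric vectors, or
#'   a data.frame with columns `site` and `value`.
#' @return List with `omnibus` (htest), `pairwise` (pairwise.htest or NULL),
#'   `medians`; or an `underpowered` marker when groups are too small.
#' @export
location_tests <- function(samples) {
  if (is.data.frame(samples)) {
    samples <- split(samples$value, samples$site)
  }
  samples <- samples[vapply(samples, length, 1L) > 0]
  if (length(samples) < 2 || any(vapply(samples, length, 1L) < 3)) {
    return(list(underpowered = TRUE,
                note = "need >= 2 site groups with >= 3 values each"))
  }
  value <- unlist(samples, use.names = FALSE)
  site <- factor(rep(names(samples), vapply(samples, length, 1L)))
  om <- stats::kruskal.test(value, site)
  pw <- if (length(unique(value)) > 1)
    stats::pairwise.wilcox.test(value, site, p.adjust.method = "holm",
                                exact = FALSE) else NULL
  list(underpowered = FALSE, omnibus = om, pairwise = pw,
       medians = vapply(samples, stats::median, 0))
}

#' Write a machine-readable suite report
#'
#' Emits `report.json` (run summaries, dimensionless numbers, statistics),
#' `site_summaries.csv`, `wall_metrics.csv` and (optionally) one PDF of
#' TAWSS along the walls per run into `dir`. Deterministic given its
#' inputs.
#'
#' @param summaries List of run summaries.
#' @param stats Optional list of statistics blocks (e.g. from
#'   [spearman_angle_correlation()] / [location_tests()]).
#' @param dir Output directory (created if needed).
#' @param figures Also write per-run wall-TAWSS figures (PDF).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(summaries, stats = NULL, dir = "report",
                         figures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- lapply(summaries, function(s) {
    if (isTRUE(s$failed))
      return(list(id = s$id, failed = TRUE, error = s$error))
    list(id = s$id, failed = FALSE,
         plaque_model = s$config$plaque_model,
         bifurcation_angle = s$config$bifurcation_angle,
         n_nodes = s$n_nodes,
         dimensionless = s$dimensionless,
         sections = s$sections,
         ridge_flank_peak_wss = s$ridge_flank_peak_wss,
         risk_fractions = as.list(s$risk_fractions),
         max_mass_defect = max(s$diagnostics$mass_defect),
         particles = if (!is.null(s$particles))
           list(exit_fractions = as.list(s$particles$exit_fractions),
                retained = s$particles$retained_fraction) else NULL)
  })
  rep_obj <- list(
    package = "carotidflow",
    n_runs = length(runs),
    runs = runs,
    statistics = stats,
    note = paste("Location tests: Kruskal-Wallis omnibus +",
                 "Holm-adjusted pairwise Wilcoxon rank-sum;",
                 "sampling unit = wall-node value within a site window",
                 "(spatially autocorrelated)"))
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(rep_obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  ss <- do.call(rbind, lapply(summaries, function(s) {
    if (isTRUE(s$failed)) return(NULL)
    cbind(run = s$id, s$site_summary)
  }))
  ss_path <- file.path(dir, "site_summaries.csv")
  if (!is.null(ss)) utils::write.csv(ss, ss_path, row.names = FALSE)
  wm <- do.call(rbind, lapply(summaries, function(s) {
    if (isTRUE(s$failed)) return(NULL)
    cbind(run = s$id, s$wall_metrics)
  }))
  wm_path <- file.path(dir, "wall_metrics.csv")
  if (!is.null(wm)) utils::write.csv(wm, wm_path, row.names = FALSE)
  figs <- character(0)
  if (figures) {
    for (s in summaries) {
      if (isTRUE(s$failed)) next
      fp <- file.path(dir, paste0("tawss_", s$id, ".pdf"))
      grDevices::pdf(fp, width = 7, height = 4.5)
      m <- s$wall_metrics
      plot(NA, xlim = range(m$x) * 1e3, ylim = c(0, max(m$tawss) * 1.05),
           xlab = "x (mm)", ylab = "TAWSS (Pa)",
           main = paste("Wall TAWSS -", s$id))
      cols <- c(bot = "steelblue", top = "firebrick",
                ridge_hi = "darkorange", ridge_lo = "purple")
      for (wid in unique(m$wall_id)) {
        k <- m$wall_id == wid
        o <- order(m$x[k])
        graphics::lines(m$x[k][o] * 1e3, m$tawss[k][o],
                        col = cols[[wid]], lwd = 1.5)
      }
      graphics::legend("topleft", legend = names(cols), col = unname(cols),
                       lwd = 1.5, bty = "n", cex = 0.8)
      grDevices::dev.off()
      figs <- c(figs, fp)
    }
  }
  invisible(c(json_path, ss_path, wm_path, figs))
}
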