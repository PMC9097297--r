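#' Default run configuration
#'
#' Returns the full configuration list with the benchmark protocol defaults:
#' 301 beads and a 1e-6 au string tolerance, jump distance 0.1 au, 8
#' Gauss-Hermite DVR points with order-8 polynomial fits, 7 basis functions
#' per mode and a 6-quantum excitation cap (the molecular-scale counterparts
#' are 201 beads, 0.25 au, 11 points and 16 functions).  Any entry can be
#' overridden via `...` or by a YAML file through [read_run_config()].
#'
#' @param ... named overrides of the defaults (nested lists are merged).
#' @return configuration list of class `vibtun_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    pes = list(type = "model2d", alpha1_L = 1.6, alpha2_L = 4.0,
               alpha1_R = 1.6, alpha2_R = 4.0, beta = 2.0,
               theta = pi / 12, d = 0, m = 3.5),
    path = list(n_beads = 301, tol = 1e-6, cp = 0.5),
    instanton = list(epsilon = 0.1, rk_step = NULL),
    local = list(method = "vci", n_dvr = 8, fit_order = 8,
                 basis_size = 7, max_quanta = 6),
    tm = list(model_size = "all", n_states = 3),
    qm = list(compare = FALSE, n_points = 96, n_levels = 8, check = FALSE)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  class(cfg) <- "vibtun_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return configuration list (defaults filled in).
#' @export
read_run_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

.config_pes <- function(cfg) {
  p <- cfg$pes
  stopifnot(p$type == "model2d")
  model_2d_pes(model_2d_params(
    alpha1_L = p$alpha1_L, alpha2_L = p$alpha2_L,
    alpha1_R = p$alpha1_R, alpha2_R = p$alpha2_R,
    beta = p$beta, theta = p$theta, d = p$d, m = p$m))
}

#' Run the full spectrum pipeline on one configuration
#'
#' Wells -> minimum action path -> width/excitation transport -> local states
#' (VCI or harmonic) -> Herring couplings -> tunneling matrix -> spectrum.
#' Deterministic throughout (no stochastic stages).
#'
#' @param config a [default_config()] list.
#' @return list with every intermediate: `pes`, `wells`, `path`, `h_block`,
#'   `energies` (per well, harmonic and VCI), `tm`, `spectrum`, `states`
#'   (quanta list), and `qm` (reference DVR levels when requested).
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  pes <- .config_pes(cfg)
  wL <- characterize_minimum(pes, attr(pes, "min_L"))
  wR <- characterize_minimum(pes, attr(pes, "min_R"))
  path <- optimize_map(pes, wL, wR, n_beads = cfg$path$n_beads,
                       tol = cfg$path$tol, d = cfg$pes$d, cp = cfg$path$cp)
  nmode <- length(wL$frequencies)
  nst <- min(cfg$tm$n_states, nmode + 1)
  states <- c(list(rep(0L, nmode)),
              lapply(seq_len(nmode), function(i) {
                q <- rep(0L, nmode); q[i] <- 1L; q
              }))[seq_len(nst)]
  labels <- vapply(states, .quanta_label, "")
  wdL <- propagate_widths(path, "L", epsilon = cfg$instanton$epsilon,
                          rk_step = cfg$instanton$rk_step)
  wdR <- propagate_widths(path, "R", epsilon = cfg$instanton$epsilon,
                          rk_step = cfg$instanton$rk_step)
  fL <- lapply(states, function(q) instanton_field(path, "L", q, widths = wdL))
  fR <- lapply(states, function(q) instanton_field(path, "R", q, widths = wdR))
  h <- matrix(0, nst, nst, dimnames = list(labels, labels))
  for (i in seq_len(nst)) for (j in seq_len(nst))
    h[i, j] <- tm_element_fundamental(fL[[i]], fR[[j]], path)
  e_harm <- function(w) w$energy + sum(w$frequencies) / 2 +
    vapply(states, function(q) sum(q * w$frequencies), numeric(1))
  energies <- list(harmonic_L = e_harm(wL), harmonic_R = e_harm(wR))
  if (identical(cfg$local$method, "vci")) {
    pick <- function(ls) vapply(labels, function(lb)
      ls$table$energy_abs[which(ls$table$label == lb)[1]], numeric(1))
    lsL <- vcisd_solve(vscf_solve(build_nmode_surface(
      pes, wL, cfg$local$n_dvr, cfg$local$fit_order), cfg$local$basis_size),
      cfg$local$max_quanta)
    lsR <- vcisd_solve(vscf_solve(build_nmode_surface(
      pes, wR, cfg$local$n_dvr, cfg$local$fit_order), cfg$local$basis_size),
      cfg$local$max_quanta)
    energies$vci_L <- pick(lsL); energies$vci_R <- pick(lsR)
    energies$local_L <- lsL; energies$local_R <- lsR
    EL <- energies$vci_L; ER <- energies$vci_R
  } else {
    EL <- energies$harmonic_L; ER <- energies$harmonic_R
  }
  tm <- assemble_tm(EL, ER, h, labels_L = labels, labels_R = labels,
                    model_size = cfg$tm$model_size)
  spec <- spectrum(tm)
  qm <- NULL
  if (isTRUE(cfg$qm$compare)) {
    qm <- solve_2d_dvr(pes, minima = list(attr(pes, "min_L"),
                                          attr(pes, "min_R")),
                       n_levels = cfg$qm$n_levels, check = cfg$qm$check)
  }
  list(config = cfg, pes = pes, wells = list(L = wL, R = wR), path = path,
       states = states, labels = labels, h_block = h, energies = energies,
       tm = tm, spectrum = spec, qm = qm)
}

#' Gap between two tunneling-matrix levels at one model point
#'
#' Convenience for crossing searches: runs the pipeline at the given
#' parameters and returns the gap between the chosen (ascending) levels of
#' the tunneling-matrix spectrum.
#'
#' @param config a [default_config()] list (its `local$method` selects
#'   harmonic or VCI diagonal energies).
#' @param levels length-2 integer vector of level indices.
#' @return scalar gap.
#' @export
tm_level_gap <- function(config, levels = c(4, 5)) {
  res <- run_pipeline(config)
  ev <- res$spectrum$levels
  ev[levels[2]] - ev[levels[1]]
}

#' Gap between two exact reference levels at one model point
#'
#' @param config a [default_config()] list (only the `pes` and `qm` parts
#'   are used).
#' @param levels length-2 integer vector of level indices.
#' @return scalar gap from the sinc-DVR reference solver.
#' @export
qm_level_gap <- function(config, levels = c(4, 5)) {
  pes <- .config_pes(config)
  dv <- solve_2d_dvr(pes,
                     minima = list(attr(pes, "min_L"), attr(pes, "min_R")),
                     n_levels = max(levels) + 1,
                     check = config$qm$check)
  dv$values[levels[2]] - dv$values[levels[1]]
}

#' Parameter sweep of the tunneling spectrum
#'
#' Re-optimizes the path and recomputes local states and couplings at every
#' grid point of one model parameter, reporting the exact reference levels
#' alongside the harmonic-diagonal and VCI-diagonal tunneling-matrix levels.
#'
#' @param axis `"alpha1_R"`, `"alpha2_R"` or `"d"`.
#' @param grid numeric vector of parameter values.
#' @param config base configuration.
#' @param n_levels how many levels to tabulate.
#' @param cache_dir optional directory of per-point row caches (CSV); rows
#'   already present are loaded instead of recomputed, so an interrupted
#'   sweep resumes at the missing grid points.
#' @return data frame: one row per grid point with columns
#'   `qm_k`, `harm_k`, `vci_k` for `k = 1..n_levels` and a convergence flag.
#' @export
run_sweep <- function(axis = c("alpha1_R", "alpha2_R", "d"), grid,
                      config = default_config(), n_levels = 6,
                      cache_dir = NULL) {
  axis <- match.arg(axis)
  if (!is.null(cache_dir))
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(grid, function(val) {
    cfile <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("%s_%.12g.csv", axis, val)) else NULL
    if (!is.null(cfile) && file.exists(cfile))
      return(utils::read.csv(cfile))
    cfg <- config
    cfg$pes[[axis]] <- val
    row <- stats::setNames(list(val), axis)
    ok <- TRUE
    res <- tryCatch({
      cfg$local$method <- "vci"
      r <- run_pipeline(cfg)
      evv <- r$spectrum$levels
      tmh <- assemble_tm(r$energies$harmonic_L, r$energies$harmonic_R,
                         r$h_block, labels_L = r$labels, labels_R = r$labels)
      evh <- spectrum(tmh)$levels
      pesx <- r$pes
      dv <- solve_2d_dvr(pesx, minima = list(attr(pesx, "min_L"),
                                             attr(pesx, "min_R")),
                         n_levels = n_levels, check = cfg$qm$check)
      list(evv = evv, evh = evh, evq = dv$values)
    }, error = function(e) { ok <<- FALSE; NULL })
    for (k in seq_len(n_levels)) {
      row[[paste0("qm_", k)]] <- if (ok) res$evq[k] else NA_real_
      row[[paste0("harm_", k)]] <- if (ok) res$evh[k] else NA_real_
      row[[paste0("vci_", k)]] <- if (ok) res$evv[k] else NA_real_
    }
    row$converged <- ok
    row <- as.data.frame(row)
    if (!is.null(cfile)) utils::write.csv(row, cfile, row.names = FALSE)
    row
  })
  do.call(rbind, rows)
}

#' Locate the frame-IV avoided crossing of the benchmark model
#'
#' The crossing between the transversally excited left state and the
#' longitudinally excited right state, as the right-well soft-mode frequency
#' (or the depth `d`) is swept.  Positions are located for the exact DVR
#' reference and for the tunneling-matrix model with harmonic and with VCI
#' diagonal energies, by a grid bracket plus golden-section refinement of
#' the level-4/level-5 gap.
#'
#' @param axis `"detuning"` (sweeps `alpha1_R` via
#'   \eqn{\omega_1^{(R)} = \omega_1^{(L)} + \delta}) or `"d"`.
#' @param grid sweep grid in the axis variable.
#' @param config base configuration.
#' @param models which gap curves to locate.
#' @return list of [locate_avoided_crossing()] results per model.
#' @export
model2d_crossing <- function(axis = c("detuning", "d"), grid = NULL,
                             config = default_config(),
                             models = c("qm", "harmonic", "vci")) {
  axis <- match.arg(axis)
  if (is.null(grid))
    grid <- if (axis == "detuning") seq(0.20, 0.36, by = 0.02)
            else seq(0.28, 0.48, by = 0.025)
  m <- config$pes$m
  w1L <- sqrt(config$pes$alpha1_L / m)
  cfg_at <- function(val) {
    cfg <- config
    if (axis == "detuning") cfg$pes$alpha1_R <- m * (w1L + val)^2
    else cfg$pes$d <- val
    cfg
  }
  cache <- new.env(parent = emptyenv())
  pipe_at <- function(val) {
    key <- sprintf("%.12g", val)
    if (is.null(cache[[key]])) {
      cfg <- cfg_at(val); cfg$local$method <- "vci"
      cache[[key]] <- run_pipeline(cfg)
    }
    cache[[key]]
  }
  gap <- list(
    qm = function(val) qm_level_gap(cfg_at(val)),
    harmonic = function(val) {
      r <- pipe_at(val)
      ev <- spectrum(assemble_tm(r$energies$harmonic_L,
                                 r$energies$harmonic_R, r$h_block,
                                 labels_L = r$labels,
                                 labels_R = r$labels))$levels
      ev[5] - ev[4]
    },
    vci = function(val) {
      ev <- pipe_at(val)$spectrum$levels
      ev[5] - ev[4]
    })
  out <- lapply(models, function(mm)
    locate_avoided_crossing(gap[[mm]], grid))
  names(out) <- models
  out
}
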