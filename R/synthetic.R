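#' Per-task simulation parameters
#'
#' Parameters of the latent COP process for one group and task. Static
#' tasks are simulated as a stationary 2-D process: per-axis band-limited
#' (< 3 Hz) filtered noise with the given mean offsets and SDs, plus a
#' very-low-frequency (< 0.5 Hz) component whose relative weight is
#' `low_band_gain` and a fast (3-5.5 Hz) component whose weight scales with
#' `zero_crossing_gain`; the mixture is rescaled so the marginal SD equals
#' `sway_sd_*`. Active tasks add a deterministic template (functional
#' reach: smooth AP excursion forward and back; bend over: AP excursion
#' with a force dip; gait: alternating stance windows with a heel-to-toe AP
#' sweep and a double-bump force profile).
#'
#' @param ml_offset,ap_offset Mean COP offset from the insole centroid (mm).
#' @param sway_sd_ml,sway_sd_ap Marginal sway SD per axis (mm), > 0.
#' @param low_band_gain Multiplier (> 0) on the < 0.5 Hz component weight.
#' @param zero_crossing_gain Multiplier (> 0) on the fast-band component
#'   weight (raises the zero-crossing rate of COP velocity).
#' @param asymmetry_gain Relative scaling (> 0) of the right foot's offsets
#'   and SDs versus the left (1 = symmetric feet).
#' @param trial_duration Trial length in s (>= 5). Defaults follow the
#'   study protocol: 30 s quiet-stance trials (the one-foot task is 30 s
#'   per foot), and short active trials (10 s gait, 6 s reach/bend).
#' @param total_force Per-foot loaded total force (arbitrary units).
#' @return A named list of validated parameters.
#' @export
task_params <- function(ml_offset = 0, ap_offset = 0,
                        sway_sd_ml = 3, sway_sd_ap = 4,
                        low_band_gain = 1, zero_crossing_gain = 1,
                        asymmetry_gain = 1, trial_duration = 30,
                        total_force = 350) {
  p <- list(ml_offset = ml_offset, ap_offset = ap_offset,
            sway_sd_ml = sway_sd_ml, sway_sd_ap = sway_sd_ap,
            low_band_gain = low_band_gain,
            zero_crossing_gain = zero_crossing_gain,
            asymmetry_gain = asymmetry_gain,
            trial_duration = trial_duration, total_force = total_force)
  if (!all(vapply(p, function(v) is.numeric(v) && is.finite(v), TRUE)))
    stop("task_params: all parameters must be finite numbers")
  if (sway_sd_ml <= 0 || sway_sd_ap <= 0)
    stop("task_params: sway SDs must be positive")
  if (low_band_gain <= 0 || zero_crossing_gain <= 0 || asymmetry_gain <= 0)
    stop("task_params: gains must be positive")
  if (trial_duration < 5)
    stop("task_params: trial_duration must be at least 5 s")
  p
}

default_task_durations <- function() {
  c(EO = 30, EC = 30, OF = 30, GAIT = 10, FR = 6, BO = 6)
}

#' Group effect configurations
#'
#' An effect configuration maps each group to per-task [task_params()].
#' `effect_config()` builds one from per-group arguments: each argument is
#' either a single `task_params()` list applied to every task, or a named
#' list of per-task overrides (tasks not named get defaults). Trial
#' durations default per task (see [task_params()]).
#'
#' `preset_effects()` returns ready-made configurations:
#' * `"null"` — two groups (`control`, `pd`) with identical parameters
#'   (no true effect; the selection stack should behave at chance).
#' * `"pd_vs_control"` — the affected group carries a lateral ML mean
#'   shift, larger sway, and left/right asymmetry on EO and BO, the
#'   direction pattern seen in parkinsonian posturography.
#' * `"faller_vs_nonfaller"` — within-PD preset: fallers carry a raised
#'   zero-crossing rate on EC, extra low-band ML power in gait, and EC
#'   asymmetry. Magnitudes are simulation choices, not clinical claims.
#'
#' @param ... Named per-group specifications (see details).
#' @return An `effect_config`: named list group -> task -> parameters.
#' @export
effect_config <- function(...) {
  groups <- list(...)
  if (length(groups) < 1L || is.null(names(groups)) ||
      any(names(groups) == ""))
    stop("effect_config: provide named per-group specifications")
  out <- lapply(groups, function(g) {
    per_task <- if (!is.null(names(g)) && all(names(g) %in% all_tasks()))
      g else stats::setNames(rep(list(g), 6L), all_tasks())
    cfg <- lapply(all_tasks(), function(tk) {
      p <- per_task[[tk]]
      if (is.null(p)) p <- list()
      if (is.null(p$trial_duration))
        p$trial_duration <- default_task_durations()[[tk]]
      do.call(task_params, p)
    })
    stats::setNames(cfg, all_tasks())
  })
  structure(out, class = "effect_config")
}

#' @rdname effect_config
#' @param preset Preset name.
#' @param effect_size Overall multiplier on the preset's injected
#'   differences (1 = default magnitudes; 0 recovers the null).
#' @export
preset_effects <- function(preset = c("null", "pd_vs_control",
                                      "faller_vs_nonfaller"),
                           effect_size = 1) {
  preset <- match.arg(preset)
  base <- list()
  e <- effect_size
  switch(preset,
    null = effect_config(control = base, pd = base),
    pd_vs_control = effect_config(
      control = base,
      pd = list(
        EO = list(ml_offset = 8 * e, sway_sd_ml = 3 * (1 + 0.5 * e),
                  sway_sd_ap = 4 * (1 + 0.5 * e),
                  asymmetry_gain = 1 + 0.3 * e),
        BO = list(ml_offset = 6 * e, asymmetry_gain = 1 + 0.3 * e),
        FR = list(sway_sd_ml = 3 * (1 + 0.4 * e)),
        OF = list(sway_sd_ml = 3 * (1 + 0.4 * e)))),
    faller_vs_nonfaller = effect_config(
      nonfaller = base,
      faller = list(
        EC = list(zero_crossing_gain = 1 + 1.5 * e,
                  asymmetry_gain = 1 + 0.35 * e),
        GAIT = list(low_band_gain = 1 + 1.5 * e,
                    sway_sd_ml = 3 * (1 + 0.5 * e)),
        OF = list(asymmetry_gain = 1 + 0.25 * e))))
}

#' Simulate a latent COP trajectory and total-force series
#'
#' Produces the target COP series (mm, insole coordinates) and per-frame
#' total force for one foot and task, before rendering to zone forces.
#' Deterministic given the RNG state (seed the session, or see
#' [simulate_cohort()]).
#'
#' @param task Task label.
#' @param params A [task_params()] list.
#' @param geom A [zone_geometry()]; the latent process is centered on its
#'   zone centroid plus the configured offsets.
#' @param fs Simulation rate in Hz (default 50, the study's native rate).
#' @param stance_mask Optional logical mask of loaded frames (used for
#'   gait and one-foot trials); unloaded frames get zero force.
#' @param noise Set `FALSE` for the deterministic template only.
#' @param phase_offset Gait-cycle phase offset in s (the second foot of a
#'   gait trial runs half a cycle behind the first).
#' @return List with `ml`, `ap`, `total` (numeric vectors) and `fs`.
#' @export
simulate_cop_trajectory <- function(task, params, geom =
                                      default_zone_geometry(),
                                    fs = 50, stance_mask = NULL,
                                    noise = TRUE, phase_offset = 0) {
  task <- match.arg(task, all_tasks())
  n <- round(params$trial_duration * fs)
  t <- (seq_len(n) - 1L) / fs
  c_ml <- mean(geom$ml); c_ap <- mean(geom$ap)

  tpl <- task_template(task, t, params, phase_offset)
  ml <- c_ml + params$ml_offset + tpl$ml
  ap <- c_ap + params$ap_offset + tpl$ap
  total <- tpl$force_profile * params$total_force

  if (noise) {
    ml <- ml + sway_noise(n, fs, params$sway_sd_ml,
                          params$low_band_gain, params$zero_crossing_gain)
    ap <- ap + sway_noise(n, fs, params$sway_sd_ap, 1,
                          params$zero_crossing_gain)
  }
  if (!is.null(stance_mask)) {
    stopifnot(length(stance_mask) == n)
    total[!stance_mask] <- 0
  }
  list(ml = ml, ap = ap, total = total, fs = fs)
}

# Band-limited sway noise: <3 Hz base + <0.5 Hz slow + 3-5.5 Hz fast
# components, mixed and rescaled to the target SD.
sway_noise <- function(n, fs, sd_target, low_band_gain, zc_gain) {
  pad <- min(4L * fs, n)                      # settle the filters
  m <- n + 2L * pad
  unit <- function(x) {
    s <- stats::sd(x)
    if (s > 0) x / s else x
  }
  lp <- function(x, f_hi) {
    bf <- signal::butter(2, f_hi / (fs / 2), type = "low")
    as.numeric(signal::filtfilt(bf, x))
  }
  bp <- function(x, f_lo, f_hi) {
    bf <- signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  }
  mid <- unit(bp(stats::rnorm(m), 0.5, 3))
  slow <- unit(lp(stats::rnorm(m), 0.5))
  fast <- unit(bp(stats::rnorm(m), 3, min(5.5, 0.45 * fs)))
  mix <- mid + 0.8 * low_band_gain * slow + 0.3 * zc_gain * fast
  mix <- mix[(pad + 1L):(pad + n)]
  sd_target * unit(mix)
}

# Deterministic task templates (relative to the centered stance point).
task_template <- function(task, t, params, phase_offset = 0) {
  n <- length(t)
  dur <- params$trial_duration
  zero <- rep(0, n)
  ones <- rep(1, n)
  switch(task,
    EO = , EC = , OF = list(ml = zero, ap = zero, force_profile = ones),
    FR = list(ml = zero, ap = 60 * sin(pi * t / dur)^2,
              force_profile = ones),
    BO = list(ml = zero, ap = 70 * sin(pi * t / dur)^2,
              force_profile = 1 - 0.3 * sin(pi * t / dur)^2),
    GAIT = {
      u <- gait_stance_phase(t, offset = phase_offset)
      loaded <- !is.na(u)
      ap <- zero
      # heel-to-toe sweep over each stance, ~ +/-60 mm about mid-foot
      ap[loaded] <- -60 + 120 * u[loaded]
      fp <- zero
      fp[loaded] <- sin(pi * u[loaded]) *
        (1 - 0.3 * cos(2 * pi * (u[loaded] - 0.5)))
      list(ml = zero, ap = ap, force_profile = fp)
    })
}

# Phase within stance (0..1) under a 1.2 s gait cycle with 0.7 s stance;
# NA during swing. One foot; the cohort simulator offsets the other foot
# by half a cycle.
gait_stance_phase <- function(t, cycle = 1.2, stance = 0.7, offset = 0) {
  ph <- (t + offset) %% cycle
  u <- ph / stance
  u[ph >= stance] <- NA_real_
  u
}

#' Render a COP trajectory into 8-zone forces
#'
#' Inverse of the COP centroid computation: per frame, finds non-negative
#' zone forces summing to the target total force whose force-weighted
#' centroid equals the target COP. The minimum-norm solution of the three
#' equality constraints is computed for all frames at once via a
#' precomputed pseudo-inverse; frames where it turns out negative are
#' resolved by an active-set non-negative refinement (with an exact
#' barycentric fallback on a hull triangulation). Target points outside
#' the zone convex hull are projected onto it (toward the hull centroid)
#' and flagged.
#'
#' @param ml,ap Target COP series (mm).
#' @param total Target per-frame total force; frames with `total <= 0`
#'   yield all-zero forces.
#' @param geom A [zone_geometry()].
#' @return Numeric matrix (frames x 8). Attribute `"projected"` holds the
#'   indices of frames whose target lay outside the hull.
#' @export
render_zone_forces <- function(ml, ap, total, geom =
                                 default_zone_geometry()) {
  stopifnot(length(ml) == length(ap), length(ml) == length(total))
  n <- length(ml)
  proj <- which(!in_zone_hull(ml, ap, geom))
  if (length(proj) > 0L) {
    pp <- project_into_hull(ml[proj], ap[proj], geom)
    ml[proj] <- pp$ml; ap[proj] <- pp$ap
  }
  C <- rbind(1, geom$ml, geom$ap)               # 3 x 8 constraint matrix
  Cp <- t(C) %*% solve(C %*% t(C))              # min-norm pseudo-inverse
  D <- rbind(1, ml, ap)
  U <- Cp %*% D                                 # 8 x n normalized weights
  bad <- which(apply(U < -1e-12, 2L, any))
  for (i in bad) {
    U[, i] <- nn_min_norm(C, c(1, ml[i], ap[i]), geom, i)
  }
  U[U < 0] <- 0                                 # numerical dust only
  forces <- t(U) * total
  forces[total <= 0, ] <- 0
  attr(forces, "projected") <- proj
  forces
}

# Min-norm solution of C u = d with u >= 0 (active-set on 8 zones);
# falls back to exact barycentric weights on a hull triangulation.
nn_min_norm <- function(C, d, geom, frame) {
  support <- seq_len(ncol(C))
  for (iter in 1:16) {
    Cs <- C[, support, drop = FALSE]
    M <- Cs %*% t(Cs)
    if (ncol(Cs) < 3L || rcond(M) < 1e-12) break
    us <- t(Cs) %*% solve(M, d)
    if (all(us >= -1e-12)) {
      u <- numeric(ncol(C))
      u[support] <- pmax(us, 0)
      if (max(abs(C %*% u - d)) < 1e-9) return(u)
      break
    }
    support <- support[us >= -1e-12]
    if (length(support) < 3L) break
  }
  u <- barycentric_weights(d[2L], d[3L], geom)
  if (is.null(u))
    stop("render_zone_forces: infeasible frame ", frame,
         " (target COP outside every hull triangle)")
  u
}

# Exact convex weights from a fan triangulation of the hull.
barycentric_weights <- function(ml, ap, geom) {
  hull <- grDevices::chull(geom$ml, geom$ap)
  for (k in 2:(length(hull) - 1L)) {
    tri <- hull[c(1L, k, k + 1L)]
    x <- geom$ml[tri]; y <- geom$ap[tri]
    det <- (y[2L] - y[3L]) * (x[1L] - x[3L]) +
      (x[3L] - x[2L]) * (y[1L] - y[3L])
    if (abs(det) < 1e-12) next
    l1 <- ((y[2L] - y[3L]) * (ml - x[3L]) +
             (x[3L] - x[2L]) * (ap - y[3L])) / det
    l2 <- ((y[3L] - y[1L]) * (ml - x[3L]) +
             (x[1L] - x[3L]) * (ap - y[3L])) / det
    l3 <- 1 - l1 - l2
    if (min(l1, l2, l3) >= -1e-10) {
      u <- numeric(8L)
      u[tri] <- pmax(c(l1, l2, l3), 0)
      return(u / sum(u))
    }
  }
  NULL
}

# Pull outside points just inside the hull along the ray from the hull
# centroid.
project_into_hull <- function(ml, ap, geom, inset = 1e-9) {
  hull <- grDevices::chull(geom$ml, geom$ap)
  hx <- geom$ml[hull]; hy <- geom$ap[hull]
  cx <- mean(hx); cy <- mean(hy)
  nh <- length(hull)
  for (i in seq_along(ml)) {
    dx <- ml[i] - cx; dy <- ap[i] - cy
    tmax <- 1
    for (e in seq_len(nh)) {
      j <- if (e == nh) 1L else e + 1L
      ex <- hx[j] - hx[e]; ey <- hy[j] - hy[e]
      denom <- ex * dy - ey * dx
      if (abs(denom) < 1e-12) next
      tt <- (ex * (cy - hy[e]) - ey * (cx - hx[e])) / -denom
      ss <- if (abs(ex) > abs(ey)) (cx + tt * dx - hx[e]) / ex
            else (cy + tt * dy - hy[e]) / ey
      if (tt > 0 && ss >= -1e-9 && ss <= 1 + 1e-9) tmax <- min(tmax, tt)
    }
    tmax <- tmax * (1 - inset)
    ml[i] <- cx + tmax * dx
    ap[i] <- cy + tmax * dy
  }
  list(ml = ml, ap = ap)
}

#' Simulate a full insole-pressure cohort
#'
#' Draws per-subject latent parameters around each group's configured
#' effects, simulates the latent COP process for every requested task and
#' both feet at the native 50 Hz rate, and renders 8-zone force recordings.
#' Right-foot sway SDs and offsets are scaled by the task's
#' `asymmetry_gain`; per-subject lognormal jitter (~10% SD) individualises
#' SDs and a 1 mm between-subject SD individualises offsets. The one-foot
#' trial spans two trial durations: left foot loaded first, then right.
#' Everything is deterministic given `seed`.
#'
#' @param n_per_group Named integer vector, subjects per group; group names
#'   must match the effect configuration. At least 2 per group.
#' @param effects An [effect_config()] (or [preset_effects()] output).
#' @param seed Integer RNG seed.
#' @param geom A [zone_geometry()].
#' @param fs Native simulation rate (Hz), default 50.
#' @param tasks Tasks to simulate (default all six).
#' @param meta_group Optional mapping from effect-config group names to
#'   [subject_meta()] groups and faller status; by default config groups
#'   named `pd`/`faller`/`nonfaller` map onto the PD cohort labels and
#'   anything else onto `age_matched_control`.
#' @return A `synthetic_cohort`: list with `recordings` (list of
#'   [insole_recording()]), `meta` (with a `label` column naming the
#'   config group), and `truth` (the configuration, per-subject latent
#'   parameters and seed).
#' @export
simulate_cohort <- function(n_per_group, effects = preset_effects("null"),
                            seed = 1, geom = default_zone_geometry(),
                            fs = 50, tasks = all_tasks(),
                            meta_group = NULL) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% names(effects)))
    stop("simulate_cohort: n_per_group names must match the effect config (",
         paste(names(effects), collapse = ", "), ")")
  if (any(n_per_group < 2L))
    stop("simulate_cohort: need at least 2 subjects per group")
  tasks <- intersect(all_tasks(), tasks)
  set.seed(seed)
  recordings <- list()
  meta_rows <- list()
  latents <- list()
  for (grp in names(n_per_group)) {
    for (k in seq_len(n_per_group[[grp]])) {
      sid <- sprintf("%s_%02d", grp, k)
      lat <- draw_subject_latents(effects[[grp]], tasks)
      latents[[sid]] <- lat
      for (tk in tasks) {
        recs <- simulate_subject_task(sid, tk, lat[[tk]], geom, fs)
        recordings <- c(recordings, recs)
      }
      meta_rows[[sid]] <- data.frame(
        subject_id = sid, label = grp,
        group = map_meta_group(grp, meta_group),
        faller = map_meta_faller(grp, meta_group),
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  structure(list(recordings = recordings, meta = meta,
                 truth = list(effects = effects, latents = latents,
                              seed = seed, fs = fs, tasks = tasks)),
            class = "synthetic_cohort")
}

map_meta_group <- function(grp, meta_group) {
  if (!is.null(meta_group) && !is.null(meta_group[[grp]]))
    return(meta_group[[grp]]$group)
  if (grp %in% c("pd", "faller", "nonfaller")) "pd"
  else if (grp == "young_control") "young_control"
  else "age_matched_control"
}

map_meta_faller <- function(grp, meta_group) {
  if (!is.null(meta_group) && !is.null(meta_group[[grp]]))
    return(meta_group[[grp]]$faller)
  if (grp == "faller") TRUE else if (grp == "nonfaller") FALSE else NA
}

# Per-subject, per-task, per-foot parameter draws.
draw_subject_latents <- function(group_cfg, tasks) {
  out <- list()
  for (tk in tasks) {
    p <- group_cfg[[tk]]
    jitter_sd <- exp(stats::rnorm(1, 0, 0.1))
    d_ml <- stats::rnorm(1, 0, 1)
    d_ap <- stats::rnorm(1, 0, 1)
    left <- p
    left$ml_offset <- p$ml_offset + d_ml
    left$ap_offset <- p$ap_offset + d_ap
    left$sway_sd_ml <- p$sway_sd_ml * jitter_sd
    left$sway_sd_ap <- p$sway_sd_ap * jitter_sd
    right <- left
    g <- p$asymmetry_gain * exp(stats::rnorm(1, 0, 0.03))
    right$ml_offset <- left$ml_offset * g
    right$ap_offset <- left$ap_offset * g
    right$sway_sd_ml <- left$sway_sd_ml * g
    right$sway_sd_ap <- left$sway_sd_ap * g
    out[[tk]] <- list(left = left, right = right)
  }
  out
}

# Simulate and render both feet of one subject-task.
simulate_subject_task <- function(sid, task, foot_params, geom, fs) {
  make_rec <- function(foot, sim, timestamps) {
    forces <- render_zone_forces(sim$ml, sim$ap, sim$total, geom)
    insole_recording(sid, task, foot, timestamps, forces, fs)
  }
  if (task == "OF") {
    # left loaded for one trial duration, then right; the trial is one
    # continuous two-block recording per foot
    pl <- foot_params$left; pr <- foot_params$right
    nblk <- round(pl$trial_duration * fs)
    tt <- (seq_len(2L * nblk) - 1L) / fs
    sim_l <- simulate_cop_trajectory(task, pl, geom, fs)
    sim_r <- simulate_cop_trajectory(task, pr, geom, fs)
    zl <- list(ml = c(sim_l$ml, rep(mean(geom$ml), nblk)),
               ap = c(sim_l$ap, rep(mean(geom$ap), nblk)),
               total = c(sim_l$total, rep(0, nblk)))
    zr <- list(ml = c(rep(mean(geom$ml), nblk), sim_r$ml),
               ap = c(rep(mean(geom$ap), nblk), sim_r$ap),
               total = c(rep(0, nblk), sim_r$total))
    list(make_rec("left", zl, tt), make_rec("right", zr, tt))
  } else if (task == "GAIT") {
    pl <- foot_params$left; pr <- foot_params$right
    sim_l <- simulate_cop_trajectory(task, pl, geom, fs)
    sim_r <- simulate_cop_trajectory(task, pr, geom, fs,
                                     phase_offset = 0.6)
    tt <- (seq_along(sim_l$ml) - 1L) / fs
    list(make_rec("left", sim_l, tt), make_rec("right", sim_r, tt))
  } else {
    pl <- foot_params$left; pr <- foot_params$right
    sim_l <- simulate_cop_trajectory(task, pl, geom, fs)
    sim_r <- simulate_cop_trajectory(task, pr, geom, fs)
    tt <- (seq_along(sim_l$ml) - 1L) / fs
    list(make_rec("left", sim_l, tt), make_rec("right", sim_r, tt))
  }
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%s) | %d recordings | tasks: %s\n",
    nrow(x$meta), paste(table(x$meta$label), collapse = "/"),
    length(x$recordings), paste(x$truth$tasks, collapse = ", ")))
  invisible(x)
}
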