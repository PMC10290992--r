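# Synthetic contracting-heart cine phantom and test-scenario assembly.
# Stands in for clinical cine data so that every downstream stage (dictionary,
# filters, CS) is testable without external datasets.

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Soft membership of radius r in [0, edge] with transition width w.
soft_disk <- function(r, edge, w) smoothstep((edge - r) / w + 0.5)

#' Default phantom geometry
#'
#' Geometry of the synthetic thorax: a static elliptical "thorax", a
#' contracting annular "ventricle" (bright myocardial wall around a dark
#' blood pool) and a counter-phased "atrium" blob that fills while the
#' ventricle contracts. All coordinates live on the [-1, 1]^2 square.
#'
#' @param ventricle_center,atrium_center centers in normalized coordinates.
#' @param r_outer_dia,r_inner_dia outer/inner ventricular radii at end
#'   diastole.
#' @param contract_outer,contract_inner radius reduction at end systole.
#' @param r_atrium_dia,atrium_amp atrial radius at end diastole and its
#'   counter-phased growth amplitude.
#' @param intensity named magnitudes of thorax, wall, blood pool, atrium
#'   (all in [0, 1]).
#' @return a list of geometry parameters for [make_phantom_cycle()].
#' @export
phantom_geometry <- function(ventricle_center = c(-0.15, -0.10),
                             atrium_center = c(0.30, 0.35),
                             r_outer_dia = 0.46, r_inner_dia = 0.30,
                             contract_outer = 0.05, contract_inner = 0.17,
                             r_atrium_dia = 0.12, atrium_amp = 0.08,
                             intensity = c(thorax = 0.25, wall = 0.90,
                                           pool = 0.15, atrium = 0.70)) {
  list(ventricle_center = ventricle_center, atrium_center = atrium_center,
       r_outer_dia = r_outer_dia, r_inner_dia = r_inner_dia,
       contract_outer = contract_outer, contract_inner = contract_inner,
       r_atrium_dia = r_atrium_dia, atrium_amp = atrium_amp,
       intensity = intensity)
}

# Two-harmonic contraction curve over one cycle, normalized to [0, 1].
# Phase 1 is early systole (contraction starts), the minimum sits at end
# diastole; the second harmonic skews the curve so inter-frame changes are
# large in systole and small in diastole, mimicking real cine temporal
# statistics.
contraction_curve <- function(T) {
  th <- 2 * pi * (seq_len(T) - 1) / T
  raw <- 0.65 * (1 - cos(th)) / 2 + 0.35 * (1 - cos(2 * th - 0.9)) / 2
  (raw - min(raw)) / (max(raw) - min(raw))
}

#' Generate one synthetic cardiac cycle
#'
#' Produces T complex-valued N x N frames of a beating-heart phantom: a
#' static thorax ellipse, a ventricular annulus whose inner radius follows a
#' smooth two-harmonic periodic contraction, and a counter-phased atrial
#' blob. A fixed low-order polynomial spatial phase map makes the pixels
#' genuinely complex without confounding the motion. Pixel magnitudes lie in
#' [0, 1]. The seed jitters the geometry slightly (+-2%) so different seeds
#' give distinct but comparable anatomies; output is deterministic for a
#' fixed seed.
#'
#' @param N grid size (>= 8).
#' @param T phases per cycle (>= 4).
#' @param geometry output of [phantom_geometry()].
#' @param seed integer seed for the geometry jitter.
#' @return a training-flagged `cine_series` with attributes `contraction`
#'   (the T-vector contraction curve) and `geometry`.
#' @export
make_phantom_cycle <- function(N = 32, T = 20, geometry = phantom_geometry(),
                               seed = 0) {
  N <- as.integer(N); T <- as.integer(T)
  if (N < 8L) stop("N must be >= 8")
  if (T < 4L) stop("T must be >= 4")
  g <- geometry
  # Distinct realizations (seeds) emulate distinct heartbeats of the same
  # acquisition: +-2% beat-to-beat geometry variation, no repositioning.
  jit <- withr::with_seed(seed, stats::runif(4, -0.02, 0.02))
  g$r_outer_dia <- g$r_outer_dia * (1 + jit[1])
  g$r_inner_dia <- g$r_inner_dia * (1 + jit[2])
  g$r_atrium_dia <- g$r_atrium_dia * (1 + jit[3])
  g$contract_inner <- g$contract_inner * (1 + jit[4])

  xs <- seq(-1, 1, length.out = N)
  X <- matrix(xs, N, N, byrow = TRUE)   # column coordinate
  Y <- matrix(xs, N, N)                 # row coordinate
  w <- 2.5 / N                          # edge transition width

  r_thorax <- sqrt((X / 0.95)^2 + (Y / 0.80)^2)
  m_thorax <- smoothstep((1 - r_thorax) / (2 * w) + 0.5)
  rv <- sqrt((X - g$ventricle_center[1])^2 + (Y - g$ventricle_center[2])^2)
  ra <- sqrt((X - g$atrium_center[1])^2 + (Y - g$atrium_center[2])^2)

  phase_map <- 0.5 + 1.2 * X - 0.8 * Y + 0.6 * X * Y + 0.3 * X^2
  s <- contraction_curve(T)
  # Atrial filling lags ventricular contraction by a quarter cycle; the
  # shift also makes the cycle injective in image space (no two phases
  # share identical geometry), as in real cine where systolic and
  # diastolic passes through the same ventricular volume differ in shape.
  s_atr <- s[((seq_len(T) - 1 + round(T / 4)) %% T) + 1]

  frames <- array(0 + 0i, c(N, N, T))
  for (t in seq_len(T)) {
    r_out <- g$r_outer_dia - g$contract_outer * s[t]
    r_in <- g$r_inner_dia - g$contract_inner * s[t]
    r_atr <- g$r_atrium_dia + g$atrium_amp * s_atr[t]
    mag <- g$intensity[["thorax"]] * m_thorax
    m_wall <- soft_disk(rv, r_out, w)
    mag <- mag * (1 - m_wall) + g$intensity[["wall"]] * m_wall
    m_pool <- soft_disk(rv, r_in, w)
    mag <- mag * (1 - m_pool) + g$intensity[["pool"]] * m_pool
    m_atr <- soft_disk(ra, r_atr, w)
    mag <- mag * (1 - m_atr) + g$intensity[["atrium"]] * m_atr
    frames[, , t] <- mag * exp(1i * phase_map)
  }
  out <- cine_series(frames, seq_len(T), T, is_training = TRUE)
  attr(out, "contraction") <- s
  attr(out, "geometry") <- g
  out
}

#' Specify a test scenario
#'
#' @param kind one of `"periodic"` (regular repeated heartbeats),
#'   `"arrhythmia"` (one cycle truncated by an early return to systole),
#'   `"rate_change"` (one cycle at a faster rate keeping every
#'   `skip_stride`-th phase), `"temporal_upsample"` (training decimated by
#'   `upsample_factor` while the test keeps full temporal resolution).
#' @param n_cycles number of heartbeats in the test series.
#' @param truncate_at_phase last phase retained in the arrhythmic cycle.
#' @param skip_stride phase stride of the accelerated cycle (>= 2).
#' @param upsample_factor temporal resolution ratio V (>= 2).
#' @param affected_cycle which heartbeat carries the irregularity.
#' @param seed integer seed (recorded; scenario assembly is deterministic).
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(kind = c("periodic", "arrhythmia", "rate_change",
                                   "temporal_upsample"),
                          n_cycles = 5, truncate_at_phase = NULL,
                          skip_stride = 2L, upsample_factor = 5L,
                          affected_cycle = 2L, seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_cycles = as.integer(n_cycles),
                 truncate_at_phase = truncate_at_phase,
                 skip_stride = as.integer(skip_stride),
                 upsample_factor = as.integer(upsample_factor),
                 affected_cycle = as.integer(affected_cycle),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Assemble a ground-truth test series from a test cycle
#'
#' Replicates the test cycle into `n_cycles` heartbeats and applies the
#' requested irregularity: the periodic scenario yields `n_cycles * T`
#' frames; arrhythmia truncates the affected cycle after
#' `truncate_at_phase` (an early return to systole); the rate change keeps
#' phases 1, 1+stride, ... of the affected cycle; the temporal-upsample
#' scenario leaves the test at full resolution and decimates the training
#' series instead.
#'
#' @param train the training `cine_series` (one full cycle).
#' @param test_cycle the ground-truth test cycle (one full cycle).
#' @param spec a [scenario_spec()].
#' @return a list with `test` (ground-truth `cine_series`), `schedule`
#'   (integer phase label of every test frame) and `train` (the training
#'   series, decimated for the temporal-upsample scenario).
#' @export
build_scenario <- function(train, test_cycle, spec) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(train, "cine_series"),
            inherits(test_cycle, "cine_series"))
  T <- test_cycle$period_T
  if (spec$kind != "temporal_upsample" && train$period_T != T)
    stop("training and test cycles must share period_T for primary scenarios")
  if (n_frames(test_cycle) != T)
    stop("test_cycle must contain exactly one full cycle")

  cycle_phases <- function(k) {
    if (spec$kind == "arrhythmia" && k == spec$affected_cycle) {
      tp <- spec$truncate_at_phase
      if (is.null(tp) || tp >= T || tp < 1L)
        stop("truncate_at_phase must lie in [1, period_T - 1]")
      seq_len(tp)
    } else if (spec$kind == "rate_change" && k == spec$affected_cycle) {
      if (spec$skip_stride < 2L) stop("skip_stride must be >= 2")
      if (spec$skip_stride >= T) stop("skip_stride incompatible with period_T")
      seq(1L, T, by = spec$skip_stride)
    } else seq_len(T)
  }

  schedule <- unlist(lapply(seq_len(spec$n_cycles), cycle_phases))
  test <- cine_series(test_cycle$frames[, , schedule, drop = FALSE],
                      phase_labels = schedule, period_T = T,
                      pixel_scale = test_cycle$pixel_scale)
  train_out <- if (spec$kind == "temporal_upsample")
    decimate_training(train, spec$upsample_factor) else train
  list(test = test, schedule = schedule, train = train_out)
}
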