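#' Parameters for the biased persistent random-walk track generator
#'
#' The generator emulates chemotaxis-chamber time-lapse recordings (frames
#' every 45 s for 2 h by default). The walk model is a convex combination
#' of three unit vectors: the previous step direction (weight
#' `persistence`), the gradient direction (weight `bias`), and a uniformly
#' random direction (weight `1 - persistence - bias`), renormalized to unit
#' length. Step length is `dt` times a truncated-normal (>= 0) speed draw.
#'
#' Default speeds echo the magnitudes reported for chemokine-treated
#' lymphocytes (~12 um/min with chemokine via the chemokinesis multiplier,
#' ~6.9 um/min without) without claiming to reproduce them.
#'
#' @param n_cells Number of tracks to generate.
#' @param dt Minutes per frame (default 0.75, i.e. 45 s).
#' @param duration Recording duration in minutes (default 120).
#' @param speed_mean Mean basal speed, um/min (default 6.9).
#' @param speed_sd Speed s.d., um/min (default 1.5).
#' @param persistence Weight of the previous step direction, in \[0, 1).
#' @param bias Weight of the gradient direction, in \[0, 1\].
#' @param chemokinesis_factor Speed multiplier applied when `chemokine` is
#'   `TRUE` (>= 1; default 12/6.9 so the chemokine-on default speed is
#'   ~12 um/min).
#' @param chemokine Is chemokine present? Controls only the chemokinesis
#'   speed multiplier; directional bias is set independently via `bias`.
#' @param gradient_axis 2D gradient direction (normalized internally).
#' @param group Group label stamped on every generated track.
#' @param seed Integer seed; all randomness in [simulate_tracks()] flows
#'   from it.
#' @return A list of class `track_sim_params`.
#' @export
track_sim_params <- function(n_cells = 30L, dt = 0.75, duration = 120,
                             speed_mean = 6.9, speed_sd = 1.5,
                             persistence = 0.4, bias = 0.3,
                             chemokinesis_factor = 12 / 6.9,
                             chemokine = TRUE,
                             gradient_axis = c(1, 0),
                             group = "WT", seed = 1L) {
  assert_scalar_number(n_cells, "n_cells", min = 1)
  assert_scalar_number(dt, "dt", min = 0, strict_min = TRUE)
  assert_scalar_number(duration, "duration", min = 2 * dt)
  assert_scalar_number(speed_mean, "speed_mean", min = 0)
  assert_scalar_number(speed_sd, "speed_sd", min = 0)
  assert_scalar_number(persistence, "persistence", min = 0)
  if (persistence >= 1) stop_input("`persistence` must be < 1")
  assert_scalar_number(bias, "bias", min = 0, max = 1)
  if (persistence + bias > 1) {
    stop_input("`persistence` + `bias` must be <= 1 (got %g)",
               persistence + bias)
  }
  assert_scalar_number(chemokinesis_factor, "chemokinesis_factor", min = 1)
  assert_scalar_number(seed, "seed")
  structure(
    list(n_cells = as.integer(n_cells), dt = dt, duration = duration,
         speed_mean = speed_mean, speed_sd = speed_sd,
         persistence = persistence, bias = bias,
         chemokinesis_factor = chemokinesis_factor,
         chemokine = isTRUE(chemokine),
         gradient_axis = unit2(gradient_axis, "gradient_axis"),
         group = as.character(group), seed = as.integer(seed)),
    class = "track_sim_params"
  )
}

#' Simulate chemotaxis tracks (biased persistent random walk)
#'
#' Generates `n_cells` tracks on a uniform time grid. Per track, the draw
#' order is fixed so an identical seed reproduces identical tracks: first
#' `n_steps + 1` uniform angles (the initial heading plus one random
#' component per step), then `n_steps` truncated-normal speed draws.
#' The direction of step k is
#' `normalize(persistence * d[k-1] + bias * g + (1 - persistence - bias) * u[k])`
#' where `g` is the gradient direction and `u[k]` a uniformly random unit
#' vector; the step length is the speed draw times `dt`.
#'
#' @param params A [track_sim_params()] object.
#' @return List of [track()] objects, ids `"sim_1"`, `"sim_2"`, ...
#' @examples
#' trs <- simulate_tracks(track_sim_params(n_cells = 5, seed = 42))
#' mean(vapply(trs, directionality, numeric(1), axis = c(1, 0)))
#' @export
simulate_tracks <- function(params) {
  if (!inherits(params, "track_sim_params")) {
    stop_input("`params` must come from track_sim_params()")
  }
  p <- params
  n_steps <- floor(p$duration / p$dt)
  tgrid <- seq(0, by = p$dt, length.out = n_steps + 1)
  speed_mu <- p$speed_mean * if (p$chemokine) p$chemokinesis_factor else 1
  speed_sd <- p$speed_sd * if (p$chemokine) p$chemokinesis_factor else 1
  w_rand <- 1 - p$persistence - p$bias
  g <- p$gradient_axis

  withr::with_seed(p$seed, {
    lapply(seq_len(p$n_cells), function(i) {
      ang <- stats::runif(n_steps + 1, 0, 2 * pi)
      speeds <- rnorm_trunc0(n_steps, speed_mu, speed_sd)
      x <- numeric(n_steps + 1)
      y <- numeric(n_steps + 1)
      d <- c(cos(ang[1]), sin(ang[1]))  # initial heading
      for (k in seq_len(n_steps)) {
        u <- c(cos(ang[k + 1]), sin(ang[k + 1]))
        v <- p$persistence * d + p$bias * g + w_rand * u
        nv <- sqrt(sum(v^2))
        # degenerate cancellation: keep previous heading
        if (nv > 0) d <- v / nv
        step <- speeds[k] * p$dt
        x[k + 1] <- x[k] + step * d[1]
        y[k + 1] <- y[k] + step * d[2]
      }
      track(sprintf("sim_%d", i), t = tgrid, x = x, y = y,
            group = p$group,
            volume = 150)  # nominal lymphocyte volume, passes the 16 um^3 gate
    })
  })
}
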