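# Generators for every input the experiments need: Poisson spike trains,
# time-varying regression pseudo-targets, and dynamic-vision-sensor-like
# two-polarity event streams from a moving-bar stimulus, plus the event
# binning / spatial downsampling / random slicing preprocessing used for
# event-camera data. All generators are pure functions of their parameters
# and seed.

#' Poisson spike trains as per-bin Bernoulli draws
#'
#' At millisecond-scale bins a Poisson process is generated as independent
#' Bernoulli trials with probability `rate * dt / 1000` per bin (at most
#' one spike per bin).
#'
#' @param rates per-unit firing rates in Hz (vector; recycled scalars are
#'   not expanded — pass one rate per unit).
#' @param T_steps number of time steps.
#' @param dt bin width in ms.
#' @param seed RNG seed.
#' @return binary matrix `(T_steps, n_units)`.
#' @export
poisson_spike_train <- function(rates, T_steps, dt = 1, seed) {
  if (any(rates < 0)) abort("`rates` must be non-negative")
  T_steps <- check_count(T_steps, "T_steps")
  check_scalar_number(dt, "dt", positive = TRUE)
  p <- rates * dt / 1000
  if (any(p > 1)) abort("rate * dt exceeds one spike per bin; reduce `dt` or the rate")
  n <- length(rates)
  with_seed(seed, {
    u <- matrix(stats::runif(T_steps * n), T_steps, n)
    (u < matrix(p, T_steps, n, byrow = TRUE)) * 1
  })
}

#' Pseudo-target traces for the regression task
#'
#' Three traces in `[0, 1]`: a linear ramp from 0 to 1 over the duration, a
#' high-frequency sinusoid and a low-frequency sinusoid, each scaled as
#' `0.5 * (1 + sin(2 * pi * f * t))`.
#'
#' @param T_steps number of time steps.
#' @param dt step width in ms.
#' @param f_hi,f_lo frequencies in Hz of the fast and slow sinusoid
#'   (defaults 20 and 2 Hz: both resolvable within a 500 ms stimulus).
#' @return matrix `(T_steps, 3)` with columns `ramp`, `sin_hi`, `sin_lo`.
#' @export
regression_targets <- function(T_steps, dt = 1, f_hi = 20, f_lo = 2) {
  T_steps <- check_count(T_steps, "T_steps", min = 2L)
  t_sec <- (seq_len(T_steps) - 1) * dt / 1000
  cbind(
    ramp = seq(0, 1, length.out = T_steps),
    sin_hi = 0.5 * (1 + sin(2 * pi * f_hi * t_sec)),
    sin_lo = 0.5 * (1 + sin(2 * pi * f_lo * t_sec))
  )
}

#' Moving-bar class catalog
#'
#' Eight classes: a bright bar sweeping left-to-right, right-to-left,
#' top-to-bottom or bottom-to-top, each at base speed (classes 1-4) or at
#' double speed (classes 5-8).
#'
#' @return data frame with columns `class`, `direction`, `speed_factor`.
#' @export
moving_bar_classes <- function() {
  data.frame(
    class = 1:8,
    direction = rep(c("LR", "RL", "TB", "BT"), 2),
    speed_factor = rep(c(1, 2), each = 4)
  )
}

#' Synthetic two-polarity event stream from a moving bar
#'
#' Emulates a dynamic vision sensor watching a bright bar translate across
#' the pixel array: at each step the bar's leading edge emits ON events
#' (brightness increase) and its trailing edge emits OFF events
#' (decrease), one event per edge pixel, so leading and trailing edges
#' co-occur with opposite polarities. The bar wraps around the sensor.
#' Optional Gaussian timestamp jitter and uniform salt-and-pepper noise
#' events model sensor imperfections.
#'
#' @param class_id class from [moving_bar_classes()].
#' @param width,height sensor geometry in pixels.
#' @param duration stream duration in ms.
#' @param dt motion step in ms (the bar advances every `dt`).
#' @param speed base bar speed in pixels per step.
#' @param bar_width bar thickness in pixels.
#' @param jitter standard deviation of per-event timestamp jitter, ms.
#' @param noise_rate expected number of uniform noise events per ms over
#'   the whole sensor.
#' @param seed RNG seed.
#' @return an event stream: a `data.frame` of class `decolle_event_stream`
#'   with columns `t` (ms), `x`, `y` (0-based pixel indices) and `p`
#'   (`"ON"`/`"OFF"`), sorted by `t`, with `width`, `height` and
#'   `duration` attributes.
#' @export
moving_bar_events <- function(class_id, width = 16, height = 16, duration = 300,
                              dt = 1, speed = 1, bar_width = 2, jitter = 0,
                              noise_rate = 0, seed = 1) {
  catalog <- moving_bar_classes()
  if (!class_id %in% catalog$class) abort("unknown `class_id`")
  dir <- catalog$direction[catalog$class == class_id]
  v <- speed * catalog$speed_factor[catalog$class == class_id]
  n_steps <- floor(duration / dt)
  steps <- 0:(n_steps - 1)
  # leading/trailing edge coordinate along the motion axis, wrapped
  extent <- if (dir %in% c("LR", "RL")) width else height
  lead_fwd <- (steps * v) %% extent
  trail_fwd <- (lead_fwd - bar_width) %% extent
  flip <- function(z) extent - 1 - z
  pos <- switch(dir,
    LR = list(lead = lead_fwd, trail = trail_fwd),
    RL = list(lead = flip(lead_fwd), trail = flip(trail_fwd)),
    TB = list(lead = lead_fwd, trail = trail_fwd),
    BT = list(lead = flip(lead_fwd), trail = flip(trail_fwd))
  )
  n_cross <- if (dir %in% c("LR", "RL")) height else width
  cross <- 0:(n_cross - 1)
  per_step <- function(edge_pos, pol) {
    if (dir %in% c("LR", "RL")) {
      data.frame(
        t = rep(steps * dt, each = n_cross),
        x = rep(edge_pos, each = n_cross),
        y = rep(cross, times = n_steps),
        p = pol
      )
    } else {
      data.frame(
        t = rep(steps * dt, each = n_cross),
        x = rep(cross, times = n_steps),
        y = rep(edge_pos, each = n_cross),
        p = pol
      )
    }
  }
  ev <- rbind(per_step(pos$lead, "ON"), per_step(pos$trail, "OFF"))
  ev <- with_seed(seed, {
    if (jitter > 0) {
      ev$t <- pmin(pmax(ev$t + stats::rnorm(nrow(ev), sd = jitter), 0), duration - 1e-9)
    }
    n_noise <- stats::rpois(1, noise_rate * duration)
    if (n_noise > 0) {
      ev <- rbind(ev, data.frame(
        t = stats::runif(n_noise, 0, duration - 1e-9),
        x = sample.int(width, n_noise, replace = TRUE) - 1L,
        y = sample.int(height, n_noise, replace = TRUE) - 1L,
        p = sample(c("ON", "OFF"), n_noise, replace = TRUE)
      ))
    }
    ev
  })
  ev <- ev[order(ev$t), , drop = FALSE]
  ev$x <- as.integer(round(ev$x))
  ev$y <- as.integer(round(ev$y))
  rownames(ev) <- NULL
  structure(ev,
    width = as.integer(width), height = as.integer(height),
    duration = duration, class = c("decolle_event_stream", "data.frame")
  )
}

#' Bin an event stream into a dense frame tensor
#'
#' Counts events per time bin, polarity channel and (optionally spatially
#' downsampled) pixel. `spatial_factor = 2` sums events from each 2x2
#' pixel neighbourhood into one stream (four pixels); the total count is
#' conserved. Channel 1 holds ON events, channel 2 OFF events.
#'
#' @param stream a [moving_bar_events()]-style event stream (any data
#'   frame with `t`, `x`, `y`, `p` and geometry attributes).
#' @param bin_ms time bin width in ms.
#' @param spatial_factor integer spatial downsampling factor; sensor
#'   dimensions must be divisible by it.
#' @return integer array `(n_bins, 2, height/f, width/f)` of event counts,
#'   with a `bin_ms` attribute.
#' @export
bin_events <- function(stream, bin_ms = 1, spatial_factor = 1) {
  check_scalar_number(bin_ms, "bin_ms", positive = TRUE)
  spatial_factor <- check_count(spatial_factor, "spatial_factor")
  w <- attr(stream, "width")
  h <- attr(stream, "height")
  duration <- attr(stream, "duration")
  if (is.null(w) || is.null(h) || is.null(duration)) {
    abort("`stream` must carry width/height/duration attributes")
  }
  if (w %% spatial_factor != 0 || h %% spatial_factor != 0) {
    abort("sensor dimensions must be divisible by `spatial_factor`")
  }
  ws <- w %/% spatial_factor
  hs <- h %/% spatial_factor
  n_bins <- as.integer(ceiling(duration / bin_ms))
  out <- array(0L, c(n_bins, 2L, hs, ws))
  attr(out, "bin_ms") <- bin_ms
  if (nrow(stream) == 0L) return(out)
  bin <- pmin(floor(stream$t / bin_ms), n_bins - 1L)
  ch <- ifelse(stream$p == "ON", 0L, 1L)
  xx <- stream$x %/% spatial_factor
  yy <- stream$y %/% spatial_factor
  lin <- 1L + bin + n_bins * (ch + 2L * (yy + hs * xx))
  counts <- tabulate(lin, nbins = n_bins * 2L * hs * ws)
  out[] <- counts
  out
}

#' Random fixed-length slice of a frame tensor
#'
#' Picks a uniformly random start such that a full slice of the requested
#' length fits (start offsets 0 to `T - n` bins, inclusive).
#'
#' @param frames a frame tensor from [bin_events()] (time-major array with
#'   a `bin_ms` attribute).
#' @param slice_len_ms slice length in ms.
#' @param seed RNG seed.
#' @return the sliced tensor, same trailing dimensions.
#' @export
slice_sequence <- function(frames, slice_len_ms, seed) {
  bin_ms <- attr(frames, "bin_ms")
  if (is.null(bin_ms)) bin_ms <- 1
  n <- as.integer(round(slice_len_ms / bin_ms))
  T_bins <- dim(frames)[1]
  if (n > T_bins) abort("input shorter than the requested slice")
  start <- with_seed(seed, sample.int(T_bins - n + 1L, 1L)) - 1L
  idx <- seq_len(n) + start
  d <- dim(frames)
  out <- if (length(d) == 4L) frames[idx, , , , drop = FALSE] else frames[idx, , drop = FALSE]
  attr(out, "bin_ms") <- bin_ms
  attr(out, "start_ms") <- start * bin_ms
  out
}

#' Write / read an event stream as a plain tabular text file
#'
#' One event per line (`t,x,y,p`), preceded by comment lines recording the
#' sensor geometry and duration so the stream round-trips losslessly.
#'
#' @param stream an event stream.
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns
#'   the event stream.
#' @export
write_events <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# width=%d height=%d duration=%g",
    attr(stream, "width"), attr(stream, "height"), attr(stream, "duration")
  ), con)
  utils::write.csv(as.data.frame(stream), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("width=(\\d+) height=(\\d+) duration=([0-9.]+)", header))[[1]]
  if (length(m) != 4L) abort("not an event stream file (missing geometry header)")
  ev <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(ev,
    width = as.integer(m[2]), height = as.integer(m[3]), duration = as.numeric(m[4]),
    class = c("decolle_event_stream", "data.frame")
  )
}

#' Stack per-sequence frame tensors into a batched input stream
#'
#' @param tensors list of `(T, C, H, W)` frame tensors with identical
#'   dimensions.
#' @return array `(T, B, C, H, W)` suitable for [train_online()].
#' @export
frames_to_batch <- function(tensors) {
  d <- dim(tensors[[1]])
  B <- length(tensors)
  out <- array(0, c(d[1], B, d[2], d[3], d[4]))
  for (b in seq_len(B)) out[, b, , , ] <- tensors[[b]]
  out
}
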