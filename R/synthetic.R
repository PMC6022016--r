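# Synthetic surveillance-video generator: a single person-sized elliptical
# blob that walks, falls, sits down or crouches in front of a static
# background, with per-frame ground-truth labels and kinematics. Everything
# downstream (segmentation, features, classification) is testable against
# these sequences without any external dataset.

#' Scenario specification for the synthetic video generator
#'
#' Describes one simulated sequence: a person-sized elliptical blob that
#' walks across the scene and optionally performs an action. A *fall* is a
#' rapid rotation of the body axis from vertical (90 degrees) to horizontal
#' (0 degrees) about a pivot at the feet; *sitting down* is the same rotation
#' performed much more slowly; *crouching* is a vertical contraction with no
#' rotation. The only structural difference between falling and sitting is
#' the speed of the action, which is what the temporal-variance features are
#' designed to pick up.
#'
#' @param scenario one of `"walk"`, `"fall"`, `"sit"`, `"crouch"`.
#' @param frame_size integer `(height, width)` of each frame in pixels.
#' @param fps frame rate, frames per second.
#' @param person_size integer `(height, width)` of the upright person blob in
#'   pixels; must be strictly smaller than `frame_size` in both dimensions.
#' @param walk_speed horizontal translation speed in px/frame while walking.
#' @param action_duration number of frames over which the fall/sit rotation
#'   (or crouch contraction) takes place. Defaults per scenario: fall 10
#'   (rapid, about 1/3 s at 30 fps), sit 45 (gradual), crouch 30, walk 10
#'   (inert, only sets the sequence length).
#' @param noise_sigma standard deviation of additive per-pixel Gaussian
#'   intensity noise (8-bit scale).
#' @param seed integer seed; identical specs produce bit-identical sequences.
#' @param pre_frames walking frames before the action starts.
#' @param post_frames frames after the action completes (person motionless).
#' @param onset_angle labelling rule: a frame is labelled `fall`/`sitting`
#'   once the true body orientation drops below this angle (degrees). The
#'   source datasets do not publish their frame-level labelling rule, so this
#'   is an explicit, configurable stand-in.
#' @param background_level background gray level (0-255).
#' @param person_level blob gray level (0-255).
#' @param texture_amp amplitude of an optional fixed sinusoidal background
#'   texture (0 disables it).
#'
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("walk", "fall", "sit", "crouch"),
                          frame_size = c(120L, 160L),
                          fps = 30,
                          person_size = c(48L, 16L),
                          walk_speed = 1.2,
                          action_duration = NULL,
                          noise_sigma = 2,
                          seed = 1L,
                          pre_frames = 45L,
                          post_frames = 20L,
                          onset_angle = 80,
                          background_level = 120,
                          person_level = 220,
                          texture_amp = 0) {
  scenario <- match.arg(scenario)
  if (is.null(action_duration)) {
    action_duration <- switch(scenario,
      fall = 10L, sit = 45L, crouch = 30L, walk = 10L)
  }
  spec <- list(
    scenario = scenario,
    frame_size = as.integer(frame_size),
    fps = fps,
    person_size = as.integer(person_size),
    walk_speed = walk_speed,
    action_duration = as.integer(action_duration),
    noise_sigma = noise_sigma,
    seed = as.integer(seed),
    pre_frames = as.integer(pre_frames),
    post_frames = as.integer(post_frames),
    onset_angle = onset_angle,
    background_level = background_level,
    person_level = person_level,
    texture_amp = texture_amp
  )
  class(spec) <- "scenario_spec"
  validate_scenario_spec(spec)
  spec
}

validate_scenario_spec <- function(spec) {
  if (!spec$scenario %in% c("walk", "fall", "sit", "crouch"))
    stop("invalid scenario name: ", spec$scenario)
  if (length(spec$frame_size) != 2L || length(spec$person_size) != 2L)
    stop("frame_size and person_size must each be (height, width)")
  if (any(spec$person_size >= spec$frame_size))
    stop("person larger than frame: person_size must be strictly smaller ",
         "than frame_size in both dimensions")
  if (spec$fps <= 0) stop("fps must be positive")
  if (spec$action_duration < 1L) stop("action_duration must be >= 1")
  if (spec$noise_sigma < 0) stop("noise_sigma must be non-negative")
  invisible(spec)
}

#' Rasterize a filled ellipse blob into a binary mask
#'
#' Pixel-centre test of the implicit ellipse equation. `theta_deg` is the
#' angle of the major axis measured from the horizontal x-axis (90 =
#' vertical), with y increasing downward as in image coordinates.
#'
#' @param frame_size `(height, width)` in pixels.
#' @param center `(x, y)` centre in pixels (1-based, x = column, y = row).
#' @param semi_axes `(a, b)` semi-major and semi-minor axis lengths.
#' @param theta_deg major-axis angle from horizontal, degrees.
#' @return logical matrix of dimension `frame_size`.
#' @export
rasterize_blob <- function(frame_size, center, semi_axes, theta_deg) {
  h <- frame_size[1]; w <- frame_size[2]
  a <- semi_axes[1]; b <- semi_axes[2]
  th <- theta_deg * pi / 180
  dx <- matrix(rep(seq_len(w) - center[1], each = h), h, w)
  dy <- matrix(rep(seq_len(h) - center[2], times = w), h, w)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# Per-frame true kinematics (centre, orientation, axis scale) for a scenario.
scenario_kinematics <- function(spec) {
  a <- spec$person_size[1] / 2     # semi-major (half body height)
  b <- spec$person_size[2] / 2     # semi-minor (half body width)
  h <- spec$frame_size[1]; w <- spec$frame_size[2]
  n <- spec$pre_frames + spec$action_duration + spec$post_frames
  floor_y <- h - 6
  x_min <- a + 4; x_max <- w - a - 4

  angle <- rep(90, n)
  scale <- rep(1, n)
  cx <- numeric(n); cy <- numeric(n)

  # Walking: horizontal translation with reflection at the margins.
  x <- a + 6; dir <- 1
  walking <- if (spec$scenario == "walk") rep(TRUE, n)
             else c(rep(TRUE, spec$pre_frames), rep(FALSE, n - spec$pre_frames))
  for (t in seq_len(n)) {
    if (t > 1 && walking[t]) {
      x <- x + dir * spec$walk_speed
      if (x > x_max) { x <- 2 * x_max - x; dir <- -dir }
      if (x < x_min) { x <- 2 * x_min - x; dir <- -dir }
    }
    cx[t] <- x; cy[t] <- floor_y - a
  }

  if (spec$scenario %in% c("fall", "sit")) {
    d <- spec$action_duration
    t0 <- spec$pre_frames
    pivot_x <- cx[t0]                      # feet stay put during the action
    for (t in (t0 + 1):n) {
      i <- min(t - t0, d)
      phi <- 90 * (1 - i / d)              # 90 -> 0, linear in time
      angle[t] <- phi
      phr <- phi * pi / 180
      cx[t] <- pivot_x + a * cos(phr)      # body pivots about the feet
      cy[t] <- floor_y - a * sin(phr)
    }
  } else if (spec$scenario == "crouch") {
    d <- spec$action_duration
    t0 <- spec$pre_frames
    pivot_x <- cx[t0]
    for (t in (t0 + 1):n) {
      i <- min(t - t0, d)
      s <- 1 - 0.45 * i / d                # height contracts to 55%
      scale[t] <- s
      cx[t] <- pivot_x
      cy[t] <- floor_y - a * s
    }
  }

  list(n = n, a = a, b = b, cx = cx, cy = cy, angle = angle, scale = scale)
}

#' Simulate one labelled fall/walk/sit/crouch sequence
#'
#' Renders the scenario described by `spec` as a sequence of 8-bit grayscale
#' frames (integer matrices, 0-255) over a constant mid-gray background, and
#' returns the ground truth alongside: per-frame activity labels, the true
#' blob orientation/centre, and (optionally) the exact planted masks.
#'
#' Labels follow the configurable onset rule: a frame is `fall` (or
#' `sitting`) once the true orientation drops below `spec$onset_angle`
#' degrees; all later frames keep that label, so the labelled segment is a
#' contiguous suffix. Walk and crouch frames are always `no_fall`.
#'
#' @param spec a [scenario_spec()].
#' @param keep_masks keep the planted per-frame blob masks in the ground
#'   truth (used by segmentation tests; costs memory).
#' @return a list with components `sequence` (class `frame_sequence`: list of
#'   frames, `fps`, `background`) and `truth` (class `ground_truth`: `labels`,
#'   `angle`, `center`, `extent`, `masks`).
#' @export
simulate_sequence <- function(spec, keep_masks = TRUE) {
  validate_scenario_spec(spec)
  kin <- scenario_kinematics(spec)
  fs <- spec$frame_size

  background <- matrix(spec$background_level, fs[1], fs[2])
  if (spec$texture_amp > 0) {
    tex <- outer(sin(seq_len(fs[1]) / 7), cos(seq_len(fs[2]) / 9))
    background <- background + spec$texture_amp * tex
  }
  background <- matrix(as.integer(pmin(pmax(round(background), 0), 255)),
                       fs[1], fs[2])

  frames <- vector("list", kin$n)
  masks <- if (keep_masks) vector("list", kin$n)
  with_seed(spec$seed, {
    for (t in seq_len(kin$n)) {
      mask <- rasterize_blob(fs, c(kin$cx[t], kin$cy[t]),
                             c(kin$a * kin$scale[t], kin$b), kin$angle[t])
      fr <- background
      fr[mask] <- spec$person_level
      if (spec$noise_sigma > 0) {
        fr <- fr + rnorm(length(fr), sd = spec$noise_sigma)
      }
      frames[[t]] <- matrix(as.integer(pmin(pmax(round(fr), 0), 255)),
                            fs[1], fs[2])
      if (keep_masks) masks[[t]] <- mask
    }
  })

  labels <- rep("no_fall", kin$n)
  if (spec$scenario %in% c("fall", "sit")) {
    cls <- if (spec$scenario == "fall") "fall" else "sitting"
    labels[kin$angle < spec$onset_angle] <- cls
  }

  sequence <- structure(
    list(frames = frames, fps = spec$fps, background = background),
    class = "frame_sequence")
  truth <- structure(
    list(labels = labels,
         angle = kin$angle,
         center = cbind(x = kin$cx, y = kin$cy),
         extent = cbind(a = kin$a * kin$scale, b = rep(kin$b, kin$n)),
         masks = masks,
         scenario = spec$scenario,
         onset_angle = spec$onset_angle),
    class = "ground_truth")
  list(sequence = sequence, truth = truth)
}

#' Generate a labelled dataset of simulated sequences
#'
#' @param n_sequences total number of sequences (>= 1).
#' @param class_mix named numeric vector of scenario proportions (must sum to
#'   1, names among walk/fall/sit/crouch). Counts are assigned by largest
#'   remainder so they match `floor(mix * n)` up to rounding.
#' @param spec_template a [scenario_spec()] whose fields (other than
#'   `scenario` and `seed`) are shared by all sequences.
#' @param seed master seed; per-sequence seeds are derived deterministically.
#' @param keep_masks passed to [simulate_sequence()].
#' @return list of `list(sequence, truth)` pairs, in scenario-block order.
#' @export
generate_dataset <- function(n_sequences, class_mix,
                             spec_template = scenario_spec(),
                             seed = 1L, keep_masks = FALSE) {
  if (length(class_mix) == 0L) stop("class_mix must be non-empty")
  if (any(class_mix < 0)) stop("class_mix proportions must be non-negative")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% c("walk", "fall", "sit", "crouch")))
    stop("class_mix must be named with scenarios walk/fall/sit/crouch")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (n_sequences < 1L) stop("n_sequences must be >= 1")

  # largest-remainder apportionment
  raw <- class_mix * n_sequences
  counts <- floor(raw)
  rem <- n_sequences - sum(counts)
  if (rem > 0) {
    frac_order <- order(raw - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }

  out <- vector("list", n_sequences)
  idx <- 1L
  for (sc in names(class_mix)) {
    for (j in seq_len(counts[[sc]])) {
      sp <- spec_template
      sp$scenario <- sc
      sp$action_duration <- switch(sc,
        fall = 10L, sit = 45L, crouch = 30L, walk = 10L)
      sp$seed <- as.integer(derive_seed(seed, idx))
      validate_scenario_spec(sp)
      out[[idx]] <- simulate_sequence(sp, keep_masks = keep_masks)
      out[[idx]]$scenario <- sc
      idx <- idx + 1L
    }
  }
  out
}
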