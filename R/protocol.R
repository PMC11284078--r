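#' Spatial stimulus specification
#'
#' A stimulus (encoding item or recall cue) is a truncated cosine over the
#' ring, `a * cos(B_type * (theta - center))` on the support where
#' `B_type * (theta - center)` lies in `[-pi/2, pi/2]` (wrapped difference)
#' and zero outside, plus i.i.d. Gaussian noise of strength `noise_sigma`
#' per neuron, redrawn every integration step.  `amplitude` sets signal
#' strength, `sharpness` its spatial precision (support half-width
#' `pi/(2*sharpness)`).
#'
#' @param amplitude stimulus strength `a_type` (>= 0, drive units).
#' @param sharpness spatial sharpness `B_type` (> 0).
#' @param center stimulus orientation (radians, wrapped to `[-pi/2, pi/2)`).
#' @param noise_sigma per-neuron input noise strength.
#' @return object of class `stim_spec`.
#' @export
stim_spec <- function(amplitude, sharpness, center = 0, noise_sigma = 0) {
  stopifnot(amplitude >= 0, sharpness > 0, noise_sigma >= 0)
  structure(
    list(amplitude = amplitude, sharpness = sharpness,
         center = wrap_orientation(center), noise_sigma = noise_sigma),
    class = "stim_spec"
  )
}

#' Evaluate a stimulus profile on the ring
#'
#' @param spec a [stim_spec()].
#' @param grid a [ring_grid()].
#' @param noise optional vector of standard normal draws (one per neuron);
#'   `NULL` gives the noise-free profile.
#' @return numeric vector over ring positions.
#' @export
#' @examples
#' g <- ring_grid(32)
#' stimulus_profile(stim_spec(5, 4, 0), g)
stimulus_profile <- function(spec, grid, noise = NULL) {
  arg <- spec$sharpness * wrap_orientation(grid$thetas - spec$center)
  out <- ifelse(abs(arg) <= pi / 2, spec$amplitude * cos(arg), 0)
  if (!is.null(noise)) out <- out + spec$noise_sigma * noise
  out
}

#' Draw item orientations for a trial
#'
#' The first item is uniform on `[-pi/2, pi/2)`; subsequent items are offset
#' by an orientation difference drawn from the task's discrete set:
#' `c(17, 24, 38, 52, 66, 80)` degrees (both signs) for two items and
#' `c(12, 24, 36, 48, 60, 72, 84)` degrees (both signs, drawn independently
#' per item) for three items.  Draws that collide within one grid spacing
#' (after wrapping) are rejected and redrawn, so neuronal groups for distinct
#' items never coincide.
#'
#' @param m number of items (2 or 3).
#' @param delta_set allowed positive orientation differences (radians);
#'   defaults to the set for `m`.
#' @param grid_spacing minimal allowed wrapped separation between items
#'   (radians).
#' @return numeric vector of `m` orientations in `[-pi/2, pi/2)`.
#' @export
draw_item_angles <- function(m, delta_set = NULL, grid_spacing = pi / 128) {
  if (!m %in% c(2L, 3L)) stop("m must be 2 or 3", call. = FALSE)
  if (is.null(delta_set)) delta_set <- delta_theta_set(m)
  stopifnot(length(delta_set) > 0)
  signed <- c(delta_set, -delta_set)
  for (attempt in 1:100) {
    th1 <- stats::runif(1, -pi / 2, pi / 2)
    dth <- sample(signed, m - 1L, replace = TRUE)
    th <- wrap_orientation(c(th1, th1 + dth))
    sep <- abs(wrap_orientation(outer(th, th, "-")))
    if (all(sep[upper.tri(sep)] > grid_spacing)) return(th)
  }
  stop("could not draw non-colliding item angles", call. = FALSE)
}

#' @rdname draw_item_angles
#' @export
delta_theta_set <- function(m) {
  if (m == 2L) {
    c(17, 24, 38, 52, 66, 80) * pi / 180
  } else {
    c(12, 24, 36, 48, 60, 72, 84) * pi / 180
  }
}

#' Delay-recall task protocol
#'
#' The per-trial time course: each item is presented for `t_encode` seconds,
#' successive items separated by `t_gap` (no gap after the last item); the
#' maintenance period of `t_maintain` starts at last-item offset; a weak
#' recall cue centred on the cued item's orientation is then presented for
#' `t_recall`.  Encoding must be much stronger and sharper than the cue
#' (`a_encode >> a_recall`, `B_encode > B_recall`).
#'
#' @param item_angles item orientations (radians, `[-pi/2, pi/2)`).
#' @param t_encode,t_gap,t_maintain,t_recall phase durations (s, >= 0).
#' @param cued_item index (1..M) of the item to recall.
#' @param encode_spec,recall_spec [stim_spec()] templates; their `center` is
#'   overridden per item / per cue.  Defaults: encoding amplitude 40,
#'   sharpness 8; cue amplitude 3.5 (at the bump-reignition threshold), sharpness 1.
#' @return object of class `task_protocol`.
#' @export
task_protocol <- function(item_angles,
                          t_encode = 0.25, t_gap = 1.0,
                          t_maintain = 1.0, t_recall = 0.5,
                          cued_item = 1L,
                          encode_spec = stim_spec(40, 8, noise_sigma = 0.5),
                          recall_spec = stim_spec(3.5, 1, noise_sigma = 0.5)) {
  m <- length(item_angles)
  stopifnot(
    m >= 1L,
    t_encode >= 0, t_gap >= 0, t_maintain >= 0, t_recall >= 0,
    cued_item >= 1L, cued_item <= m
  )
  if (!(encode_spec$amplitude > 2 * recall_spec$amplitude &&
        encode_spec$sharpness > recall_spec$sharpness)) {
    stop("encoding must dominate the cue: a_encode >> a_recall and ",
         "B_encode > B_recall", call. = FALSE)
  }
  structure(
    list(item_angles = wrap_orientation(item_angles), t_encode = t_encode,
         t_gap = t_gap, t_maintain = t_maintain, t_recall = t_recall,
         cued_item = as.integer(cued_item), encode_spec = encode_spec,
         recall_spec = recall_spec),
    class = "task_protocol"
  )
}

#' Expand a protocol into a stimulus schedule
#'
#' @param protocol a [task_protocol()].
#' @return tibble with one row per interval: `t_start`, `t_end`, `phase`
#'   (encode/gap/maintain/recall), `item` (NA outside encoding), and the
#'   active stimulus columns `amplitude`, `sharpness`, `center`,
#'   `noise_sigma` (zero amplitude when no input is present).  Total duration
#'   is `M*t_encode + (M-1)*t_gap + t_maintain + t_recall`.
#' @export
#' @examples
#' pr <- task_protocol(c(-0.3, 0.2), t_maintain = 2)
#' build_schedule(pr)
build_schedule <- function(protocol) {
  p <- protocol
  m <- length(p$item_angles)
  rows <- list()
  t <- 0
  for (i in seq_len(m)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      t_start = t, t_end = t + p$t_encode, phase = "encode", item = i,
      amplitude = p$encode_spec$amplitude,
      sharpness = p$encode_spec$sharpness,
      center = p$item_angles[i],
      noise_sigma = p$encode_spec$noise_sigma
    )
    t <- t + p$t_encode
    if (i < m && p$t_gap > 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        t_start = t, t_end = t + p$t_gap, phase = "gap", item = NA_integer_,
        amplitude = 0, sharpness = 1, center = 0, noise_sigma = 0
      )
      t <- t + p$t_gap
    }
  }
  if (p$t_maintain > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      t_start = t, t_end = t + p$t_maintain, phase = "maintain",
      item = NA_integer_, amplitude = 0, sharpness = 1, center = 0,
      noise_sigma = 0
    )
    t <- t + p$t_maintain
  }
  if (p$t_recall > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      t_start = t, t_end = t + p$t_recall, phase = "recall",
      item = NA_integer_,
      amplitude = p$recall_spec$amplitude,
      sharpness = p$recall_spec$sharpness,
      center = p$item_angles[p$cued_item],
      noise_sigma = p$recall_spec$noise_sigma
    )
  }
  dplyr::bind_rows(rows)
}

protocol_duration <- function(protocol) {
  m <- length(protocol$item_angles)
  m * protocol$t_encode + (m - 1) * protocol$t_gap +
    protocol$t_maintain + protocol$t_recall
}

# offset time of each item's encoding interval
item_offsets <- function(protocol) {
  m <- length(protocol$item_angles)
  (seq_len(m) - 1L) * (protocol$t_encode + protocol$t_gap) + protocol$t_encode
}
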