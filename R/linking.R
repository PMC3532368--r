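# Frame-to-frame linking of spot detections into trajectories.

#' Link spot detections into trajectories
#'
#' Greedy globally-sorted assignment: for each frame, all admissible
#' (track, detection) pairs are ranked by squared displacement and
#' assigned in ascending cost, each track and detection used at most once.
#' A pair is admissible when the displacement does not exceed
#' `max_disp_um * (gap + 1)`, where `gap` is the number of skipped frames
#' (tracks survive up to `max_gap_frames` frames without a detection, so
#' brief disappearances are bridged). Ties break on lowest track id, then
#' detection order after canonical sorting, making the result independent
#' of the input order of detections within a frame.
#'
#' @param detections Tibble from [detect_spots()] (`frame`, `x`, `y`,
#'   `response`, optionally `intensity`).
#' @param max_disp_um Maximum displacement per frame (um); default 1
#'   (vesicles typically stay within a ~1 um neighborhood between frames).
#' @param max_gap_frames Maximum number of bridged missing frames.
#' @param frame_interval Frame interval (s) used to fill the `t` column.
#' @param min_length Drop tracks with fewer points than this.
#' @return A trajectory tibble (`track_id`, `frame`, `t`, `x`, `y`,
#'   `condition = NA`).
#' @export
link_trajectories <- function(detections, max_disp_um = 1,
                              max_gap_frames = 0L, frame_interval = 1,
                              min_length = 2L) {
  check_number(max_disp_um, "max_disp_um", min = 0, strict_min = TRUE)
  max_gap_frames <- check_count(max_gap_frames, "max_gap_frames", 0L)
  if (!base::nrow(detections)) {
    return(tibble(track_id = integer(), frame = integer(), t = numeric(),
                  x = numeric(), y = numeric(), condition = NA_character_))
  }
  det <- dplyr::arrange(detections, .data$frame, .data$x, .data$y)
  frames <- sort(unique(det$frame))
  # active track state
  tr_x <- numeric(); tr_y <- numeric(); tr_last <- integer(); tr_id <- integer()
  next_id <- 1L
  pieces <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    dsub <- det[det$frame == f, ]
    nd <- base::nrow(dsub)
    assigned_det <- rep(FALSE, nd)
    assigned_trk <- rep(FALSE, length(tr_id))
    det_track <- rep(NA_integer_, nd)
    alive <- which(tr_last >= f - 1L - max_gap_frames)
    if (length(alive) && nd) {
      gap <- f - tr_last[alive]            # >= 1
      gate2 <- (max_disp_um * gap)^2
      dx <- outer(dsub$x, tr_x[alive], "-")
      dy <- outer(dsub$y, tr_y[alive], "-")
      cost <- dx * dx + dy * dy            # nd x nalive
      ok <- which(cost <= matrix(gate2, nd, length(alive), byrow = TRUE),
                  arr.ind = TRUE)
      if (base::nrow(ok)) {
        cand <- tibble(
          d = ok[, 1], a = ok[, 2],
          cost = cost[ok],
          id = tr_id[alive[ok[, 2]]]
        )
        cand <- dplyr::arrange(cand, .data$cost, .data$id, .data$d)
        for (r in seq_len(base::nrow(cand))) {
          d <- cand$d[r]; a <- cand$a[r]
          if (assigned_det[d] || assigned_trk[alive[a]]) next
          assigned_det[d] <- TRUE
          assigned_trk[alive[a]] <- TRUE
          det_track[d] <- alive[a]
        }
      }
    }
    # update matched tracks, open new ones for orphans
    for (d in seq_len(nd)) {
      if (is.na(det_track[d])) {
        tr_x <- c(tr_x, dsub$x[d]); tr_y <- c(tr_y, dsub$y[d])
        tr_last <- c(tr_last, f); tr_id <- c(tr_id, next_id)
        det_track[d] <- length(tr_id)
        next_id <- next_id + 1L
      } else {
        k <- det_track[d]
        tr_x[k] <- dsub$x[d]; tr_y[k] <- dsub$y[d]; tr_last[k] <- f
      }
    }
    if (nd) {
      pieces[[fi]] <- tibble(track_id = tr_id[det_track], frame = f,
                             x = dsub$x, y = dsub$y)
    }
  }
  out <- dplyr::bind_rows(pieces) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::filter(dplyr::n() >= min_length) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::mutate(t = .data$frame * frame_interval,
                  condition = NA_character_) |>
    dplyr::select("track_id", "frame", "t", "x", "y", "condition")
  out
}

#' Fill bridged detection gaps by linear interpolation
#'
#' Tracks produced with `max_gap_frames > 0` can skip frames where the
#' spot was briefly undetected, which breaks the uniform time grid that
#' MSD estimation requires. This fills every missing frame inside each
#' track with positions linearly interpolated between the neighboring
#' detections. Tracks without gaps pass through unchanged.
#'
#' @param trajs Trajectory tibble (`track_id`, `frame`, `t`, `x`, `y`,
#'   optionally `condition`).
#' @return The same tibble with gap frames inserted, sorted by track and
#'   frame.
#' @export
interpolate_gaps <- function(trajs) {
  validate_trajectory(trajs)
  has_cond <- "condition" %in% names(trajs)
  trajs |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$frame)
      frames <- seq(min(g$frame), max(g$frame))
      if (length(frames) == base::nrow(g)) return(g)
      out <- tibble(
        frame = frames,
        t = stats::approx(g$frame, g$t, xout = frames)$y,
        x = stats::approx(g$frame, g$x, xout = frames)$y,
        y = stats::approx(g$frame, g$y, xout = frames)$y
      )
      if (has_cond) out$condition <- g$condition[1]
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("track_id", "frame", "t", "x", "y",
                                  "condition")))
}
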