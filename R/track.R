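#' Link per-frame detections into trajectories
#'
#' Deterministic greedy globally-nearest-neighbour linking: for each frame,
#' candidate (track, detection) pairs are ranked by distance and accepted
#' smallest-first, subject to a hard displacement gate `max_disp_um`.
#' Unmatched detections start new tracks; a track unmatched for more than
#' `memory_frames` consecutive frames is terminated (it may skip up to
#' `memory_frames` missing frames and still be re-linked).
#'
#' @param detections data.frame with at least `frame`, `x_um`, `y_um`; any
#'   further columns (label, area, volume, ...) are carried through.
#' @param max_disp_um hard gate on link length (um), regardless of frame gap.
#' @param memory_frames number of consecutive missed frames tolerated.
#' @return the input rows with a `cell_id` column prepended, ordered by
#'   `cell_id` then `frame`.
#' @examples
#' d <- data.frame(frame = rep(1:10, each = 2),
#'                 x_um = rep(c(0, 20), 10) + rep(0:9, each = 2) * 2,
#'                 y_um = 0)
#' tr <- link_tracks(d, max_disp_um = 5)
#' table(tr$cell_id)
#' @export
link_tracks <- function(detections, max_disp_um = 10, memory_frames = 2) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  if (!nrow(detections)) {
    out <- cbind(cell_id = integer(0), detections)
    return(out)
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  cell_id <- integer(nrow(detections))
  # active tracks: id, x, y, last frame seen
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)
  next_id <- 1L
  for (f in frames) {
    rows <- which(detections$frame == f)
    # retire tracks that have been silent too long
    alive <- (f - act_f) <= (memory_frames + 1L)
    act_id <- act_id[alive]; act_x <- act_x[alive]
    act_y <- act_y[alive]; act_f <- act_f[alive]
    assigned_det <- rep(FALSE, length(rows))
    used_tr <- rep(FALSE, length(act_id))
    if (length(act_id) && length(rows)) {
      dx <- outer(act_x, detections$x_um[rows], `-`)
      dy <- outer(act_y, detections$y_um[rows], `-`)
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_disp_um, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dist[cand], cand[, 1], cand[, 2]), , drop = FALSE]
        for (ci in seq_len(nrow(cand))) {
          tr <- cand[ci, 1]; de <- cand[ci, 2]
          if (used_tr[tr] || assigned_det[de]) next
          used_tr[tr] <- TRUE; assigned_det[de] <- TRUE
          cell_id[rows[de]] <- act_id[tr]
          act_x[tr] <- detections$x_um[rows[de]]
          act_y[tr] <- detections$y_um[rows[de]]
          act_f[tr] <- f
        }
      }
    }
    if (any(!assigned_det)) {
      new <- which(!assigned_det)
      ids <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
      cell_id[rows[new]] <- ids
      act_id <- c(act_id, ids)
      act_x <- c(act_x, detections$x_um[rows[new]])
      act_y <- c(act_y, detections$y_um[rows[new]])
      act_f <- c(act_f, rep(f, length(new)))
    }
  }
  out <- cbind(cell_id = cell_id, detections)
  out <- out[order(out$cell_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop short tracks from downstream statistics
#'
#' @param tracks output of [link_tracks()].
#' @param min_length minimum number of frames per track.
#' @return filtered tracks.
#' @export
filter_tracks <- function(tracks, min_length = 5) {
  n <- table(tracks$cell_id)
  keep <- as.integer(names(n)[n >= min_length])
  out <- tracks[tracks$cell_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
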