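#' Frame-to-frame linking of detections into tracks
#'
#' Maintains a set of persistent particle identities across frames.  By
#' default candidate (track, detection) pairs within `max_disp` px in xy
#' and of the same class are linked greedily in order of increasing
#' distance (the real-time rule); set `global = TRUE` for optimal
#' per-frame assignment instead.  Depth is deliberately excluded from the
#' linking cost (it is the quantity under validation in stage-step
#' experiments).  Unassigned detections spawn new tracks; tracks unmatched
#' for more than `max_misses` consecutive frames are marked lost.
#'
#' @param tracker a tracker state from [new_tracker()].
#' @param detections data.frame of this frame's detections
#'   (`class,x_px,y_px,z_um,score`).
#' @param frame integer frame index (strictly increasing across calls).
#' @return The updated tracker (functional style: reassign it).
#' @export
link_frames <- function(tracker, detections, frame) {
  stopifnot(inherits(tracker, "particle_tracker"))
  nd <- nrow(detections)
  active <- which(vapply(tracker$tracks, function(t) t$state == "active", TRUE))
  assigned_det <- rep(FALSE, nd)
  matched_track <- rep(FALSE, length(tracker$tracks))
  if (length(active) && nd > 0) {
    tx <- vapply(tracker$tracks[active], function(t) t$last_x, 0)
    ty <- vapply(tracker$tracks[active], function(t) t$last_y, 0)
    tc <- vapply(tracker$tracks[active], function(t) t$class, "")
    d <- sqrt(outer(tx, detections$x_px, "-")^2 +
              outer(ty, detections$y_px, "-")^2)
    ok <- d <= tracker$max_disp
    if (tracker$require_class)
      ok <- ok & outer(tc, detections$class, "==")
    if (tracker$global) {
      BIG <- 1e9
      cost <- ifelse(ok, d, BIG)
      a <- solve_assignment(cost)
      for (k in seq_along(a)) {
        if (!is.na(a[k]) && ok[k, a[k]]) {
          tracker <- tracker_append(tracker, active[k], detections[a[k], ],
                                    frame)
          matched_track[active[k]] <- TRUE
          assigned_det[a[k]] <- TRUE
        }
      }
    } else {
      cand <- which(ok, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          k <- cand[r, 1]; j <- cand[r, 2]
          if (matched_track[active[k]] || assigned_det[j]) next
          tracker <- tracker_append(tracker, active[k], detections[j, ], frame)
          matched_track[active[k]] <- TRUE
          assigned_det[j] <- TRUE
        }
      }
    }
  }
  # unmatched active tracks age; beyond the budget they are lost
  for (k in active) {
    if (!matched_track[k]) {
      tracker$tracks[[k]]$misses <- tracker$tracks[[k]]$misses + 1L
      if (tracker$tracks[[k]]$misses > tracker$max_misses)
        tracker$tracks[[k]]$state <- "lost"
    }
  }
  # unassigned detections spawn new tracks
  for (j in which(!assigned_det)) {
    id <- tracker$next_id
    tracker$next_id <- id + 1L
    tracker$tracks[[id]] <- list(
      id = id, class = detections$class[j], state = "active", misses = 0L,
      last_x = detections$x_px[j], last_y = detections$y_px[j],
      points = det_point(detections[j, ], frame))
  }
  tracker
}

det_point <- function(det, frame) {
  data.frame(frame = frame, class = det$class, x_px = det$x_px,
             y_px = det$y_px, z_um = det$z_um,
             score = if ("score" %in% names(det)) det$score else NA_real_)
}

tracker_append <- function(tracker, k, det, frame) {
  tr <- tracker$tracks[[k]]
  tr$points <- rbind(tr$points, det_point(det, frame))
  tr$last_x <- det$x_px; tr$last_y <- det$y_px; tr$misses <- 0L
  tracker$tracks[[k]] <- tr
  tracker
}

#' @rdname link_frames
#' @param max_disp maximum per-frame xy displacement in px.
#' @param max_misses frames a track may go unmatched before it is lost.
#' @param require_class require equal class labels for linking.
#' @param global use optimal per-frame assignment instead of greedy.
#' @export
new_tracker <- function(max_disp, max_misses = 3L, require_class = TRUE,
                        global = FALSE) {
  stopifnot(max_disp > 0)
  structure(list(tracks = list(), next_id = 1L, max_disp = max_disp,
                 max_misses = as.integer(max_misses),
                 require_class = isTRUE(require_class),
                 global = isTRUE(global)),
            class = "particle_tracker")
}

#' Flatten tracker state to a tidy tracks table
#' @param tracker a `particle_tracker`.
#' @return data.frame `track_id,frame,class,x_px,y_px,z_um,score`.
#' @export
tracks_to_df <- function(tracker) {
  if (!length(tracker$tracks))
    return(data.frame(track_id = integer(), frame = integer(),
                      class = character(), x_px = numeric(), y_px = numeric(),
                      z_um = numeric(), score = numeric()))
  do.call(rbind, lapply(tracker$tracks, function(t) {
    cbind(track_id = t$id, t$points)
  }))
}

#' Detect and track particles through a video
#'
#' Runs [detect_particles()] on every frame and links the detections with
#' [link_frames()].
#'
#' @param net a `defocus_net`.
#' @param frames list of frame matrices (see [read_video_frames()]).
#' @param max_disp,max_misses,require_class,global tracker settings.
#' @param score_threshold,top_k detection settings.
#' @return List with `tracks` (tidy data.frame) and `tracker` (final
#'   state).
#' @export
track_video <- function(net, frames, max_disp = 10, max_misses = 3L,
                        require_class = TRUE, global = FALSE,
                        score_threshold = 0.3, top_k = 50L) {
  tracker <- new_tracker(max_disp, max_misses, require_class, global)
  for (f in seq_along(frames)) {
    det <- detect_particles(net, frames[[f]], score_threshold, top_k)
    tracker <- link_frames(tracker, det, f)
  }
  list(tracks = tracks_to_df(tracker), tracker = tracker)
}

#' Stage-step profile
#'
#' Ordered, contiguous, non-overlapping frame ranges with the commanded
#' z-stage offset of each range, e.g. the classic -5/-1/0/1/5/10 um step
#' sequence.
#'
#' @param offsets_um commanded z offsets, one per level.
#' @param frames_per_level frames at each level (scalar or vector).
#' @param start_frame first frame index.
#' @return A `stage_profile` data.frame
#'   (`level,frame_start,frame_end,offset_um`).
#' @export
stage_profile <- function(offsets_um, frames_per_level, start_frame = 1L) {
  n <- length(offsets_um)
  fp <- rep_len(frames_per_level, n)
  ends <- as.integer(start_frame - 1L + cumsum(fp))
  starts <- as.integer(c(start_frame, head(ends, -1) + 1L))
  structure(data.frame(level = seq_len(n), frame_start = starts,
                       frame_end = ends, offset_um = offsets_um),
            class = c("stage_profile", "data.frame"))
}

#' Compare a track's z trace against commanded stage steps
#'
#' For each profile level: the median tracked z over the level's frames and
#' the residual against (baseline + commanded offset).  The baseline is the
#' median of `z - offset` over all frames the track covers, unless given.
#' Levels the track does not reach are flagged absent.
#'
#' @param track one track's tidy rows (`frame`, `z_um`).
#' @param profile a [stage_profile()].
#' @param baseline_z_um optional known baseline z (um).
#' @param diameter_um optional bead diameter; adds residual as a fraction
#'   of it.
#' @return data.frame `level,offset_um,n_frames,median_z_um,residual_um
#'   [,residual_frac],absent`.
#' @export
z_trace_vs_stage <- function(track, profile, baseline_z_um = NULL,
                             diameter_um = NULL) {
  stopifnot(all(c("frame", "z_um") %in% names(track)))
  lvl_of <- function(fr) {
    i <- which(profile$frame_start <= fr & fr <= profile$frame_end)
    if (length(i)) i[1] else NA_integer_
  }
  lv <- vapply(track$frame, lvl_of, 0L)
  if (is.null(baseline_z_um)) {
    covered <- !is.na(lv)
    baseline_z_um <- median(track$z_um[covered] - profile$offset_um[lv[covered]])
  }
  rows <- lapply(seq_len(nrow(profile)), function(i) {
    zs <- track$z_um[!is.na(lv) & lv == i]
    if (!length(zs)) {
      data.frame(level = i, offset_um = profile$offset_um[i], n_frames = 0L,
                 median_z_um = NA_real_, residual_um = NA_real_, absent = TRUE)
    } else {
      med <- median(zs)
      data.frame(level = i, offset_um = profile$offset_um[i],
                 n_frames = length(zs), median_z_um = med,
                 residual_um = med - (baseline_z_um + profile$offset_um[i]),
                 absent = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(diameter_um)) out$residual_frac <- out$residual_um / diameter_um
  attr(out, "baseline_z_um") <- baseline_z_um
  out
}

#' Mean squared displacement of a track
#'
#' \eqn{MSD(\tau)} is the mean over all overlapping windows of the squared
#' xy displacement (in um^2) at lag \eqn{\tau}, for lags up to a quarter of
#' the track length.  Linear in lag for Brownian motion (slope `4 D`),
#' quadratic for ballistic motion.
#'
#' @param track one track's tidy rows (`frame,x_px,y_px`).
#' @param pixel_scale_um micrometres per pixel.
#' @param frame_interval_s seconds between consecutive frames.
#' @return data.frame `lag_frames,lag_s,msd_um2,n_pairs`.
#' @export
msd <- function(track, pixel_scale_um, frame_interval_s) {
  n <- nrow(track)
  if (n < 2) stop("track too short for MSD (length ", n, ")")
  ord <- order(track$frame)
  fr <- track$frame[ord]
  x <- track$x_px[ord] * pixel_scale_um
  y <- track$y_px[ord] * pixel_scale_um
  max_lag <- max(1L, floor((max(fr) - min(fr)) / 4))
  rows <- lapply(seq_len(max_lag), function(lag) {
    j <- match(fr + lag, fr)
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    data.frame(lag_frames = lag, lag_s = lag * frame_interval_s,
               msd_um2 = mean(d2), n_pairs = sum(ok))
  })
  do.call(rbind, rows)
}
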