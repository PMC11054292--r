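#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Jonker-Volgenant-style shortest augmenting path solution of the linear
#' assignment problem in O(n^3).  Rows are assigned to columns; if there
#' are more rows than columns the problem is solved transposed.
#'
#' @param cost numeric cost matrix (rows x cols), finite.
#' @return Integer vector `a` of length `nrow(cost)`: `a[i]` is the column
#'   assigned to row `i` (`NA` for unassigned rows when `nrow > ncol`).
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), all(is.finite(cost)))
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0) return(integer(0))
  if (nc == 0) return(rep(NA_integer_, nr))
  if (nr > nc) {
    bycol <- solve_assignment(t(cost))
    out <- rep(NA_integer_, nr)
    out[bycol[!is.na(bycol)]] <- which(!is.na(bycol))
    return(out)
  }
  INF <- .Machine$double.xmax / 4
  n <- nr; m <- nc
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)            # p[j + 1] = row assigned to column j
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      free_j <- which(!used[-1])
      if (length(free_j)) {
        cur <- cost[i0, free_j] - u[i0 + 1] - v[free_j + 1]
        upd <- cur < minv[free_j]
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1] <- j0
        jbest <- free_j[which.min(minv[free_j])]
        delta <- minv[jbest]; j1 <- jbest
      }
      used_idx <- which(used) - 1L
      u[p[used_idx + 1] + 1] <- u[p[used_idx + 1] + 1] + delta
      v[used_idx + 1] <- v[used_idx + 1] - delta
      minv[setdiff(seq_len(m), used_idx[-1])] <-
        minv[setdiff(seq_len(m), used_idx[-1])] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0) out[p[j + 1]] <- j
  out
}

#' Match detections to ground-truth annotations
#'
#' Class-agnostic optimal one-to-one assignment minimizing total xy
#' distance among pairs within the gate; class mismatches are recorded on
#' the pair rather than blocking the match.  Unmatched truths are missed,
#' unmatched predictions spurious.
#'
#' @param preds detections data.frame (`class,x_px,y_px,z_um`,...).
#' @param truths annotations data.frame (`class,x_px,y_px,z_um`,...).
#' @param gate maximum pairing distance in px (> 0).
#' @return List with `pairs` (data.frame `pred,truth,dist_px,dz_um,
#'   class_pred,class_truth,class_match`), `missed` (truth row indices),
#'   `spurious` (pred row indices).
#' @export
match_detections <- function(preds, truths, gate) {
  stopifnot(gate > 0)
  np <- nrow(preds); nt <- nrow(truths)
  empty <- data.frame(pred = integer(), truth = integer(), dist_px = numeric(),
                      dz_um = numeric(), class_pred = character(),
                      class_truth = character(), class_match = logical())
  if (np == 0 || nt == 0)
    return(list(pairs = empty, missed = seq_len(nt), spurious = seq_len(np)))
  d <- sqrt(outer(preds$x_px, truths$x_px, "-")^2 +
            outer(preds$y_px, truths$y_px, "-")^2)
  BIG <- 1e9
  cost <- ifelse(d <= gate, d, BIG)
  assign <- solve_assignment(cost)
  pi <- which(!is.na(assign))
  ti <- assign[pi]
  ok <- d[cbind(pi, ti)] <= gate
  pi <- pi[ok]; ti <- ti[ok]
  pairs <- if (length(pi)) data.frame(
    pred = pi, truth = ti, dist_px = d[cbind(pi, ti)],
    dz_um = preds$z_um[pi] - truths$z_um[ti],
    class_pred = preds$class[pi], class_truth = truths$class[ti],
    class_match = preds$class[pi] == truths$class[ti]) else empty
  list(pairs = pairs,
       missed = setdiff(seq_len(nt), ti),
       spurious = setdiff(seq_len(np), pi))
}

#' Localization-error report from matched pairs
#'
#' Horizontal error per pair is the Euclidean xy distance converted to
#' micrometres via the pixel scale; vertical error is `|z_pred - z_true|`.
#' Mean absolute errors are reported overall and per truth size class, with
#' a per-depth-bin table (1 um bins over the calibrated z range).  With no
#' pairs the MAEs are `NA` and `undefined` is set, never zero.
#'
#' @param match result of [match_detections()] (or a pooled list of pairs
#'   with the same columns), with `truths` z available via `z_true`.
#' @param truths the truth data.frame used for matching (for per-class and
#'   per-depth accounting).
#' @param pixel_scale_um micrometres per pixel.
#' @param z_min,z_max depth-bin range (um).
#' @return An `eval_report` list.
#' @export
compute_errors <- function(match, truths, pixel_scale_um,
                           z_min = -10, z_max = 10) {
  pairs <- match$pairs
  n <- nrow(pairs)
  report <- list(
    n_matched = n, n_missed = length(match$missed),
    n_spurious = length(match$spurious),
    pixel_scale_um = pixel_scale_um, undefined = n == 0)
  if (n == 0) {
    report$horizontal_mae_um <- NA_real_
    report$vertical_mae_um <- NA_real_
    report$per_class <- data.frame(class = character(), n = integer(),
                                   horizontal_mae_um = numeric(),
                                   vertical_mae_um = numeric())
    report$per_depth <- data.frame(bin_lo = numeric(), bin_hi = numeric(),
                                   n = integer(),
                                   horizontal_mae_um = numeric(),
                                   vertical_mae_um = numeric())
    class(report) <- "eval_report"
    return(report)
  }
  h_um <- pairs$dist_px * pixel_scale_um
  v_um <- abs(pairs$dz_um)
  report$horizontal_mae_um <- mean(h_um)
  report$vertical_mae_um <- mean(v_um)
  cls <- pairs$class_truth
  report$per_class <- do.call(rbind, lapply(sort(unique(cls)), function(cl) {
    sel <- cls == cl
    data.frame(class = cl, n = sum(sel),
               horizontal_mae_um = mean(h_um[sel]),
               vertical_mae_um = mean(v_um[sel]))
  }))
  z_true <- truths$z_um[pairs$truth]
  edges <- seq(floor(z_min), ceiling(z_max), by = 1)
  bin <- findInterval(z_true, edges, rightmost.closed = TRUE)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_lo = edges[b], bin_hi = edges[b] + 1, n = sum(sel),
               horizontal_mae_um = mean(h_um[sel]),
               vertical_mae_um = mean(v_um[sel]))
  })
  report$per_depth <- do.call(rbind, rows)
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$undefined) {
    cat("<eval_report> no matched pairs (", x$n_missed, "missed,",
        x$n_spurious, "spurious )\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<eval_report> %d matched / %d missed / %d spurious\n  horizontal MAE %.4f um, vertical MAE %.4f um\n",
    x$n_matched, x$n_missed, x$n_spurious,
    x$horizontal_mae_um, x$vertical_mae_um))
  invisible(x)
}

#' Evaluate a trained network on a dataset split
#'
#' Runs detection on every image of the split, matches detections to the
#' ground truth, and pools the pairs into one [compute_errors()] report.
#'
#' @param net a `defocus_net`.
#' @param manifest dataset manifest ([read_manifest()]).
#' @param split split name.
#' @param gate_um match gate in micrometres (converted to px by the
#'   dataset's pixel scale).
#' @param score_threshold,top_k detection parameters.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(net, manifest, split = "eval", gate_um = 2,
                           score_threshold = 0.3, top_k = 100L) {
  records <- load_split(manifest, split)
  px <- manifest$optical$pixel_scale_um
  evaluate_records(net, records, pixel_scale_um = px,
                   gate_px = gate_um / px, score_threshold = score_threshold,
                   top_k = top_k,
                   z_min = manifest$optical$z_min,
                   z_max = manifest$optical$z_max)
}

evaluate_records <- function(net, records, pixel_scale_um, gate_px,
                             score_threshold = 0.3, top_k = 100L,
                             z_min = -10, z_max = 10) {
  all_pairs <- list(); missed <- 0L; spurious <- 0L; truth_pool <- list()
  off <- 0L
  for (rec in records) {
    det <- detect_particles(net, rec$image, score_threshold, top_k)
    m <- match_detections(det, rec$annotations, gate_px)
    if (nrow(m$pairs)) {
      m$pairs$truth <- m$pairs$truth + off
      all_pairs[[length(all_pairs) + 1]] <- m$pairs
    }
    missed <- missed + length(m$missed)
    spurious <- spurious + length(m$spurious)
    truth_pool[[length(truth_pool) + 1]] <- rec$annotations
    off <- off + nrow(rec$annotations)
  }
  pooled <- list(
    pairs = if (length(all_pairs)) do.call(rbind, all_pairs) else
      match_detections(data.frame(), data.frame(), 1)$pairs,
    missed = seq_len(missed), spurious = seq_len(spurious))
  compute_errors(pooled, do.call(rbind, truth_pool), pixel_scale_um,
                 z_min = z_min, z_max = z_max)
}
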