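#' Loss weights and focal exponents
#'
#' @param heat,off,depth non-negative weights of the heatmap, offset and
#'   depth loss terms.
#' @param alpha,beta focal-loss exponents (penalty on confident mistakes
#'   and on near-center negatives, respectively).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(heat = 1, off = 1, depth = 1, alpha = 2, beta = 4) {
  stopifnot(heat >= 0, off >= 0, depth >= 0, alpha >= 0, beta >= 0)
  structure(list(heat = heat, off = off, depth = depth,
                 alpha = alpha, beta = beta), class = "loss_weights")
}

#' Detection loss: penalty-reduced focal + masked L1
#'
#' The heatmap term is the penalty-reduced pixelwise focal loss on the
#' sigmoid heatmap: at ground-truth center cells (target exactly 1)
#' \eqn{-(1-p)^\alpha \log p}; elsewhere
#' \eqn{-(1-y)^\beta p^\alpha \log(1-p)}, where `y` is the Gaussian splat
#' value.  Offset and depth terms are absolute-difference losses restricted
#' to center-mask cells.  The heatmap term is normalized by the number of
#' annotated centers (floored at 1); offset and depth terms are averaged
#' over masked cells, and are 0 when the mask is empty.  The total is the
#' weighted sum and is 0 iff the prediction
#' matches the target exactly on the heatmap and at all masked cells.
#'
#' @param pred list with `heat_logits` (Hs x Ws x C), `offset`
#'   (Hs x Ws x 2), `depth` (Hs x Ws x 1) — the raw head outputs of
#'   [net_forward()].
#' @param target a `target_maps` from [encode_targets()].
#' @param weights a [loss_weights()].
#' @param grads also return gradients w.r.t. the raw head outputs.
#' @return List with `total`, `heat`, `off`, `depth` and, if requested,
#'   `grads` (named `heat_logits`, `offset`, `depth`).
#' @export
total_loss <- function(pred, target, weights = loss_weights(),
                       grads = FALSE) {
  L <- pred$heat_logits
  if (!all(dim(L) == dim(target$heatmap))) stop("heatmap shape mismatch")
  if (!all(dim(pred$offset)[1:2] == dim(target$offset)[1:2]))
    stop("offset shape mismatch")
  eps <- 1e-12
  P <- 1 / (1 + exp(-L))
  P <- pmin(pmax(P, 1e-7), 1 - 1e-7)
  Y <- target$heatmap
  pos <- Y >= 1 - eps
  N <- max(1, sum(pos))
  al <- weights$alpha; be <- weights$beta

  l_pos <- -(1 - P)^al * log(P)
  l_neg <- -(1 - Y)^be * P^al * log(1 - P)
  heat_loss <- (sum(l_pos[pos]) + sum(l_neg[!pos])) / N

  mask <- target$center_mask
  nm <- sum(mask)
  doff <- pred$offset - target$offset
  ddep <- pred$depth[, , 1] - target$depth
  off_loss <- if (nm > 0)
    (sum(abs(doff[, , 1][mask])) + sum(abs(doff[, , 2][mask]))) / nm else 0
  dep_loss <- if (nm > 0) sum(abs(ddep[mask])) / nm else 0

  out <- list(total = weights$heat * heat_loss + weights$off * off_loss +
                weights$depth * dep_loss,
              heat = heat_loss, off = off_loss, depth = dep_loss)
  if (grads) {
    # d(loss)/dP, then chain through sigmoid: dP/dL = P (1 - P)
    dP <- array(0, dim(P))
    dP[pos] <- al * (1 - P[pos])^(al - 1) * log(P[pos]) -
      (1 - P[pos])^al / P[pos]
    dP[!pos] <- -(1 - Y[!pos])^be *
      (al * P[!pos]^(al - 1) * log(1 - P[!pos]) - P[!pos]^al / (1 - P[!pos]))
    g_heat <- weights$heat * dP * P * (1 - P) / N
    g_off <- array(0, dim(pred$offset))
    g_dep <- array(0, dim(pred$depth))
    if (nm > 0) {
      for (k in 1:2) {
        gk <- matrix(0, nrow(mask), ncol(mask))
        gk[mask] <- sign(doff[, , k][mask]) / nm
        g_off[, , k] <- weights$off * gk
      }
      gd <- matrix(0, nrow(mask), ncol(mask))
      gd[mask] <- sign(ddep[mask]) / nm
      g_dep[, , 1] <- weights$depth * gd
    }
    out$grads <- list(heat_logits = g_heat, offset = g_off, depth = g_dep)
  }
  out
}
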