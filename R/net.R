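#' Keypoint-detection network for 3D particle localization
#'
#' Builds the detection network: a convolutional backbone emitting a feature
#' pyramid at strides 4/8/16/32, an FPN-style neck of SPP+CSP and ELAN
#' aggregation blocks that fuses the pyramid down to a single stride-4
#' feature map, and three prediction heads producing per-class center
#' heatmaps, sub-cell offsets, and normalized depth.
#'
#' Backbones: `"resnet50"` (bottleneck residual stages, channels
#' 256/512/1024/2048), `"resnet18"` (basic residual stages, 64/128/256/512)
#' and `"tiny"` (plain convolutional stages, 16/32/64/128) for CPU-scale
#' experiments.  Neck channel widths scale proportionally with the backbone
#' (relative to the 2048-channel reference), floored at 16 channels so the
#' heads keep a usable width at the tiny scale.
#'
#' @param backbone one of `"tiny"`, `"resnet18"`, `"resnet50"`.
#' @param input_size square network input edge in px; divisible by 32.
#'   1024 is the full-scale default; 256 is the tiny-config default.
#' @param classes named list of [bead_class()] objects (fixes heatmap
#'   channel order).
#' @param config an [optical_config()] (z normalization range).
#' @param seed weight-initialization seed.
#' @return A `defocus_net`: list with `plan`, `params`, `meta`.
#' @export
build_net <- function(backbone = c("tiny", "resnet18", "resnet50"),
                      input_size = 256L, classes = default_bead_classes(),
                      config = optical_config(), seed = 1L) {
  backbone <- match.arg(backbone)
  plan <- net_plan(backbone, input_size, classes, config)
  params <- net_init_params(plan, substream_seed(seed, "net-init"))
  structure(list(plan = plan, params = params, meta = plan$meta),
            class = "defocus_net", classes = classes)
}

#' @export
print.defocus_net <- function(x, ...) {
  np <- sum(vapply(x$params, function(p)
    if (is.null(p)) 0 else length(p$W) + length(p$b), 0))
  cat(sprintf("<defocus_net> %s @ %d px input, %d classes, %s parameters\n",
              x$meta$backbone, x$meta$input_size,
              length(x$meta$class_labels), format(np, big.mark = ",")))
  invisible(x)
}

#' Build the architecture plan (shapes only, no weights)
#'
#' The plan fixes every layer's input/output shape at build time, so the
#' full architecture — including the per-stage neck geometry audited by
#' [neck_shape_table()] — can be inspected without allocating weights.
#'
#' @inheritParams build_net
#' @return A plan list: `nodes`, `stages`, `outputs`, `meta`.
#' @export
net_plan <- function(backbone, input_size, classes = default_bead_classes(),
                     config = optical_config()) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32, got ", input_size)
  g <- g_new(input_size, 1L)
  input <- 1L
  pyr <- switch(backbone,
    tiny = backbone_tiny(g, input),
    resnet18 = backbone_resnet(g, input, blocks = c(2, 2, 2, 2), expansion = 1),
    resnet50 = backbone_resnet(g, input, blocks = c(3, 4, 6, 3), expansion = 4),
    stop("unknown backbone: ", backbone))
  nc <- neck_channels(g_shape(g, pyr["C5"])[3])

  p5 <- g_sppcsp(g, pyr["C5"], nc$spp_c2[1], nc$spp_out[1], "SPP+CSP 1")
  t5 <- g_conv(g, g_upsample2(g, p5), nc$spp_out[2], k = 1L)
  p4 <- g_sppcsp(g, pyr["C4"], nc$spp_c2[2], nc$spp_out[2], "SPP+CSP 2")
  f1 <- g_conv(g, g_concat(g, c(t5, p4)), nc$elan_c1[1], k = 1L)
  e1 <- g_elan(g, f1, nc$elan_c2[1], nc$elan_out[1], "ELAN 1")
  t4 <- g_conv(g, g_upsample2(g, e1), nc$spp_out[3], k = 1L)
  p3 <- g_sppcsp(g, pyr["C3"], nc$spp_c2[3], nc$spp_out[3], "SPP+CSP 3")
  f2 <- g_conv(g, g_concat(g, c(t4, p3)), nc$elan_c1[2], k = 1L)
  e2 <- g_elan(g, f2, nc$elan_c2[2], nc$elan_out[2], "ELAN 2")
  l2 <- g_conv(g, pyr["C2"], nc$elan_c1[3], k = 1L)
  t3 <- g_conv(g, g_upsample2(g, e2), nc$elan_c1[3], k = 1L)
  f3 <- g_conv(g, g_concat(g, c(t3, l2)), nc$elan_c1[3], k = 1L)
  e3 <- g_elan(g, f3, nc$elan_c2[3], nc$elan_out[3], "ELAN 3")

  hidden <- max(32L, g_shape(g, e3)[3])  # head width floors at 32
  labels <- vapply(classes, `[[`, "", "label")
  # head biases start at the mean of their targets: -2.19 puts the initial
  # peak probability near 0.1 (focal-loss convention); offsets and
  # normalized depth are uniform on [0, 1], so their heads start at 0.5
  # instead of spending hundreds of optimizer steps climbing from zero.
  hm <- g_conv(g, g_conv(g, e3, hidden, k = 3L), length(labels), k = 1L,
               act = "linear", bias_init = -2.19)
  off <- g_conv(g, g_conv(g, e3, hidden, k = 3L), 2L, k = 1L,
                act = "linear", bias_init = 0.5)
  dep <- g_conv(g, g_conv(g, e3, hidden, k = 3L), 1L, k = 1L,
                act = "linear", bias_init = 0.5)

  list(nodes = g$nodes, stages = g$stages,
       outputs = list(heat = hm, off = off, dep = dep),
       meta = list(backbone = backbone, input_size = input_size,
                   stride = 4L, class_labels = unname(labels),
                   z_min = config$z_min, z_max = config$z_max,
                   head_hidden = hidden))
}

backbone_tiny <- function(g, input) {
  s1 <- g_conv(g, input, 8L, stride = 2L)
  c2 <- g_conv(g, s1, 16L, stride = 2L)
  c3 <- g_conv(g, g_conv(g, c2, 32L, stride = 2L), 32L)
  c4 <- g_conv(g, g_conv(g, c3, 64L, stride = 2L), 64L)
  c5 <- g_conv(g, c4, 128L, stride = 2L)
  c(C2 = c2, C3 = c3, C4 = c4, C5 = c5)
}

backbone_resnet <- function(g, input, blocks, expansion) {
  x <- g_conv(g, input, 64L, k = 7L, stride = 2L)
  x <- g_maxpool(g, x, 3L, stride = 2L, pad = 1L)
  widths <- c(64L, 128L, 256L, 512L)
  pyr <- integer(4)
  for (st in 1:4) {
    stride <- if (st == 1) 1L else 2L
    cout <- widths[st] * expansion
    for (b in seq_len(blocks[st])) {
      s <- if (b == 1) stride else 1L
      x <- if (expansion == 1) res_basic(g, x, cout, s)
           else res_bottleneck(g, x, widths[st], cout, s)
    }
    pyr[st] <- x
  }
  c(C2 = pyr[1], C3 = pyr[2], C4 = pyr[3], C5 = pyr[4])
}

res_bottleneck <- function(g, x, mid, cout, stride) {
  cin <- g_shape(g, x)[3]
  y <- g_conv(g, x, mid, k = 1L)
  y <- g_conv(g, y, mid, k = 3L, stride = stride)
  y <- g_conv(g, y, cout, k = 1L, act = "linear")
  skip <- if (cin != cout || stride != 1L)
    g_conv(g, x, cout, k = 1L, stride = stride, act = "linear") else x
  g_add2(g, y, skip, act = "relu")
}

res_basic <- function(g, x, cout, stride) {
  cin <- g_shape(g, x)[3]
  y <- g_conv(g, x, cout, k = 3L, stride = stride)
  y <- g_conv(g, y, cout, k = 3L, act = "linear")
  skip <- if (cin != cout || stride != 1L)
    g_conv(g, x, cout, k = 1L, stride = stride, act = "linear") else x
  g_add2(g, y, skip, act = "relu")
}

# Neck widths scale with the backbone's deepest channel count relative to
# the 2048-channel reference, floored at 16.
neck_channels <- function(c5) {
  scale <- c5 / 2048
  spp_out <- pmax(16L, as.integer(round(c(256, 256, 128) * scale)))
  elan_out <- pmax(16L, as.integer(round(c(256, 128, 64) * scale)))
  list(spp_out = spp_out, spp_c2 = spp_out,
       elan_c1 = elan_out, elan_c2 = 2L * elan_out, elan_out = elan_out)
}

# SPP+CSP: cross-stage-partial split into two 1x1 branches; one branch runs
# parallel same-size max pools (5/9/13) + a 3x3 fuse, then both branches are
# concatenated and fused 1x1 to `out` channels.  Spatial size preserved.
g_sppcsp <- function(g, x, c2, out, name) {
  stopifnot(g_shape(g, x)[3] >= 1)
  a <- g_conv(g, x, c2, k = 1L)
  b <- g_conv(g, x, c2, k = 1L)
  m5 <- g_maxpool(g, b, 5L)
  m9 <- g_maxpool(g, b, 9L)
  m13 <- g_maxpool(g, b, 13L)
  s <- g_conv(g, g_concat(g, c(b, m5, m9, m13)), c2, k = 3L)
  fuse <- g_conv(g, g_concat(g, c(a, s)), out, k = 1L)
  g_mark_stage(g, name, "sppcsp", c1 = g_shape(g, x)[3], c2 = c2,
               in_id = x, out_id = fuse)
  fuse
}

# ELAN: two parallel 1x1 stems at c2/2; one stem feeds a chain of four 3x3
# convs with taps after conv 2 and conv 4; concat [stem1, stem2, tap1, tap2]
# (= 2*c2 channels) is fused 1x1 to `out`.  Spatial size preserved.
g_elan <- function(g, x, c2, out, name) {
  if (c2 %% 2L != 0L) stop("ELAN c2 must be even, got ", c2)
  half <- c2 %/% 2L
  a <- g_conv(g, x, half, k = 1L)
  b <- g_conv(g, x, half, k = 1L)
  d1 <- g_conv(g, b, half, k = 3L)
  d2 <- g_conv(g, d1, half, k = 3L)
  d3 <- g_conv(g, d2, half, k = 3L)
  d4 <- g_conv(g, d3, half, k = 3L)
  fuse <- g_conv(g, g_concat(g, c(a, b, d2, d4)), out, k = 1L)
  g_mark_stage(g, name, "elan", c1 = g_shape(g, x)[3], c2 = c2,
               in_id = x, out_id = fuse)
  fuse
}

#' Per-stage shape table of the neck
#'
#' One row per SPP+CSP / ELAN stage with its configured channel parameters
#' and the actual input/output spatial sizes and channel counts read from
#' the plan's resolved shapes, for auditing against the reference
#' architecture tables.
#'
#' @param plan a plan from [net_plan()] (or a `defocus_net`'s `$plan`).
#' @return data.frame with columns `stage,kind,c1,c2,in_h,in_w,out_h,out_w,
#'   in_channel,out_channel`.
#' @export
neck_shape_table <- function(plan) {
  rows <- lapply(plan$stages, function(st) {
    ins <- plan$nodes[[st$in_id]]$shape
    outs <- plan$nodes[[st$out_id]]$shape
    data.frame(stage = st$name, kind = st$kind, c1 = st$c1, c2 = st$c2,
               in_h = ins[1], in_w = ins[2], out_h = outs[1], out_w = outs[2],
               in_channel = ins[3], out_channel = outs[3])
  })
  df <- do.call(rbind, rows)
  df[order(df$stage), , drop = FALSE]
}

#' Run the network on one image
#'
#' The image is normalized per-image to zero mean and unit variance and
#' pushed through the graph.  The heatmap head is squashed through a
#' sigmoid; offsets and depth are returned raw.
#'
#' @param net a `defocus_net`.
#' @param image numeric matrix matching the configured input size (use
#'   [detect_particles()] for automatic rescaling).
#' @param cache keep forward intermediates (needed for backprop).
#' @return List with `maps` (a `target_maps`-shaped object ready for
#'   [decode_detections()]), `raw` (head outputs: `heat_logits`, `offset`,
#'   `depth`) and, when `cache = TRUE`, `fwd` (engine cache).
#' @export
net_forward <- function(net, image, cache = FALSE) {
  m <- net$meta
  stopifnot(nrow(image) == m$input_size, ncol(image) == m$input_size)
  x <- normalize_image(image)
  fwd <- net_graph_forward(net$plan, net$params, array(x, c(dim(x), 1)),
                           cache = cache)
  logits <- fwd$vals[[net$plan$outputs$heat]]
  offm <- fwd$vals[[net$plan$outputs$off]]
  depm <- fwd$vals[[net$plan$outputs$dep]]
  maps <- structure(list(
    heatmap = 1 / (1 + exp(-logits)), offset = offm, depth = depm[, , 1],
    center_mask = NULL, stride = m$stride, class_labels = m$class_labels,
    z_min = m$z_min, z_max = m$z_max, image_size = m$input_size),
    class = "target_maps")
  out <- list(maps = maps,
              raw = list(heat_logits = logits, offset = offm, depth = depm))
  if (cache) out$fwd <- fwd
  out
}

# Center each image on its own mean (robust to background level) but use a
# fixed intensity scale: per-image sd scaling would erase the absolute
# amplitude of the defocus pattern, which carries depth information (the
# envelope dims as |z| grows and the central lobe brightness encodes the
# sign of z).
normalize_image <- function(image) {
  (image - mean(image)) / 0.1
}

#' Detect particles in an arbitrary-size square image
#'
#' Rescales the image to the network input size (bilinear), runs
#' [net_forward()] and [decode_detections()], and maps the decoded
#' sub-pixel coordinates back to the original pixel grid.
#'
#' @param net a `defocus_net` (or checkpoint loaded with
#'   [load_checkpoint()]).
#' @param image square numeric matrix.
#' @param score_threshold,top_k passed to [decode_detections()].
#' @return Detections data.frame in original-image coordinates.
#' @export
detect_particles <- function(net, image, score_threshold = 0.3, top_k = 100L) {
  if (nrow(image) != ncol(image)) stop("image must be square")
  orig <- nrow(image)
  m <- net$meta
  scaled <- resize_bilinear(image, m$input_size)
  det <- decode_detections(net_forward(net, scaled)$maps,
                           score_threshold = score_threshold, top_k = top_k)
  if (orig != m$input_size) {
    f <- orig / m$input_size
    det$x_px <- (det$x_px + 0.5) * f - 0.5
    det$y_px <- (det$y_px + 0.5) * f - 0.5
  }
  det
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS file with the weights and architecture metadata
#' plus a human-readable `*.yaml` sidecar recording backbone, input size,
#' classes, stride and z normalization.  Loading rebuilds the plan from the
#' metadata and verifies it against the sidecar.
#'
#' @param net a `defocus_net`.
#' @param path checkpoint file path (`.rds`).
#' @return `save_checkpoint`: `path`, invisibly.  `load_checkpoint`: a
#'   `defocus_net`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(meta = net$meta, params = net$params,
               classes = attr(net, "classes")), path)
  side <- list(backbone = net$meta$backbone,
               input_size = net$meta$input_size,
               stride = net$meta$stride,
               classes = as.list(net$meta$class_labels),
               z_min = net$meta$z_min, z_max = net$meta$z_max)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    side <- yaml::read_yaml(sidecar)
    same <- identical(side$backbone, ck$meta$backbone) &&
      side$input_size == ck$meta$input_size &&
      identical(unlist(side$classes), ck$meta$class_labels) &&
      side$z_min == ck$meta$z_min && side$z_max == ck$meta$z_max
    if (!same) stop("checkpoint sidecar disagrees with stored metadata: ", path)
  }
  cfg <- optical_config(z_min = ck$meta$z_min, z_max = ck$meta$z_max,
                        z_step = (ck$meta$z_max - ck$meta$z_min) / 400)
  classes <- if (!is.null(ck$classes)) ck$classes else {
    cls <- default_bead_classes()
    cls[intersect(ck$meta$class_labels, names(cls))]
  }
  plan <- net_plan(ck$meta$backbone, ck$meta$input_size, classes, cfg)
  plan$meta <- ck$meta
  structure(list(plan = plan, params = ck$params, meta = ck$meta),
            class = "defocus_net")
}
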