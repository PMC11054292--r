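test_that("input size must divide by 32", {
  expect_error(net_plan("tiny", 1023), "divisible by 32")
  expect_error(build_net("tiny", input_size = 100), "divisible by 32")
})

test_that("backbone pyramids land at the documented strides and widths", {
  plan50 <- net_plan("resnet50", 1024)
  tab <- neck_shape_table(plan50)
  spp1 <- tab[tab$stage == "SPP+CSP 1", ]
  expect_equal(spp1$in_h, 32); expect_equal(spp1$in_channel, 2048)

  plan_t <- net_plan("tiny", 256)
  tt <- neck_shape_table(plan_t)
  expect_equal(tt[tt$stage == "ELAN 3", "out_h"], 64)  # stride 4 of 256
  # final head maps are stride 4
  hm_shape <- plan_t$nodes[[plan_t$outputs$heat]]$shape
  expect_equal(hm_shape, c(64, 64, 2))
  off_shape <- plan_t$nodes[[plan_t$outputs$off]]$shape
  expect_equal(off_shape[3], 2)
})

test_that("SPP+CSP and ELAN stages preserve spatial size", {
  for (plan in list(net_plan("tiny", 256), net_plan("resnet18", 512))) {
    tab <- neck_shape_table(plan)
    expect_true(all(tab$in_h == tab$out_h & tab$in_w == tab$out_w))
    expect_true(all(tab$c1 == tab$in_channel))
  }
})

test_that("forward pass emits finite maps of the declared shapes", {
  cfg <- mini_optical()
  net <- build_net("tiny", 128, mini_classes, cfg, seed = 2)
  # a realistic empty scene: background plus camera noise
  img <- with_seed(3, matrix(0.15 + rnorm(128 * 128, sd = 0.02), 128, 128))
  out <- net_forward(net, img)
  expect_equal(dim(out$maps$heatmap), c(32, 32, 2))
  expect_equal(dim(out$maps$offset), c(32, 32, 2))
  expect_equal(dim(out$maps$depth), c(32, 32))
  expect_true(all(is.finite(out$maps$heatmap)))
  expect_true(all(out$maps$heatmap >= 0 & out$maps$heatmap <= 1))
  # focal-style bias initialization keeps initial peak probability low
  expect_lt(median(out$maps$heatmap), 0.3)

  # inference determinism
  out2 <- net_forward(net, img)
  expect_identical(out$maps, out2$maps)
})

test_that("the network is translation-equivariant at stride granularity", {
  cfg <- mini_optical()
  lib <- mini_library()
  net <- build_net("tiny", 256, mini_classes, cfg, seed = 4)
  sc <- compose_scene(lib, 1, 256, seed = 8, noise_sd = 0)
  shift <- 12  # 3 cells at stride 4
  img <- sc$pixels
  shifted <- matrix(sc$background, 256, 256)
  shifted[, (shift + 1):256] <- img[, 1:(256 - shift)]
  a1 <- which(net_forward(net, img)$maps$heatmap[, , 1] ==
                max(net_forward(net, img)$maps$heatmap[, , 1]),
              arr.ind = TRUE)[1, ]
  hm2 <- net_forward(net, shifted)$maps$heatmap[, , 1]
  a2 <- which(hm2 == max(hm2), arr.ind = TRUE)[1, ]
  expect_equal(unname(a2["row"]), unname(a1["row"]))
  expect_equal(unname(a2["col"]), unname(a1["col"]) + shift / 4)
})

test_that("loss is zero iff prediction equals target, and terms decompose", {
  cfg <- mini_optical()
  ann <- data.frame(particle_id = 1, class = "small", x_px = 30.2,
                    y_px = 41.7, z_um = 0.5)
  tgt <- encode_targets(ann, 64, 4, mini_classes, cfg)
  # a perfect prediction: logits = +/- inf surrogate via large values
  logits <- array(-50, dim(tgt$heatmap))
  logits[tgt$heatmap >= 1] <- 50
  # non-center cells of the splat have 0 < y < 1: focal loss is not zero
  # there unless pred matches y; restrict check to the masked terms
  pred <- list(heat_logits = logits, offset = tgt$offset,
               depth = array(tgt$depth, c(dim(tgt$depth), 1)))
  ls <- total_loss(pred, tgt)
  expect_equal(ls$off, 0)
  expect_equal(ls$depth, 0)
  expect_lt(ls$heat, 1e-3)

  # empty mask: only the heatmap term contributes
  empty <- encode_targets(ann[0, ], 64, 4, mini_classes, cfg)
  ls2 <- total_loss(list(heat_logits = array(0, dim(tgt$heatmap)),
                         offset = array(0.3, dim(tgt$offset)),
                         depth = array(0.7, c(dim(tgt$depth), 1))), empty)
  expect_equal(ls2$off, 0)
  expect_equal(ls2$depth, 0)
  expect_equal(ls2$total, ls2$heat)
})

test_that("the focal term matches the hand-evaluated single-cell formula", {
  cfg <- mini_optical()
  # one annotated center cell, prediction 0.5 there
  hm <- array(0, c(4, 4, 1)); hm[2, 2, 1] <- 1
  tgt <- structure(list(heatmap = hm, offset = array(0, c(4, 4, 2)),
                        depth = matrix(0, 4, 4),
                        center_mask = matrix(FALSE, 4, 4), stride = 4L,
                        class_labels = "small", z_min = -2, z_max = 2,
                        image_size = 16L), class = "target_maps")
  logits <- array(-50, c(4, 4, 1))
  logits[2, 2, 1] <- 0                      # sigmoid -> 0.5
  ls <- total_loss(list(heat_logits = logits,
                        offset = array(0, c(4, 4, 2)),
                        depth = array(0, c(4, 4, 1))), tgt)
  expect_equal(ls$heat, -(1 - 0.5)^2 * log(0.5), tolerance = 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- mini_optical()
  lib <- mini_library()
  net <- build_net("tiny", 64, mini_classes, cfg, seed = 6)
  img <- with_seed(11, matrix(runif(64 * 64), 64, 64))
  ann <- data.frame(particle_id = 1, class = "big", x_px = 33.4,
                    y_px = 28.9, z_um = -1)
  tgt <- encode_targets(ann, 64, 4, mini_classes, cfg)
  out <- net_forward(net, img, cache = TRUE)
  ls <- total_loss(out$raw, tgt, grads = TRUE)
  hg <- setNames(list(ls$grads$heat_logits, ls$grads$offset, ls$grads$depth),
                 as.character(unlist(net$plan$outputs)))
  g <- defocustrack:::net_graph_backward(net$plan, net$params, out$fwd, hg)
  eps <- 1e-6
  for (id in with_seed(12, sample(which(!vapply(g, is.null, TRUE)), 4))) {
    ii <- which.max(abs(g[[id]]$W))
    net2 <- net
    net2$params[[id]]$W[ii] <- net$params[[id]]$W[ii] + eps
    l1 <- total_loss(net_forward(net2, img)$raw, tgt)$total
    net2$params[[id]]$W[ii] <- net$params[[id]]$W[ii] - eps
    l0 <- total_loss(net_forward(net2, img)$raw, tgt)$total
    expect_equal((l1 - l0) / (2 * eps), g[[id]]$W[ii], tolerance = 1e-4)
  }
})

test_that("one optimizer step decreases the loss for most seeds", {
  cfg <- mini_optical()
  lib <- mini_library()
  sc <- compose_scene(lib, 2, 128, seed = 3)
  tgt <- encode_targets(sc$annotations, 128, 4, mini_classes, cfg)
  wins <- 0L
  for (s in 1:10) {
    net <- build_net("tiny", 128, mini_classes, cfg, seed = s)
    state <- defocustrack:::adam_new(net$params)
    out <- net_forward(net, sc$pixels, cache = TRUE)
    ls <- total_loss(out$raw, tgt, grads = TRUE)
    hg <- setNames(list(ls$grads$heat_logits, ls$grads$offset,
                        ls$grads$depth),
                   as.character(unlist(net$plan$outputs)))
    g <- defocustrack:::net_graph_backward(net$plan, net$params, out$fwd, hg)
    upd <- defocustrack:::adam_step(net$params, g, state, 1e-3)
    net$params <- upd$params
    ls2 <- total_loss(net_forward(net, sc$pixels)$raw, tgt)
    if (ls2$total < ls$total) wins <- wins + 1L
  }
  expect_gte(wins, 9)
})

test_that("checkpoints round-trip and sidecar tampering is caught", {
  cfg <- mini_optical()
  net <- build_net("tiny", 128, mini_classes, cfg, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  img <- with_seed(5, matrix(runif(128^2), 128, 128))
  expect_identical(net_forward(net, img)$maps,
                   net_forward(back, img)$maps)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  side$input_size <- 512
  yaml::write_yaml(side, paste0(path, ".yaml"))
  expect_error(load_checkpoint(path), "sidecar")
})

test_that("a tiny net overfits one scene to sub-pixel accuracy", {
  cfg <- optical_config(z_min = -5, z_max = 5, z_step = 0.25, seed = 1)
  cls <- default_bead_classes()
  lib <- build_calibration_library(cls, cfg)
  sc <- compose_scene(lib, 3, 256, seed = 5)
  maps <- encode_targets(sc$annotations, 256, 4, cls, cfg)
  net <- build_net("tiny", 256, cls, cfg, seed = 1)
  state <- defocustrack:::adam_new(net$params)
  for (step in 1:300) {
    out <- net_forward(net, sc$pixels, cache = TRUE)
    ls <- total_loss(out$raw, maps, grads = TRUE)
    hg <- setNames(list(ls$grads$heat_logits, ls$grads$offset,
                        ls$grads$depth),
                   as.character(unlist(net$plan$outputs)))
    g <- defocustrack:::net_graph_backward(net$plan, net$params, out$fwd, hg)
    upd <- defocustrack:::adam_step(net$params, g, state, 1e-3)
    net$params <- upd$params; state <- upd$state
  }
  det <- detect_particles(net, sc$pixels, 0.3)
  m <- match_detections(det, sc$annotations, gate = 10)
  expect_equal(nrow(m$pairs), 3)      # recall 1.0
  expect_length(m$missed, 0)
  expect_lt(max(m$pairs$dist_px), 1)  # xy error < 1 px
})
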