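test_that("forward pass honours the shape contract and softmax constraint", {
  net <- build_unet(unet_config(depth = 1, base_channels = 4, seed = 1))
  x <- matrix(rnorm(16 * 16), 16, 16)
  fw <- unet_forward(net, x)
  expect_equal(dim(fw$probs), c(16, 16, 2, 1))
  sums <- fw$probs[, , 1, 1] + fw$probs[, , 2, 1]
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
  # indivisible size and wrong channel count are configuration errors
  expect_error(unet_forward(net, matrix(0, 15, 16)), "divisible")
  bad <- array(0, c(16, 16, 3, 1))
  expect_error(unet_forward(net, bad), "channel")
})

test_that("parameter count equals the layer-by-layer closed form", {
  for (cfg in list(c(1, 4), c(2, 8), c(2, 4))) {
    net <- build_unet(unet_config(depth = cfg[1], base_channels = cfg[2],
                                  seed = 2))
    expect_equal(n_parameters(net),
                 unet_param_count_oracle(cfg[1], cfg[2]))
    expect_equal(conv_layer_count(net$cfg), 4 * cfg[1] + 3)
  }
  # the depth-2 architecture carries the canonical 11 conv layers
  expect_equal(conv_layer_count(unet_config(depth = 2)), 11)
})

test_that("initialization is seeded and reproducible", {
  a <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 33))
  b <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 33))
  expect_identical(a$params, b$params)
  c_ <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 34))
  expect_false(identical(a$params, c_$params))
})

test_that("a zeroed final layer yields the uniform 0.5/0.5 map", {
  net <- build_unet(unet_config(depth = 1, base_channels = 4, seed = 3))
  net$params$final$W[] <- 0
  net$params$final$b[] <- 0
  fw <- unet_forward(net, matrix(rnorm(16 * 16), 16, 16))
  expect_equal(as.numeric(fw$probs), rep(0.5, length(fw$probs)))
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(4)
  net <- build_unet(unet_config(depth = 1, base_channels = 2, seed = 7))
  x <- matrix(rnorm(8 * 8), 8, 8)
  g <- random_mask(8, 0.3)
  lg <- unet_loss_and_grads(net, x, g)
  flat <- amypetseg:::flatten_params(net$params)
  gflat <- amypetseg:::flatten_params(lg$grads)
  eps <- 1e-5
  for (nm in names(flat)) {
    for (i in sample(length(flat[[nm]]), min(3, length(flat[[nm]])))) {
      fp <- flat; fp[[nm]][i] <- fp[[nm]][i] + eps
      np <- net; np$params <- amypetseg:::unflatten_params(net$params, fp)
      lp <- unet_loss_and_grads(np, x, g)$loss
      fm <- flat; fm[[nm]][i] <- fm[[nm]][i] - eps
      nn <- net; nn$params <- amypetseg:::unflatten_params(net$params, fm)
      lm <- unet_loss_and_grads(nn, x, g)$loss
      expect_equal(gflat[[nm]][i], (lp - lm) / (2 * eps),
                   tolerance = 1e-4, info = nm)
    }
  }
})

test_that("every parameter array receives gradient on a nondegenerate batch", {
  set.seed(5)
  net <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 11))
  imgs <- lapply(1:2, function(i) matrix(rnorm(16 * 16), 16, 16))
  msks <- lapply(1:2, function(i) random_mask(16, 0.3))
  lg <- unet_loss_and_grads(net, imgs, msks)
  gflat <- amypetseg:::flatten_params(lg$grads)
  for (nm in names(gflat))
    expect_gt(max(abs(gflat[[nm]])), 0, label = nm)
})

test_that("auxiliary cross-entropy term shifts loss and gradients coherently", {
  set.seed(6)
  net <- build_unet(unet_config(depth = 1, base_channels = 2, seed = 13))
  x <- matrix(rnorm(8 * 8), 8, 8)
  g <- random_mask(8, 0.4)
  l0 <- unet_loss_and_grads(net, x, g, lambda_ce = 0)
  l1 <- unet_loss_and_grads(net, x, g, lambda_ce = 0.5)
  expect_equal(l1$loss, l1$iou_loss + 0.5 * l1$ce)
  expect_equal(l0$iou_loss, l1$iou_loss)
  expect_gt(l1$ce, 0)
  # gradient of the combined objective also passes a finite difference spot
  flat <- amypetseg:::flatten_params(net$params)
  gflat <- amypetseg:::flatten_params(l1$grads)
  nm <- "final.W"; i <- 1; eps <- 1e-5
  fp <- flat; fp[[nm]][i] <- fp[[nm]][i] + eps
  np <- net; np$params <- amypetseg:::unflatten_params(net$params, fp)
  lp <- unet_loss_and_grads(np, x, g, lambda_ce = 0.5)$loss
  fm <- flat; fm[[nm]][i] <- fm[[nm]][i] - eps
  nn <- net; nn$params <- amypetseg:::unflatten_params(net$params, fm)
  lm <- unet_loss_and_grads(nn, x, g, lambda_ce = 0.5)$loss
  expect_equal(gflat[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
})

test_that("checkpoints round-trip through disk with their config", {
  net <- build_unet(unet_config(depth = 1, base_channels = 2, seed = 17))
  path <- withr::local_tempfile(fileext = ".rds")
  save_unet(net, path)
  back <- load_unet(path)
  expect_identical(back$params, net$params)
  expect_identical(back$cfg, net$cfg)
  x <- matrix(rnorm(64), 8, 8)
  expect_identical(unet_predict(net, x), unet_predict(back, x))
})
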