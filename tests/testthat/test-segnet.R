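# Small-geometry configurations are used for the contract tests; the
# standard 256 px fixture network is exercised in the acceptance suite.

test_that("forward pass preserves shape and emits probabilities in [0, 1]", {
  cfg <- segnet_config(input_size = 64L, depth = 2L, base_filters = 4L, seed = 1)
  net <- build_segnet(cfg)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  pred <- predict_mask(net, img)
  expect_equal(dim(pred$prob), c(64, 64))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  expect_true(all(pred$mask %in% c(0L, 1L)))
  # larger inputs are center-cropped; smaller ones error
  big <- matrix(runif(96 * 96), 96, 96)
  expect_equal(dim(predict_mask(net, big)$prob), c(64, 64))
  expect_error(predict_mask(net, matrix(0, 32, 32)), "smaller")
})

test_that("building is deterministic and depth must divide the input size", {
  cfg <- segnet_config(input_size = 64L, depth = 3L, base_filters = 4L, seed = 5)
  a <- build_segnet(cfg)
  b <- build_segnet(cfg)
  expect_identical(a$params, b$params)
  expect_error(segnet_config(input_size = 256L, depth = 9L), "divisible")
  expect_error(segnet_config(depth = 0L), ">= 1")
})

test_that("forward and backward match an independent double-precision reference", {
  cfg <- segnet_config(input_size = 16L, depth = 2L, base_filters = 2L, seed = 3)
  net <- build_segnet(cfg)
  set.seed(1)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  ref <- ref_segnet_grads(net$params, x / cfg$normalize - 0.5, y)
  pred <- predict_mask(net, x / cfg$normalize * 255)
  expect_lt(max(abs(pred$prob - ref$prob)), 1e-5) # single-precision forward
  fw <- veindyn:::segnet_forward(net, x / cfg$normalize - 0.5, want_cache = TRUE)
  g <- veindyn:::segnet_backward(net, fw$cache, (fw$prob - y) / length(y))
  for (nm in names(ref$grads)) {
    a <- as.numeric(ref$grads[[nm]])
    b <- as.numeric(g[[nm]])
    rel <- sqrt(sum((a - b)^2)) / (sqrt(sum(a^2)) + 1e-12)
    expect_lt(rel, 1e-4)
  }
})

test_that("the loss gradient agrees with a finite difference along the gradient direction", {
  cfg <- segnet_config(input_size = 16L, depth = 2L, base_filters = 2L, seed = 3)
  net <- build_segnet(cfg)
  set.seed(1)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  fw <- veindyn:::segnet_forward(net, x, want_cache = TRUE)
  g <- veindyn:::segnet_backward(net, fw$cache, (fw$prob - y) / length(y))
  loss_at <- function(params) {
    m <- net
    m$params <- params
    veindyn:::bce_loss(veindyn:::segnet_forward(m, x)$prob, y)
  }
  gnorm2 <- sum(vapply(names(g), function(nm) sum(g[[nm]]^2), numeric(1)))
  eps <- 1e-3 / sqrt(gnorm2)
  step <- function(sign) {
    p <- net$params
    for (nm in names(p)) p[[nm]] <- p[[nm]] + sign * eps * g[[nm]]
    p
  }
  directional <- (loss_at(step(1)) - loss_at(step(-1))) / (2 * eps)
  # ReLU/maxpool kinks and single precision bound the attainable agreement
  expect_lt(abs(directional - gnorm2) / gnorm2, 0.05)
})

test_that("training reduces the loss and is reproducible under its seed", {
  cfg <- segnet_config(
    input_size = 64L, depth = 2L, base_filters = 4L,
    epochs = 6L, batch_size = 2L, seed = 11
  )
  sp <- scene_spec(c(64L, 64L),
    vessels = list(vessel(rbind(c(1, 32), c(64, 32)), diameter_mm = 1.4)),
    noise_sigma = 2, seed = 1
  )
  pairs <- lapply(1:8, function(i) {
    render_frame(sp,
      dilation_scale = runif(1, 0.9, 1.3),
      translation = c(0, (i - 4) * 3), rng_seed = i
    )
  })
  imgs <- lapply(pairs, `[[`, "image")
  msks <- lapply(pairs, `[[`, "mask")
  tr1 <- train_segnet(build_segnet(cfg), imgs, msks)
  expect_equal(nrow(tr1$history), 6L)
  expect_lt(tail(tr1$history$loss, 1), tr1$history$loss[1])
  tr2 <- train_segnet(build_segnet(cfg), imgs, msks)
  expect_identical(tr1$history, tr2$history)
  expect_identical(tr1$model$params, tr2$model$params)
  expect_error(train_segnet(build_segnet(cfg), imgs[1:2], msks[1:2]), "at least 4")
  expect_error(train_segnet(build_segnet(cfg), list(), list()), "Empty")
  expect_error(
    train_segnet(build_segnet(cfg), imgs, c(msks[1:7], list(matrix(0, 32, 32)))),
    "smaller"
  )
})

test_that("an all-zero network emits probability 0.5 and the >= threshold keeps it", {
  cfg <- segnet_config(input_size = 64L, depth = 1L, base_filters = 2L, seed = 1)
  net <- build_segnet(cfg)
  net$params <- lapply(net$params, function(w) w * 0)
  pred <- predict_mask(net, matrix(runif(64 * 64, 0, 255), 64, 64))
  expect_true(all(pred$prob == 0.5))
  expect_true(all(pred$mask == 1L)) # mask is prob >= threshold
})

test_that("dice follows its formula, including the empty-empty convention", {
  a <- matrix(0L, 8, 8)
  b <- matrix(0L, 8, 8)
  expect_equal(dice(a, b), 1)
  a[1:4, ] <- 1L
  expect_equal(dice(a, a), 1)
  b2 <- matrix(0L, 8, 8)
  b2[5:8, ] <- 1L
  expect_equal(dice(a, b2), 0)
  half <- matrix(0L, 8, 8)
  half[1:2, ] <- 1L # half of a's area
  expect_equal(dice(half, a), 2 * 16 / (16 + 32))
  expect_error(dice(a, matrix(0L, 4, 4)), "differ")
})

test_that("weights survive a JSON save/load round trip", {
  cfg <- segnet_config(input_size = 64L, depth = 2L, base_filters = 3L, seed = 2)
  net <- build_segnet(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_segnet(net, path)
  back <- load_segnet(path)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_equal(predict_mask(back, img)$prob, predict_mask(net, img)$prob,
    tolerance = 1e-12
  )
})

test_that("manual PNG masks load as binary matrices", {
  path <- withr::local_tempfile(fileext = ".png")
  m <- matrix(0L, 16, 16)
  m[4:9, 6:12] <- 1L
  write_mask_png(m, path)
  back <- read_mask_png(path)
  expect_equal(back, m)
})
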