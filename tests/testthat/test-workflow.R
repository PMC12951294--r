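test_that("run configs round-trip through YAML and reject unknown keys", {
  cfg <- defaultRunConfig(nPhantoms = 12L, maxSteps = 40L)
  path <- file.path(withr::local_tempdir(), "run.yaml")
  yaml::write_yaml(cfg[c("nPhantoms", "maxSteps", "lambda")], path)
  back <- readRunConfig(path)
  expect_identical(back$nPhantoms, 12L)
  expect_identical(back$maxSteps, 40L)
  expect_identical(back$batchSize, 2L)   # default preserved

  yaml::write_yaml(list(nPhantom = 3), path)  # typo
  expect_error(readRunConfig(path), "unknown config keys")
})

test_that("the learning rate follows the cosine schedule between its endpoints", {
  expect_identical(cosineLearningRate(0, 1000), 3e-5)
  expect_lt(cosineLearningRate(1000, 1000), 1e-12)
  expect_equal(cosineLearningRate(500, 1000), 1.5e-5, tolerance = 1e-12)
  mid <- vapply(0:10 * 100, cosineLearningRate, numeric(1), maxSteps = 1000)
  expect_true(all(diff(mid) < 0))
})

test_that("training is reproducible from a fixed state and seed", {
  cfg <- networkConfig(baseChannels = 4L, heads = c(1L, 2L, 2L, 4L, 1L),
                       timeDim = 8L)
  net <- initNoiseNetwork(cfg, seed = 3)
  sched <- buildSchedule(20L, 50)
  set.seed(60)
  pairs <- replicate(4, {
    p <- matrix(runif(256, 0, 255), 16, 16)
    list(x0 = p, mu = p + matrix(rnorm(256, 0, 20), 16, 16))
  }, simplify = FALSE)
  r1 <- trainNoiseNetwork(net, pairs, sched, steps = 3L, seed = 17,
                          logEvery = 1L)
  r2 <- trainNoiseNetwork(net, pairs, sched, steps = 3L, seed = 17,
                          logEvery = 1L)
  expect_identical(r1$log$loss, r2$log$loss)
  expect_identical(r1$net@params, r2$net@params)
})

test_that("the end-to-end study produces a per-image report reproducibly", {
  cfg <- defaultRunConfig(nPhantoms = 10L, gridPx = 32L, spacingMm = 0.2,
                          ringElements = 32L, param = 8, T = 20L,
                          baseChannels = 8L, heads = c(1L, 2L, 4L, 8L, 1L),
                          timeDim = 16L, maxSteps = 20L, seed = 5L)
  out <- withr::local_tempdir()
  res <- runRestorationStudy(cfg, outDir = out)
  expect_identical(unname(res$split), c(8L, 1L, 1L))
  expect_identical(nrow(res$report$restored$perImage), 1L)
  expect_true(all(is.finite(res$report$restored$perImage$psnr)))
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_true(file.exists(file.path(out, "loss_log.csv")))
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  expect_true(file.exists(file.path(out, "report.json")))

  res2 <- runRestorationStudy(cfg)
  expect_identical(res$report$restored$perImage$psnr,
                   res2$report$restored$perImage$psnr)
})

test_that("restoring an undegraded pipeline keeps near-reference quality", {
  # identity degradation: mu equals the full-view reference; restoration
  # must stay close to it even with a briefly trained network
  imgs <- makePhantomDataset(6, "disks", grid = 32L, seed = 21L)
  geom <- RingGeometry(nElements = 32L, imageExtent = 6.4)
  pairs <- buildPairedDataset(imgs, geom, "sparse", 32)
  expect_identical(pixels(pairs[[1]]$x0), pixels(pairs[[1]]$mu))
  sched <- buildSchedule(100L, 50)
  cfgN <- networkConfig(baseChannels = 8L, heads = c(1L, 2L, 4L, 8L, 1L),
                        timeDim = 16L)
  net <- initNoiseNetwork(cfgN, seed = 2)
  tr <- trainNoiseNetwork(net, pairs[1:5], sched, steps = 200L, lr0 = 1e-3,
                          seed = 3)
  set.seed(4)
  restored <- reverseSample(pixels(pairs[[6]]$mu), tr$net, sched)
  expect_true(is.finite(psnr(pixels(pairs[[6]]$x0), restored)))
  expect_gt(psnr(pixels(pairs[[6]]$x0), restored), 15)
})
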