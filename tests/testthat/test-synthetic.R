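# The synthetic colony-image generator: manifest fidelity, determinism,
# morphology separability.

test_that("the reference manifest reproduces the published per-class counts", {
  m <- table1Manifest()
  expect_identical(nrow(m), 24L)
  expect_identical(m$sampleCount[5], 2562L)
  expect_identical(m$sampleCount[13], 177L)
  expect_identical(sum(m$sampleCount), 18221L)
  expect_identical(max(m$sampleCount) / min(m$sampleCount), 2562 / 177)
})

test_that("scaled manifests round half even with a per-class floor", {
  m <- table1Manifest(scale = 0.1, minPerClass = 1L)
  expect_identical(m$sampleCount[13], 18L)  # round(17.7)
  m2 <- table1Manifest(scale = 0.001, minPerClass = 5L)
  expect_true(all(m2$sampleCount >= 5L))
  expect_error(table1Manifest(scale = 0), "positive")
})

test_that("the 24 morphology specs are pairwise distinct in at least two parameters", {
  specs <- defaultClassSpecs()
  cols <- setdiff(names(specs), c("classId", "speciesName"))
  for (i in 1:23) for (j in (i + 1):24) {
    ndiff <- sum(vapply(cols, function(cl) {
      specs[[cl]][i] != specs[[cl]][j]
    }, logical(1)))
    expect_gte(ndiff, 2)
  }
})

test_that("rendering is a pure function of spec, size and seed", {
  spec <- defaultClassSpecs()[4, ]
  a <- renderPlateImage(spec, 48, 48, seed = 7L)
  b <- renderPlateImage(spec, 48, 48, seed = 7L)
  expect_identical(a, b)
  c <- renderPlateImage(spec, 48, 48, seed = 8L)
  expect_false(identical(a, c))
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(dim(a), c(48L, 48L, 3L))
  expect_error(renderPlateImage(spec, 16, 16, 1L), "at least 32")
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(renderPlateImage(defaultClassSpecs()[1, ], 32, 32, 5L))
  expect_identical(.Random.seed, before)
})

test_that("the hemolysis ring appears only when the halo flag is on", {
  # a single colony rendered near the plate center (seed chosen so both
  # comparison annuli stay on the agar); locate it from the luminance map
  # and compare the annulus just outside the border with plain agar
  spec <- defaultClassSpecs()[16, ]  # golden, beta halo
  spec$countMean <- 1; spec$countSd <- 0
  spec$radiusMean <- 30; spec$radiusSd <- 0.1
  spec$borderRoughness <- 0.02
  findColony <- function(img) {
    lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    mask <- lum > 0.55 & img[, , 3] > 0.25  # bright and not bare agar
    idx <- which(mask, arr.ind = TRUE)
    list(cy = mean(idx[, 1]), cx = mean(idx[, 2]),
         r = sqrt(nrow(idx) / pi))
  }
  annulusMean <- function(img, c0, from, to) {
    d <- sqrt((row(img[, , 1]) - c0$cy)^2 + (col(img[, , 1]) - c0$cx)^2)
    sel <- d >= from & d <= to
    vapply(1:3, function(ch) mean(img[, , ch][sel]), numeric(1))
  }
  on <- renderPlateImage(spec, 128, 128, seed = 4L)
  specOff <- spec
  specOff$halo <- FALSE
  off <- renderPlateImage(specOff, 128, 128, seed = 4L)

  c1 <- findColony(on)
  ringOn <- annulusMean(on, c1, c1$r + 3, c1$r + 6)
  farOn <- annulusMean(on, c1, c1$r + 10, c1$r + 14)
  c2 <- findColony(off)
  ringOff <- annulusMean(off, c2, c2$r + 3, c2$r + 6)
  farOff <- annulusMean(off, c2, c2$r + 10, c2$r + 14)
  # halo on: the near annulus departs clearly from the plain agar
  expect_gt(sum(abs(ringOn - farOn)), 0.03)
  # halo off: near annulus statistics match the background within noise
  expect_lt(sum(abs(ringOff - farOff)), 0.02)
})

test_that("dataset generation conserves counts and is byte-deterministic", {
  man <- table1Manifest(scale = 0.0005, minPerClass = 2L, seed = 77L)
  d1 <- withr::local_tempdir()
  mf1 <- generateDataset(man, defaultClassSpecs(), d1, imageSize = 32L)
  onDisk <- table(mf1$class_id)
  expect_identical(as.integer(onDisk[as.character(man$classId)]),
                   man$sampleCount)
  expect_true(all(file.exists(file.path(d1, mf1$path))))

  # regeneration with the same seed: identical bytes and identical manifest
  d2 <- withr::local_tempdir()
  mf2 <- generateDataset(man, defaultClassSpecs(), d2, imageSize = 32L)
  expect_identical(mf1$path, mf2$path)
  expect_identical(unname(tools::md5sum(file.path(d1, mf1$path))),
                   unname(tools::md5sum(file.path(d2, mf2$path))))

  # a different global seed changes the bytes, never the counts
  man3 <- table1Manifest(scale = 0.0005, minPerClass = 2L, seed = 78L)
  d3 <- withr::local_tempdir()
  mf3 <- generateDataset(man3, defaultClassSpecs(), d3, imageSize = 32L)
  expect_identical(table(mf3$class_id), onDisk)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, mf1$path[1]))),
    unname(tools::md5sum(file.path(d3, mf3$path[1])))
  ))

  expect_error(
    generateDataset(man, defaultClassSpecs()[1:3, ], withr::local_tempdir()),
    "no morphology spec"
  )
})

test_that("two distinct colony classes separate with a trivial color-centroid classifier", {
  specs <- defaultClassSpecs()[c(2, 20), ]  # yellow cream vs green gray
  nTrain <- 60L
  nTest <- 40L
  feat <- function(img) {
    # joint 4x4x4 RGB color histogram, normalized
    b <- floor(img * 4)
    b[b > 3] <- 3
    idx <- b[, , 1] * 16 + b[, , 2] * 4 + b[, , 3] + 1
    tabulate(idx, 64) / length(idx)
  }
  getSet <- function(offset, n) {
    f <- matrix(0, 2 * n, 64)
    y <- rep(1:2, each = n)
    for (ci in 1:2) for (j in seq_len(n)) {
      img <- renderPlateImage(specs[ci, ], 32, 32,
                              seed = offset + ci * 10000L + j)
      f[(ci - 1) * n + j, ] <- feat(img)
    }
    list(f = f, y = y)
  }
  tr <- getSet(0L, nTrain)
  te <- getSet(500L, nTest)
  centroids <- rbind(colMeans(tr$f[tr$y == 1, ]), colMeans(tr$f[tr$y == 2, ]))
  pred <- apply(te$f, 1, function(v) {
    which.min(c(sum((v - centroids[1, ])^2), sum((v - centroids[2, ])^2)))
  })
  expect_gte(mean(pred == te$y), 0.95)
})
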