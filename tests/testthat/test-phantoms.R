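test_that("built-in phantom ground truths match their closed forms", {
  A <- makePhantom("A")
  expect_equal(A@truth@depth, 6)
  expect_equal(A@truth@volume, 2 / 3 * pi * 216, tolerance = 1e-12)
  expect_equal(A@truth@areaProjected, pi * 36, tolerance = 1e-12)
  expect_equal(A@truth@area3d, 2 * pi * 36, tolerance = 1e-12)
  expect_equal(A@truth@perimeter, 2 * pi * 6, tolerance = 1e-12)

  B <- makePhantom("B")
  expect_equal(B@truth@depth, 7.5)   # ramp from 0 to its specified maximum
  expect_equal(B@truth@areaProjected, (20 + 12) / 2 * 18)
  expect_equal(B@truth@volume, 7.5 * 18 * (10 - 8 / 3), tolerance = 1e-12)

  C <- makePhantom("C")
  expect_equal(C@truth@axisMajor, 18)
  expect_equal(C@truth@volume, 2 / 3 * pi * 9 * 5.5 * 4, tolerance = 1e-12)
  # numerically integrated surface area against a finer independent grid
  expect_gt(C@truth@area3d, C@truth@areaProjected)

  D <- makePhantom("D")
  expect_equal(D@truth@depth, 5.4)
  D2 <- makePhantom("D")
  expect_identical(reportValues(D@truth), reportValues(D2@truth))
  D3 <- makePhantom("D", seed = 8)
  expect_false(identical(reportValues(D@truth), reportValues(D3@truth)))
  # internal consistency required of every phantom
  for (p in list(A, B, C, D)) {
    expect_gte(p@truth@axisMajor, p@truth@axisMinor)
    expect_gte(p@truth@area3d, p@truth@areaProjected)
  }
})

test_that("sampled clouds honour the height field, the noise level and the seed", {
  p <- makePhantom("A")
  s0 <- sampleCloud(p, spacing = 0.3, noiseSigma = 0, seed = 1)
  g <- s0$cloud@points
  # noiseless: z equals the phantom surface exactly (plus working distance)
  expect_lt(max(abs(g[, 3] - 200 - p@depth(g[, 1], g[, 2]))), 1e-12)
  expect_equal(sum(s0$woundMask), sum(p@inside(g[, 1], g[, 2])))

  sN <- sampleCloud(p, spacing = 0.05, noiseSigma = 0.1, seed = 2)
  res <- sN$cloud@points[, 3] - 200 -
    p@depth(sN$cloud@points[, 1], sN$cloud@points[, 2])
  expect_gt(length(res), 1e5)
  expect_lt(abs(sd(res) / 0.1 - 1), 0.05)

  sA <- sampleCloud(p, spacing = 0.2, noiseSigma = 0.1, seed = 3)
  sB <- sampleCloud(p, spacing = 0.2, noiseSigma = 0.1, seed = 3)
  expect_identical(sA$cloud@points, sB$cloud@points)
})

test_that("rendered wound images partition the footprint and support end-to-end classification", {
  pC <- makePhantom("C")
  img <- renderWoundImage(pC, spacing = 0.2, seed = 4)
  masks <- img$tissueMasks
  wound <- sampleCloud(pC, spacing = 0.2, noiseSigma = 0, seed = 1)$woundMask
  tmask <- Reduce(`|`, masks[setdiff(names(masks), "skin")])
  expect_identical(tmask, wound)
  overlap <- Reduce(`+`, lapply(masks[setdiff(names(masks), "skin")],
                                function(m) m * 1))
  expect_true(all(overlap[wound] == 1))
  expect_true(all(overlap[!wound] == 0))

  # single-tissue phantom renders uniformly inside the wound
  pA <- makePhantom("A")
  imgA <- renderWoundImage(pA, spacing = 0.3, noiseSd = 0, seed = 5)
  wA <- sampleCloud(pA, spacing = 0.3, noiseSigma = 0, seed = 1)$woundMask
  for (k in 1:3) expect_lt(diff(range(imgA$image[, , k][wA])), 1e-12)

  # seeded classification recovers the painted tissue maps
  sp <- slicSuperpixels(img$image, wound,
                        nSegments = max(4, round(sum(wound) / 200)))
  seeds <- do.call(rbind, lapply(setdiff(names(masks), "skin"), function(cl) {
    ij <- which(masks[[cl]], arr.ind = TRUE)
    ctr <- colMeans(ij)
    best <- ij[which.min((ij[, 1] - ctr[1])^2 + (ij[, 2] - ctr[2])^2), ]
    data.frame(x = best[2] - 1, y = best[1] - 1, label = cl)
  }))
  cls <- classifyTissue(img$image, sp, seeds)
  truthLab <- matrix(NA_character_, nrow(wound), ncol(wound))
  for (cl in setdiff(names(masks), "skin")) truthLab[masks[[cl]]] <- cl
  ok <- !is.na(cls$labels) & !is.na(truthLab)
  expect_gte(mean(cls$labels[ok] == truthLab[ok]), 0.95)
})

test_that("pipeline accuracy improves as the sampling pitch shrinks", {
  p <- makePhantom("C")
  errAt <- function(sp) {
    rep <- measurePhantom(p, spacing = sp, noiseSigma = 0, seed = 5)
    mean(abs(reportValues(rep) / reportValues(p@truth) - 1))
  }
  errs <- vapply(c(0.5, 0.3, 0.2), errAt, numeric(1))
  expect_lt(errs[3], errs[1] + 0.002)
  expect_lt(errs[3], 0.03)
})

test_that("a simulated rater study emulates independent users and jitter degrades agreement", {
  ph <- list(makePhantom("A"))
  st0 <- simulateRaterStudy(ph, nRaters = 4, spacing = 0.3, noiseSigma = 0,
                            tiltSdDeg = 0, distanceRange = c(200, 200),
                            seed = 1)
  expect_equal(dim(st0@measurements), c(1, 4, 7))
  # without pose or sensor jitter the raters agree almost perfectly
  cv0 <- apply(st0@measurements[1, , ], 2, function(v) sd(v) / abs(mean(v)))
  expect_lt(max(cv0), 0.01)

  stJ <- simulateRaterStudy(ph, nRaters = 4, spacing = 0.3, noiseSigma = 0.3,
                            tiltSdDeg = 4, seed = 1)
  cvJ <- apply(stJ@measurements[1, , ], 2, function(v) sd(v) / abs(mean(v)))
  expect_gt(mean(cvJ), mean(cv0))
})
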