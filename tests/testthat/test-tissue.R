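# two-tone wound image: left half granulation red, right half slough
# yellow, on a skin-toned background ring
twoToneImage <- function(H = 80, W = 80, r = 30, bright = 0) {
  g <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
  inside <- (g$x - W / 2)^2 + (g$y - H / 2)^2 < r^2
  img <- array(0, c(H, W, 3))
  cols <- rbind(skin = c(0.91, 0.76, 0.65),
                red = c(0.70, 0.13, 0.13),
                yellow = c(0.78, 0.60, 0.16))
  lab <- ifelse(!inside, "skin", ifelse(g$x < W / 2, "red", "yellow"))
  for (k in 1:3) img[, , k] <- matrix(cols[lab, k], H, W, byrow = TRUE)
  if (bright != 0) {
    bf <- matrix(1 + bright * ((col(img[, , 1]) - 1) / (W - 1) - 0.5), H, W)
    for (k in 1:3) img[, , k] <- pmin(1, img[, , k] * bf)
  }
  mask <- matrix(inside, H, W, byrow = TRUE)
  list(image = img, mask = mask,
       redMask = matrix(inside & g$x < W / 2, H, W, byrow = TRUE))
}

test_that("chroma features drop brightness and vanish for grays", {
  img <- array(0.5, c(4, 4, 3))
  ab <- toAbFeatures(img)
  expect_lt(max(abs(ab)), 1)
  expect_equal(nrow(ab), 16)

  # a red and a shaded version of the same red: the hue angle in (a, b)
  # is stable and the chroma shift stays well below the lightness shift
  red <- array(c(0.8, 0.1, 0.1), c(1, 1, 3))
  dark <- red * 0.6
  toLab <- function(x) grDevices::convertColor(matrix(as.vector(x), 1),
                                               from = "sRGB", to = "Lab")
  lr <- toLab(red); ld <- toLab(dark)
  hue <- function(l) atan2(l[3], l[2])
  expect_lt(abs(hue(lr) - hue(ld)), 5 * pi / 180)
  relC <- abs(sqrt(sum(ld[2:3]^2)) / sqrt(sum(lr[2:3]^2)) - 1)
  relL <- abs(ld[1] / lr[1] - 1)
  expect_lt(relC, relL)

  tt <- twoToneImage()
  expect_equal(nrow(toAbFeatures(tt$image, tt$mask)), sum(tt$mask))
})

test_that("SLIC partitions the mask into compact, boundary-adherent superpixels", {
  flat <- array(0.5, c(60, 60, 3))
  lab4 <- slicSuperpixels(flat, nSegments = 4)
  sizes <- table(lab4)
  expect_equal(length(sizes), 4)
  expect_lt(max(abs(sizes / mean(sizes) - 1)), 0.2)

  tt <- twoToneImage()
  sp <- slicSuperpixels(tt$image, tt$mask, nSegments = 40)
  expect_true(all(!is.na(sp[tt$mask])))
  expect_true(all(is.na(sp[!tt$mask])))
  # boundary adherence: superpixels stay on one side of the colour edge
  # except for their one-pixel boundary ring
  mid <- ncol(sp) / 2
  for (q in stats::na.omit(unique(as.vector(sp)))) {
    px <- which(sp == q, arr.ind = TRUE)
    left <- sum(px[, 2] <= mid); right <- sum(px[, 2] > mid + 1)
    expect_true(left == 0 || right == 0 ||
                  min(left, right) <= 2 * (max(px[, 2]) - min(px[, 2]) + 2))
  }
  expect_error(slicSuperpixels(flat, nSegments = 1e6), "segments")
})

test_that("seeded k-means labels superpixels by tissue and ignores brightness", {
  tt <- twoToneImage()
  sp <- slicSuperpixels(tt$image, tt$mask, nSegments = 40)
  seeds <- data.frame(x = c(25, 55), y = c(40, 40),
                      label = c("granulation", "slough"))
  cls <- classifyTissue(tt$image, sp, seeds)
  lab <- cls$labels
  ok <- !is.na(lab)
  agree <- mean((lab[ok] == "granulation") == tt$redMask[ok])
  expect_gte(agree, 0.97)

  # adding a brightness gradient changes no labels
  ttb <- twoToneImage(bright = 0.4)
  clsb <- classifyTissue(ttb$image, sp, seeds)
  expect_gte(mean(clsb$labels[ok] == lab[ok]), 0.99)

  # single seeded class claims everything
  cls1 <- classifyTissue(tt$image, sp,
                         data.frame(x = 25, y = 40, label = "granulation"))
  expect_true(all(cls1$labels[ok] == "granulation"))

  # identical seed chroma for two classes is degenerate
  expect_error(classifyTissue(tt$image, sp,
                              data.frame(x = c(25, 25), y = c(40, 40),
                                         label = c("a", "b"))),
               "degenerate")
})

test_that("3D-weighted composition sums to one and upweights steep rims", {
  # flat wound, half/half split
  gc <- gridCloud(function(x, y) 0, ext = 8, spacing = 0.2)
  mask <- matrix(gc$x^2 + gc$y^2 < 36, gc$n, gc$n, byrow = TRUE)
  cl <- liftTo3d(mask, expandROI(mask), gc$pixelMap, gc$points)
  lab <- matrix(NA_character_, gc$n, gc$n)
  lab[mask] <- ifelse(matrix(gc$x, gc$n, gc$n, byrow = TRUE)[mask] < 0,
                      "granulation", "slough")
  frac <- tissuePercentages3d(lab, cl)
  expect_equal(sum(frac), 1, tolerance = 1e-9)
  expect_lt(abs(unname(frac["granulation"]) - 0.5), 0.02)

  # hemispherical wound: a class on the steep rim gains weight in 3D
  r <- 6
  gch <- gridCloud(function(x, y) ifelse(x^2 + y^2 < r^2,
                                         sqrt(pmax(0, r^2 - x^2 - y^2)), 0),
                   ext = 8, spacing = 0.2)
  maskh <- matrix(gch$x^2 + gch$y^2 < r^2, gch$n, gch$n, byrow = TRUE)
  clh <- liftTo3d(maskh, expandROI(maskh), gch$pixelMap, gch$points)
  rho <- sqrt(gch$x^2 + gch$y^2)
  labh <- matrix(NA_character_, gch$n, gch$n)
  rim <- matrix(rho > 0.8 * r, gch$n, gch$n, byrow = TRUE)
  labh[maskh] <- ifelse(rim[maskh], "necrosis", "granulation")
  frach <- tissuePercentages3d(labh, clh)
  pixelFrac <- sum(rim & maskh) / sum(maskh)
  expect_gt(unname(frach["necrosis"]), pixelFrac)
  expect_equal(sum(frach), 1, tolerance = 1e-9)
})
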