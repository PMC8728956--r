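# source family: launch distributions, patch containment, focusing

test_that("a pencil beam is a delta source", {
  s <- list(type = "pencil", pos = c(30, 30, 0), dir = c(0, 0, 1))
  m <- sample_launch(s, 50, seed = 11)
  expect_true(all(m[, "x"] == 30 & m[, "y"] == 30 & m[, "z"] == 0))
  expect_true(all(m[, "vz"] == 1))
  expect_true(all(m[, "w"] == 1))
})

test_that("isotropic directions have the moments of the uniform sphere", {
  s <- list(type = "isotropic", pos = c(0, 0, 0), dir = c(0, 0, 1))
  m <- sample_launch(s, 1e5, seed = 12)
  d <- m[, c("vx", "vy", "vz")]
  expect_equal(sqrt(rowSums(d^2)), rep(1, nrow(d)), tolerance = 1e-6)
  for (k in 1:3) {
    se <- sd(d[, k]) / sqrt(nrow(d))
    expect_lt(abs(mean(d[, k])), 4 * se)
  }
  se2 <- sd(d[, 3]^2) / sqrt(nrow(d))
  expect_lt(abs(mean(d[, 3]^2) - 1/3), 4 * se2)
})

test_that("fourier pattern weight has the analytic mean over the patch", {
  # kx = 1, ky = 0, phase 0: mean over u of (1 + cos(2 pi u))/2 = 1/2
  s <- list(type = "fourier", pos = c(0, 0, 0), dir = c(0, 0, 1),
            param1 = c(10, 0, 0, 1), param2 = c(0, 10, 0, 0))
  m <- sample_launch(s, 1e5, seed = 13)
  se <- sd(m[, "w"]) / sqrt(nrow(m))
  expect_lt(abs(mean(m[, "w"]) - 0.5), 4 * se)
  expect_true(all(m[, "w"] >= 0 & m[, "w"] <= 1))
  # phase packed in the fractional part: kx=1, phase=pi flips the pattern
  s$param1[4] <- 1.5
  m2 <- sample_launch(s, 1e5, seed = 13)
  se2 <- sd(m2[, "w"]) / sqrt(nrow(m2))
  expect_lt(abs(mean(m2[, "w"]) - 0.5), 4 * se2)
})

test_that("area sources sample inside their declared patch", {
  planar <- list(type = "planar", pos = c(10, 20, 5), dir = c(0, 0, 1),
                 param1 = c(8, 0, 0, 0), param2 = c(0, 4, 0, 0))
  m <- sample_launch(planar, 2000, seed = 14)
  expect_true(all(m[, "x"] >= 10 & m[, "x"] < 18))
  expect_true(all(m[, "y"] >= 20 & m[, "y"] < 24))
  expect_true(all(m[, "z"] == 5))
  expect_true(all(m[, "vz"] == 1))

  disk <- list(type = "disk", pos = c(30, 30, 0), dir = c(0, 0, 1),
               param1 = c(5, 0, 0, 0))
  md <- sample_launch(disk, 2000, seed = 15)
  r <- sqrt((md[, "x"] - 30)^2 + (md[, "y"] - 30)^2)
  expect_true(all(r <= 5))
  expect_true(all(md[, "z"] == 0))
  # uniform over the disk: E[r^2] = R^2/2
  expect_equal(mean(r^2), 12.5, tolerance = 0.05)

  line <- list(type = "line", pos = c(0, 0, 0), dir = c(0, 0, 1),
               param1 = c(6, 3, 0, 0))
  ml <- sample_launch(line, 500, seed = 16)
  tt <- ml[, "x"] / 6
  expect_true(all(tt >= 0 & tt < 1))
  expect_equal(ml[, "y"], 3 * tt, tolerance = 1e-12)
})

test_that("cone sampling stays within the half-angle and covers it", {
  s <- list(type = "cone", pos = c(0, 0, 0), dir = c(0, 0, 1),
            param1 = c(0.5, 0, 0, 0))
  m <- sample_launch(s, 5000, seed = 17)
  ct <- m[, "vz"]
  expect_true(all(ct >= cos(0.5) - 1e-12))
  # uniform solid angle: E[cos] = (1 + cos(thetamax))/2
  se <- sd(ct) / sqrt(length(ct))
  expect_lt(abs(mean(ct) - (1 + cos(0.5)) / 2), 4 * se)
  # zero half-angle reduces to a pencil
  s0 <- list(type = "cone", pos = c(0, 0, 0), dir = c(0, 0, 1),
             param1 = c(0, 0, 0, 0))
  m0 <- sample_launch(s0, 10, seed = 18)
  expect_equal(m0[, "vz"], rep(1, 10), tolerance = 1e-12)
})

test_that("gaussian radial profile has the declared waist", {
  s <- list(type = "gaussian", pos = c(0, 0, 0), dir = c(0, 0, 1),
            param1 = c(2, 0, 0, 0))
  m <- sample_launch(s, 2e4, seed = 19)
  r2 <- m[, "x"]^2 + m[, "y"]^2
  # intensity ~ exp(-r^2/w0^2): E[r^2] = w0^2
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 4), 4 * se)
})

test_that("pattern sources carry the pattern value as launch weight", {
  pat <- matrix(c(0, 1, 2, 3), 2, 2)
  s <- list(type = "pattern", pos = c(0, 0, 0), dir = c(0, 0, 1),
            param1 = c(2, 0, 0, 0), param2 = c(0, 2, 0, 0), pattern = pat)
  m <- sample_launch(s, 4000, seed = 20)
  ix <- pmin(floor(m[, "x"] / 1) + 1, 2)
  iy <- pmin(floor(m[, "y"] / 1) + 1, 2)
  expect_equal(m[, "w"], pat[cbind(ix, iy)], tolerance = 1e-12)
  # 3D pattern
  p3 <- array(runif(8), c(2, 2, 2))
  s3 <- list(type = "pattern3d", pos = c(0, 0, 0), dir = c(0, 0, 1),
             param1 = c(2, 2, 2, 0), pattern = p3)
  m3 <- sample_launch(s3, 1000, seed = 21)
  idx <- cbind(pmin(floor(m3[, "x"]) + 1, 2), pmin(floor(m3[, "y"]) + 1, 2),
               pmin(floor(m3[, "z"]) + 1, 2))
  expect_equal(m3[, "w"], p3[idx], tolerance = 1e-12)
})

test_that("launched energy equals the sum of initial weights", {
  s <- list(type = "pencil", pos = c(0, 0, 0), dir = c(0, 0, 1))
  m <- sample_launch(s, 1234, seed = 22)
  expect_identical(sum(m[, "w"]), 1234)
})

test_that("focusing bends rays through the focal point; infinite focus is collimated", {
  planar <- list(type = "planar", pos = c(0, 0, 0), dir = c(0, 0, 1),
                 param1 = c(10, 0, 0, 0), param2 = c(0, 10, 0, 0),
                 focus = 25)
  m <- sample_launch(planar, 500, seed = 23)
  tt <- (25 - m[, "z"]) / m[, "vz"]
  px <- m[, "x"] + tt * m[, "vx"]
  py <- m[, "y"] + tt * m[, "vy"]
  expect_lt(max(abs(px - 5)), 1e-9) # focal point above the patch center
  expect_lt(max(abs(py - 5)), 1e-9)

  # divergent: back-projected rays converge at the virtual point behind
  planar$focus <- -25
  md <- sample_launch(planar, 500, seed = 23)
  ttb <- (-25 - md[, "z"]) / md[, "vz"]
  expect_lt(max(abs(md[, "x"] + ttb * md[, "vx"] - 5)), 1e-9)
  expect_true(all(md[, "vz"] > 0)) # still travels forward

  planar$focus <- Inf
  mc <- sample_launch(planar, 100, seed = 23)
  expect_true(all(mc[, "vz"] == 1))

  # the R-side geometric construction agrees with the kernel's sampling
  dirs <- apply_focus(m[, c("x", "y", "z")],
                      modifyList(planar, list(focus = 25)))
  expect_equal(unname(dirs), unname(m[, c("vx", "vy", "vz")]),
               tolerance = 1e-12)
})

test_that("degenerate source configurations are rejected", {
  expect_error(sample_launch(list(type = "pattern", pos = c(0, 0, 0),
                                  dir = c(0, 0, 1),
                                  param1 = c(2, 0, 0, 0),
                                  param2 = c(0, 2, 0, 0)), 10),
               class = "source_config_error")
  expect_error(sample_launch(list(type = "planar", pos = c(0, 0, 0),
                                  dir = c(0, 0, 1),
                                  param1 = c(0, 0, 0, 0),
                                  param2 = c(0, 2, 0, 0)), 10),
               class = "source_config_error")
  expect_error(apply_focus(matrix(0, 1, 3),
                           list(type = "planar", pos = c(0, 0, 0),
                                dir = c(0, 0, 1), param1 = c(2, 0, 0, 0),
                                param2 = c(0, 2, 0, 0), focus = 0)),
               class = "source_config_error")
})
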