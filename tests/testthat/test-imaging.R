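line_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
block_angle <- function(b) (atan2(b[2], b[1]) * 180 / pi) %% 180

test_that("analytic projections conserve mass and place peaks correctly", {
  # a single centered blob projects to a radially symmetric image
  ph1 <- structure(list(centers = matrix(0, 1, 3), amplitudes = 1, widths = 3),
                   class = "cl_phantom")
  img <- project_phantom(ph1, rot_y(35), L = 64)
  expect_equal(which(img$pixels == max(img$pixels), arr.ind = TRUE)[1, ],
               c(row = 33, col = 33))
  expect_lt(max(abs(img$pixels - t(img$pixels))), 1e-12)

  # mass is independent of the viewing rotation
  ph <- gaussian_phantom(seed = 51)
  masses <- vapply(random_rotations(5, seed = 52),
                   function(R) sum(project_phantom(ph, R, L = 64)$pixels),
                   numeric(1))
  expect_lt(diff(range(masses)) / masses[1], 1e-6)

  # off-center blob lands at the projected center
  ph2 <- structure(list(centers = matrix(c(9, 0, 0), 1, 3), amplitudes = 1,
                        widths = 2), class = "cl_phantom")
  img2 <- project_phantom(ph2, diag(3), L = 64)
  peak <- which(img2$pixels == max(img2$pixels), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(33 + 9, 33))
})

test_that("SNR-calibrated noise has the requested variance and is seeded", {
  ph <- gaussian_phantom(seed = 53)
  img <- project_phantom(ph, diag(3), L = 96)
  expect_identical(add_noise_snr(img, Inf)$pixels, img$pixels)
  n1 <- add_noise_snr(img, 0.5, seed = 1)
  n2 <- add_noise_snr(img, 0.5, seed = 1)
  expect_identical(n1$pixels, n2$pixels)
  noise <- n1$pixels - img$pixels
  snr_emp <- mean(img$pixels^2) / stats::var(as.vector(noise))
  expect_lt(abs(snr_emp - 0.5) / 0.5, 0.05)
})

test_that("ray profiles obey symmetry, conjugacy and the shift theorem", {
  ph1 <- structure(list(centers = matrix(0, 1, 3), amplitudes = 1, widths = 3),
                   class = "cl_phantom")
  img <- project_phantom(ph1, diag(3), L = 64)
  # restrict to radii that carry signal (a sigma = 3 px blob has frequency
  # content only below ~5 frequency pixels)
  P <- fourier_line_profiles(img, n_theta = 36, r_band = c(1.5, 5))
  mags <- Mod(P)
  expect_lt(max(apply(mags, 2, function(col) diff(range(col)) / max(col))),
            0.02)   # radially symmetric image: all rays equal

  # Hermitian symmetry of the transform of a real image: F(-k) = Conj(F(k))
  # (this is what makes the ray at theta + 180 degrees the conjugate ray)
  ph <- gaussian_phantom(seed = 54)
  img2 <- project_phantom(ph, rot_x(20), L = 64)
  px <- img2$pixels * commonlines:::edge_window(64)
  FT <- commonlines:::fftshift2(stats::fft(commonlines:::ifftshift2(px)))
  c0 <- 33
  for (ab in list(c(5, 0), c(3, 4), c(0, 7), c(-6, 2))) {
    a <- ab[1]; b <- ab[2]
    expect_equal(FT[c0 + a, c0 + b], Conj(FT[c0 - a, c0 - b]),
                 tolerance = 1e-8)
  }

  # shifting the image changes phases only
  sh <- img2
  sh$pixels <- rbind(sh$pixels[-(1:2), ], sh$pixels[1:2, ])
  P3 <- fourier_line_profiles(sh, n_theta = 36, window = FALSE)
  P2nw <- fourier_line_profiles(img2, n_theta = 36, window = FALSE)
  expect_lt(max(abs(Mod(P3) - Mod(P2nw))) / max(Mod(P2nw)), 0.05)
})

test_that("common-line detection finds the ground-truth angles on clean images", {
  ph <- gaussian_phantom(seed = 5)
  rots <- random_rotations(6, seed = 21)
  imgs <- lapply(rots, function(R) project_phantom(ph, R))
  dm <- detected_matrix(imgs)

  errs <- vapply(seq_len(nrow(dm$detections)), function(r) {
    i <- dm$detections$i[r]; j <- dm$detections$j[r]
    max(line_dist(dm$detections$theta_i[r],
                  block_angle(pure_block(rots[[i]], rots[[j]]))),
        line_dist(dm$detections$theta_j[r],
                  block_angle(pure_block(rots[[j]], rots[[i]]))))
  }, numeric(1))
  expect_gte(mean(errs <= 2), 0.9)

  # all blocks unit norm, deterministic
  N <- commonlines:::block_norms(dm$A)
  off <- row(diag(6)) != col(diag(6))
  expect_equal(N[off], rep(1, sum(off)), tolerance = 1e-12)
  expect_identical(detected_matrix(imgs)$A, dm$A)

  # correlations are valid and self-detection is perfect
  expect_true(all(abs(dm$detections$correlation) <= 1 + 1e-12))
  self <- detect_common_line(imgs[[1]], imgs[[1]])
  expect_gt(self$correlation, 1 - 1e-9)
})

test_that("profiles at the ground-truth common line agree between images", {
  ph <- gaussian_phantom(seed = 55)
  rots <- random_rotations(3, seed = 56)
  imgs <- lapply(rots, function(R) project_phantom(ph, R))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    aij <- pure_block(rots[[i]], rots[[j]])
    aji <- pure_block(rots[[j]], rots[[i]])
    ray <- function(img, v) {
      th <- (atan2(v[2], v[1])) %% (2 * pi)
      flip <- th >= pi
      if (flip) th <- th - pi
      P <- fourier_line_profiles(img, n_theta = 1800)
      k <- round(th / pi * 1800) %% 1800 + 1
      p <- P[k, ]
      if (flip) Conj(p) else p
    }
    pi_ <- ray(imgs[[i]], aij)
    pj_ <- ray(imgs[[j]], -aji)    # a_ji represents the reversed direction
    expect_lt(sqrt(sum(Mod(pi_ - pj_)^2) / sum(Mod(pi_)^2)), 0.1)
  }
})

test_that("detection accuracy degrades monotonically with SNR", {
  ph <- gaussian_phantom(seed = 57)
  rots <- random_rotations(5, seed = 58)
  clean <- lapply(rots, function(R) project_phantom(ph, R, L = 64))
  meds <- c()
  for (snr in c(Inf, 1, 1 / 16)) {
    errs_all <- c()
    for (s in 1:3) {
      imgs <- lapply(seq_along(clean), function(k)
        add_noise_snr(clean[[k]], snr, seed = 100 * s + k))
      dm <- detected_matrix(imgs)
      errs <- vapply(seq_len(nrow(dm$detections)), function(r) {
        i <- dm$detections$i[r]; j <- dm$detections$j[r]
        max(line_dist(dm$detections$theta_i[r],
                      block_angle(pure_block(rots[[i]], rots[[j]]))),
            line_dist(dm$detections$theta_j[r],
                      block_angle(pure_block(rots[[j]], rots[[i]]))))
      }, numeric(1))
      errs_all <- c(errs_all, errs)
    }
    meds <- c(meds, stats::median(errs_all))
  }
  expect_true(all(diff(meds) >= 0))
  expect_gt(meds[3], meds[1])
})
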