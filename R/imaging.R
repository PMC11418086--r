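## Minimal download-free image pathway: an asymmetric Gaussian-blob phantom
## whose tomographic projections are available in closed form, white
## Gaussian noise calibrated to a target SNR (signal = mean squared clean
## pixel intensity), and common-line detection by maximising the correlation
## between central rays of the 2D Fourier transforms.

#' Random asymmetric Gaussian-blob phantom
#'
#' A sum of isotropic 3D Gaussians with generic random centers (which makes
#' any nontrivial point-group symmetry a probability-zero event, matching
#' the asymmetric-molecule assumption under which common lines are unique).
#' All geometry is in pixel units.
#'
#' @param n_blobs Number of blobs (>= 5 recommended for generic asymmetry).
#' @param radius Centers are drawn uniformly in a ball of this radius
#'   (pixels); keep below half the grid size used for projection.
#' @param width_range Range of isotropic Gaussian sigmas (pixels).
#' @param amp_range Range of blob amplitudes.
#' @param seed Optional integer seed.
#' @return A list of class `"cl_phantom"` with `centers` (n x 3),
#'   `amplitudes`, `widths`.
#' @export
gaussian_phantom <- function(n_blobs = 8L, radius = 24, width_range = c(1, 2),
                             amp_range = c(0.5, 1), seed = NULL) {
  stopifnot(n_blobs >= 1, radius > 0)
  if (!is.null(seed)) set.seed(seed)
  ## rejection-free ball sampling: direction * radius * U^{1/3}
  u <- matrix(stats::rnorm(3L * n_blobs), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  centers <- u * (radius * stats::runif(n_blobs)^(1 / 3))
  structure(list(centers = centers,
                 amplitudes = stats::runif(n_blobs, amp_range[1L], amp_range[2L]),
                 widths = stats::runif(n_blobs, width_range[1L], width_range[2L])),
            class = "cl_phantom")
}

## centered pixel coordinates for an L-point axis (0 at index floor(L/2)+1)
grid_coords <- function(L) (0:(L - 1L)) - floor(L / 2)

#' Analytic tomographic projection of a Gaussian phantom
#'
#' The line integral of an isotropic 3D Gaussian along the viewing axis is a
#' closed-form 2D Gaussian centered at the first two coordinates of the
#' rotated blob center, so projections are exact up to grid sampling.
#'
#' @param ph A [gaussian_phantom()].
#' @param R Viewing rotation (3x3).
#' @param L Grid side (pixels), >= 16. The default matches the scale at
#'   which 1-degree ray discrimination is comfortably resolved.
#' @param pixel_size Pixel size in Angstrom (metadata only; geometry is in
#'   pixels).
#' @return A list of class `"cl_image"` with `pixels` (L x L, row index =
#'   x), `pixel_size`, `rotation`.
#' @export
project_phantom <- function(ph, R, L = 128L, pixel_size = 3) {
  stopifnot(inherits(ph, "cl_phantom"), L >= 16L)
  xs <- grid_coords(L)
  img <- matrix(0, L, L)
  for (b in seq_len(nrow(ph$centers))) {
    p <- R %*% ph$centers[b, ]
    s <- ph$widths[b]
    gx <- exp(-(xs - p[1L])^2 / (2 * s^2))
    gy <- exp(-(xs - p[2L])^2 / (2 * s^2))
    img <- img + ph$amplitudes[b] * s * sqrt(2 * pi) * outer(gx, gy)
  }
  structure(list(pixels = img, pixel_size = pixel_size, rotation = R),
            class = "cl_image")
}

#' Add white Gaussian noise at a target SNR
#'
#' The signal is the average squared intensity over the pixels of the clean
#' image; the per-pixel noise variance is `mean(clean^2) / snr`.
#'
#' @param img A `cl_image`.
#' @param snr Target signal-to-noise ratio (> 0; `Inf` returns the input).
#' @param seed Optional integer seed.
#' @return A `cl_image` with noisy pixels.
#' @export
add_noise_snr <- function(img, snr, seed = NULL) {
  stopifnot(inherits(img, "cl_image"), snr > 0)
  if (!is.finite(snr)) return(img)
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(mean(img$pixels^2) / snr)
  img$pixels <- img$pixels +
    matrix(stats::rnorm(length(img$pixels), 0, sigma), nrow(img$pixels))
  img
}

circshift2 <- function(m, k1, k2) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- ((seq_len(n1) - 1L - k1) %% n1) + 1L
  i2 <- ((seq_len(n2) - 1L - k2) %% n2) + 1L
  m[i1, i2, drop = FALSE]
}

fftshift2 <- function(m) circshift2(m, floor(nrow(m) / 2), floor(ncol(m) / 2))
ifftshift2 <- function(m) circshift2(m, -floor(nrow(m) / 2), -floor(ncol(m) / 2))

## raised-cosine edge window on the spatial grid (1 inside, cosine taper to 0)
edge_window <- function(L, taper_start = 0.8) {
  xs <- grid_coords(L)
  rad <- sqrt(outer(xs^2, xs^2, `+`))
  rmax <- floor(L / 2) - 1
  r0 <- taper_start * rmax
  w <- matrix(1, L, L)
  mid <- rad > r0 & rad < rmax
  w[mid] <- 0.5 * (1 + cos(pi * (rad[mid] - r0) / (rmax - r0)))
  w[rad >= rmax] <- 0
  w
}

#' Central-ray profiles of an image's 2D Fourier transform
#'
#' Windows the image with a raised-cosine edge, takes the centered 2D FFT,
#' and bilinearly resamples the complex transform along `n_theta` central
#' rays at uniform angles in `[0, 180)` degrees, at integer radii within
#' `r_band` (frequency pixels; DC excluded). For a real image the ray at
#' `theta + 180` degrees is the complex conjugate of the ray at `theta`.
#'
#' @param img A `cl_image`.
#' @param n_theta Number of ray angles (>= 36).
#' @param r_band Radial band `c(rmin, rmax)` in frequency pixels,
#'   `0 < rmin < rmax <= L/2 - 1`. Default `c(3, L/2 - 2)`.
#' @param window Apply the edge window before the FFT.
#' @return Complex matrix `n_theta x n_radii`; attribute `"theta_deg"` holds
#'   the ray angles in degrees.
#' @export
fourier_line_profiles <- function(img, n_theta = 180L, r_band = NULL,
                                  window = TRUE) {
  stopifnot(inherits(img, "cl_image"), n_theta >= 36L)
  L <- nrow(img$pixels)
  if (is.null(r_band)) r_band <- c(3, L / 2 - 2)
  stopifnot(r_band[1L] > 0, r_band[1L] < r_band[2L], r_band[2L] <= L / 2)
  px <- img$pixels
  if (window) px <- px * edge_window(L)
  FT <- fftshift2(stats::fft(ifftshift2(px)))
  c0 <- floor(L / 2) + 1L   # index of DC after fftshift

  th <- (seq_len(n_theta) - 1L) * pi / n_theta
  rr <- seq(ceiling(r_band[1L]), floor(r_band[2L]))
  pts_x <- outer(cos(th), rr)          # n_theta x n_r, frequency pixels
  pts_y <- outer(sin(th), rr)
  ix <- pts_x + c0; iy <- pts_y + c0
  x0 <- floor(ix); y0 <- floor(iy)
  fx <- ix - x0; fy <- iy - y0
  g <- function(xi, yi) FT[cbind(as.vector(xi), as.vector(yi))]
  vals <- (1 - fx) * (1 - fy) * matrix(g(x0, y0), n_theta) +
    fx * (1 - fy) * matrix(g(x0 + 1L, y0), n_theta) +
    (1 - fx) * fy * matrix(g(x0, y0 + 1L), n_theta) +
    fx * fy * matrix(g(x0 + 1L, y0 + 1L), n_theta)
  structure(vals, theta_deg = (seq_len(n_theta) - 1L) * 180 / n_theta)
}

#' Detect the common line between two images
#'
#' Maximises the normalised real correlation of complex central-ray profiles
#' over all angle pairs and both relative ray orientations (a line is only
#' defined up to direction; the reversed ray of a real image is the complex
#' conjugate). Returns the best angles and unit representatives; the sign of
#' `rep_j` encodes the relative orientation so the pair is consistent with
#' one 3D line direction.
#'
#' @param img_i,img_j `cl_image` objects of the same size.
#' @param n_theta,r_band As in [fourier_line_profiles()].
#' @param profiles_i,profiles_j Optional precomputed profiles (used by
#'   [detected_matrix()] to avoid recomputing FFTs).
#' @return A list of class `"cl_detection"`: `theta_i`, `theta_j` (degrees in
#'   `[0, 180)`), `correlation`, `rep_i`, `rep_j` (unit 2-vectors).
#' @export
detect_common_line <- function(img_i, img_j, n_theta = 180L, r_band = NULL,
                               profiles_i = NULL, profiles_j = NULL) {
  Pi <- if (is.null(profiles_i))
    fourier_line_profiles(img_i, n_theta, r_band) else profiles_i
  Pj <- if (is.null(profiles_j))
    fourier_line_profiles(img_j, n_theta, r_band) else profiles_j
  ni <- sqrt(rowSums(Mod(Pi)^2)); nj <- sqrt(rowSums(Mod(Pj)^2))
  if (any(ni == 0) || any(nj == 0))
    stop("undefined detection: an image has an all-zero ray profile")
  Pin <- Pi / ni; Pjn <- Pj / nj
  Cdir <- Re(Pin %*% Conj(t(Pjn)))   # same orientation
  Cflip <- Re(Pin %*% t(Pjn))        # j-ray reversed (conjugate)
  mdir <- which.max(Cdir); mflip <- which.max(Cflip)
  flip <- Cflip[mflip] > Cdir[mdir]
  m <- if (flip) mflip else mdir
  Cbest <- if (flip) Cflip[mflip] else Cdir[mdir]
  nt <- nrow(Pin)
  ti <- (m - 1L) %% nt + 1L
  tj <- (m - 1L) %/% nt + 1L
  th <- attr(Pi, "theta_deg")
  rep_i <- c(cos(th[ti] * pi / 180), sin(th[ti] * pi / 180))
  rep_j <- c(cos(th[tj] * pi / 180), sin(th[tj] * pi / 180))
  ## a directly matched ray pair shares one 3D direction d, but the pure
  ## block convention stores a_ij ~ +d and a_ji ~ -d (reversed cross
  ## product), so the j-side representative is negated for direct matches
  if (!flip) rep_j <- -rep_j
  structure(list(theta_i = th[ti], theta_j = th[tj],
                 correlation = Cbest, rep_i = rep_i, rep_j = rep_j),
            class = "cl_detection")
}

#' Common-lines matrix from detected lines
#'
#' Runs pairwise common-line detection over an image list and assembles the
#' unit representatives into a 2n x n common-lines matrix (block `(i, j)` is
#' the representative in image `i` from the `(i, j)` detection).
#'
#' @param images List of >= 3 `cl_image` objects of equal size.
#' @param n_theta,r_band As in [fourier_line_profiles()].
#' @return A list with `A` (2n x n matrix of unit blocks) and `detections`
#'   (data frame: i, j, theta_i, theta_j, correlation).
#' @export
detected_matrix <- function(images, n_theta = 180L, r_band = NULL) {
  n <- length(images)
  if (n < 3L) stop("need at least 3 images")
  profs <- lapply(images, fourier_line_profiles, n_theta = n_theta,
                  r_band = r_band)
  A <- matrix(0, 2L * n, n)
  det_rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- detect_common_line(images[[i]], images[[j]],
                            profiles_i = profs[[i]], profiles_j = profs[[j]])
    A[c(2L * i - 1L, 2L * i), j] <- d$rep_i
    A[c(2L * j - 1L, 2L * j), i] <- d$rep_j
    det_rows[[length(det_rows) + 1L]] <-
      data.frame(i = i, j = j, theta_i = d$theta_i, theta_j = d$theta_j,
                 correlation = d$correlation)
  }
  list(A = A, detections = do.call(rbind, det_rows))
}
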