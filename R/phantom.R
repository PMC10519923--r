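## 3-D ellipsoid table for the modified (high-contrast) Shepp-Logan phantom:
## columns A, a, b, c, x0, y0, z0, phi (deg, rotation about z).
.slp3d <- matrix(c(
   1.0, 0.6900, 0.920, 0.810,  0.00,  0.0000,  0.00,   0,
  -0.8, 0.6624, 0.874, 0.780,  0.00, -0.0184,  0.00,   0,
  -0.2, 0.1100, 0.310, 0.220,  0.22,  0.0000,  0.00, -18,
  -0.2, 0.1600, 0.410, 0.280, -0.22,  0.0000,  0.00,  18,
   0.1, 0.2100, 0.250, 0.410,  0.00,  0.3500, -0.15,   0,
   0.1, 0.0460, 0.046, 0.050,  0.00,  0.1000,  0.25,   0,
   0.1, 0.0460, 0.046, 0.050,  0.00, -0.1000,  0.25,   0,
   0.1, 0.0460, 0.023, 0.050, -0.08, -0.6050,  0.00,   0,
   0.1, 0.0230, 0.023, 0.020,  0.00, -0.6060,  0.00,   0,
   0.1, 0.0230, 0.046, 0.020,  0.06, -0.6050,  0.00,   0),
  ncol = 8, byrow = TRUE)

#' Shepp-Logan head phantom (3-D ellipsoid model)
#'
#' Evaluates the modified (high-contrast, nonnegative) Shepp-Logan ellipsoid
#' phantom on an `n x n` grid at the requested axial positions, producing one
#' slice per entry of `z_positions` (coordinates in `[-1, 1]`).
#'
#' @param n slice matrix size.
#' @param z_positions axial coordinates of the slices; default a single
#'   central slice at `z = 0`.
#' @return array `n x n x length(z_positions)` of activity values in `[0, 1]`.
#' @export
shepp_logan_phantom <- function(n, z_positions = 0) {
  ax <- seq(-1, 1, length.out = n)
  x <- matrix(ax, n, n, byrow = TRUE)   # x along columns
  y <- matrix(-ax, n, n)                # y decreases with row index
  out <- array(0, c(n, n, length(z_positions)))
  for (k in seq_along(z_positions)) {
    z <- z_positions[k]
    img <- matrix(0, n, n)
    for (e in seq_len(nrow(.slp3d))) {
      p <- .slp3d[e, ]
      phi <- p[8] * pi / 180
      xc <- x - p[5]; yc <- y - p[6]
      xr <- xc * cos(phi) + yc * sin(phi)
      yr <- -xc * sin(phi) + yc * cos(phi)
      inside <- (xr / p[2])^2 + (yr / p[3])^2 + ((z - p[7]) / p[4])^2 <= 1
      img[inside] <- img[inside] + p[1]
    }
    out[, , k] <- pmax(img, 0)
  }
  out
}

#' Kinetic parameter set for one tissue
#'
#' @param K1 plasma-to-tissue influx rate, mL/min/mL.
#' @param k2 tissue-to-plasma efflux rate, 1/min.
#' @param k3 trapping rate, 1/min (irreversible model; k4 = 0).
#' @param Fv fractional blood volume in `[0, 1]`.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3, Fv = 0) {
  if (any(c(K1, k2, k3) < 0)) stop_input("rate constants must be nonnegative")
  if (Fv < 0 || Fv > 1) stop_input("Fv must lie in [0, 1]")
  structure(list(K1 = K1, k2 = k2, k3 = k3, Fv = Fv), class = "kinetic_params")
}

#' FDG kinetic parameters of the simulated brain tissues
#'
#' Two-tissue-compartment rate constants used for gray matter, white matter
#' and tumor in the dynamic brain simulation (`Fv = 0` throughout):
#' `K1 = 0.1104, 0.0622, 0.0640` mL/min/mL; `k2 = 0.1910, 0.1248, 0.0890` and
#' `k3 = 0.1024, 0.0070, 0.0738` 1/min, respectively.
#'
#' @return named list of [kinetic_params()]: `gray`, `white`, `tumor`.
#' @export
brain_tissue_params <- function() {
  list(gray  = kinetic_params(0.1104, 0.1910, 0.1024),
       white = kinetic_params(0.0622, 0.1248, 0.0070),
       tumor = kinetic_params(0.0640, 0.0890, 0.0738))
}

#' Procedural brain-like phantom
#'
#' Deterministically generates a simple brain-like label volume: a smooth,
#' seed-perturbed gray-matter shell around a white-matter core, paired
#' ventricles near the center, and one `4 x 4 x 4`-voxel tumor insert in the
#' white matter. This is a synthetic stand-in with the geometric features a
#' denoising study needs (tissue boundaries, a small hot lesion), not an
#' anatomical atlas. Labels: 0 background, 1 gray matter, 2 white matter,
#' 3 ventricle, 4 tumor.
#'
#' @param size slice matrix size (>= 64).
#' @param seed integer seed controlling the smooth shell perturbation.
#' @param n_slices number of axial slices (>= 4 so the tumor cube fits).
#' @return a `phantom_spec`: list with `labels` (`size x size x n_slices`
#'   integer array), `tissue_params` (label -> [kinetic_params()]),
#'   `voxel_size_mm`, `centers` (per-tissue 4x4x4 VOI centers,
#'   `(row, col, slice)`).
#' @export
make_brain_like_phantom <- function(size, seed = 1, n_slices = 5) {
  if (size < 64) stop_input("phantom size must be >= 64")
  if (n_slices < 4) stop_input("need >= 4 slices for the 4 x 4 x 4 tumor")
  coefs <- with_seed(seed, list(a = stats::runif(3, -1, 1),
                                b = stats::runif(3, -1, 1)))
  ax <- seq(-1, 1, length.out = size)
  x <- matrix(ax, size, size, byrow = TRUE)
  y <- matrix(-ax, size, size)
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  pert <- 0
  for (h in 1:3) pert <- pert + coefs$a[h] * cos(h * th) + coefs$b[h] * sin(h * th)
  shell <- 0.85 * (1 + 0.04 * pert)            # seed-dependent outer radius
  labels <- array(0L, c(size, size, n_slices))
  mid <- (n_slices + 1) / 2
  for (k in seq_len(n_slices)) {
    ## gentle axial taper (near-cylindrical head over the few central slices)
    sk <- sqrt(pmax(1 - ((k - mid) / (n_slices / 2 + 2))^2, 0.2))
    lab <- matrix(0L, size, size)
    lab[r <= shell * sk] <- 1L                                   # gray shell
    lab[r <= 0.70 * shell * sk] <- 2L                            # white core
    vent <- (((x - 0.12) / 0.10)^2 + (y / 0.28)^2 <= 1) |
            (((x + 0.12) / 0.10)^2 + (y / 0.28)^2 <= 1)
    lab[vent & lab == 2L] <- 3L
    labels[, , k] <- lab
  }
  ## 4 x 4 x 4 tumor cube inside the white matter, off-center
  ti <- round(size * 0.38); tj <- round(size * 0.62)
  tk <- max(1L, as.integer(floor(mid)) - 1L)
  labels[ti:(ti + 3), tj:(tj + 3), tk:(tk + 3)] <- 4L
  bp <- brain_tissue_params()
  params <- list(`1` = bp$gray, `2` = bp$white,
                 `3` = kinetic_params(0, 0.1, 0),   # CSF: no uptake
                 `4` = bp$tumor)
  ks <- as.integer(floor(mid))
  centers <- list(
    gray  = c(round(size / 2), round(size * 0.17), ks),
    white = c(round(size * 0.62), round(size * 0.38), ks),
    tumor = c(ti + 1L, tj + 1L, tk + 1L))
  structure(list(labels = labels, tissue_params = params, voxel_size_mm = 1.5,
                 centers = centers),
            class = "phantom_spec")
}
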