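#' Material coefficient table for synthetic phantoms
#'
#' Per-material refractive index decrement `delta` (dimensionless), linear
#' attenuation `mu` (1/length unit) and linear diffusion (dark-field)
#' coefficient `epsilon` (1/length unit), together with the coarse tissue
#' class stored in the phantom label map. Values are order-of-magnitude
#' placeholders for a small-animal scan at ~23 keV in a water bath: water
#' delta is the center of the usual soft-tissue display window, bone is
#' roughly three times denser in delta and over an order of magnitude more
#' attenuating, and bone's porous microstructure gives it by far the
#' largest small-angle-scattering coefficient. One length unit = one
#' detector pixel.
#'
#' @return A data.frame with columns `material`, `class` (one of
#'   `"background"`, `"water"`, `"soft"`, `"bone"`), `label` (integer id
#'   stored in the phantom label map), `delta`, `mu`, `epsilon`.
#' @export
pcct_materials <- function() {
  data.frame(
    material = c("background", "water", "soft", "soft2", "bone"),
    class    = c("background", "water", "soft", "soft", "bone"),
    label    = c(0L, 1L, 2L, 2L, 3L),
    delta    = c(0, 4.567e-7, 4.800e-7, 4.300e-7, 1.350e-6),
    mu       = c(0, 0.012, 0.020, 0.016, 0.300),
    epsilon  = c(0, 0.004, 0.006, 0.006, 0.080),
    stringsAsFactors = FALSE
  )
}

#' Describe one ellipse of a phantom specification
#'
#' @param center numeric length-2, ellipse center in pixels relative to the
#'   image center (x, y).
#' @param axes numeric length-2 semi-axes in pixels (a circle if one value).
#' @param material material name, a row of the materials table.
#' @param rotation rotation angle in radians (counter-clockwise).
#' @return A list understood by [make_phantom()].
#' @export
ellipse_spec <- function(center, axes, material, rotation = 0) {
  axes <- rep(as.numeric(axes), length.out = 2)
  list(center = as.numeric(center), axes = axes,
       material = as.character(material), rotation = as.numeric(rotation))
}

#' Default mouse-like phantom specification
#'
#' A water-immersed soft-tissue body with two lower-density inclusions and
#' two bone inserts. The bone radii are chosen so that, at the default
#' acquisition settings, transmission through bone falls below 2% and the
#' peak differential-phase fringe shift at the bone rims exceeds pi -- the
#' regime in which phase wrapping and photon starvation produce streak
#' artifacts.
#'
#' @param width image width in pixels (the default study uses 128).
#' @return List of ellipse descriptors for [make_phantom()].
#' @export
default_phantom_spec <- function(width = 128) {
  f <- width / 128
  list(
    ellipse_spec(c(0, -2) * f,   c(41, 35) * f, "soft"),
    ellipse_spec(c(-18, 12) * f, c(8, 6) * f,   "soft2"),
    ellipse_spec(c(-8, 23) * f,  c(6, 4) * f,   "soft2", rotation = 0.4),
    ellipse_spec(c(-16, -14) * f, 7 * f,        "bone"),
    ellipse_spec(c(15, -12) * f,  6 * f,        "bone")
  )
}

#' Index ranges of the homogeneous soft-tissue region of interest
#'
#' A square block (16x16 at the default 128 px study size, scaled with
#' the phantom) inside the default phantom's soft-tissue body, away from
#' both bone inserts and both inclusions, used for noise (standard
#' deviation) measurements.
#'
#' @param width phantom width in pixels.
#' @return List with integer vectors `i` and `j` (matrix indices).
#' @export
default_soft_roi <- function(width = 128) {
  f <- width / 128
  ci <- round(10 * f + width / 2 + 0.5)
  cj <- round(16 * f + width / 2 + 0.5)
  h <- max(4L, as.integer(round(8 * f)))
  list(i = (ci - h):(ci + h - 1), j = (cj - h):(cj + h - 1))
}

#' Build a 2D phantom from ellipse descriptors
#'
#' Generates paired maps of refractive decrement delta, attenuation mu,
#' dark-field coefficient epsilon and a material label map. Later ellipses
#' overwrite earlier ones. The `background` material fills the image first;
#' with `background = "water"` the phantom emulates a water bath extending
#' over the whole field of view (as used experimentally to avoid phase
#' wrapping at container edges), and the bath's delta is recorded as
#' `delta_water` so the simulator can reference phase to water.
#'
#' @param width image width in pixels (square image), >= 8.
#' @param spec list of ellipse descriptors from [ellipse_spec()]; an empty
#'   list gives a pure-background phantom.
#' @param background material name filling the image before ellipses are
#'   painted.
#' @param materials material table, see [pcct_materials()].
#' @param pixel_size voxel edge length (length units).
#' @return An object of class `pcct_phantom`: list with `delta_map`,
#'   `mu_map`, `epsilon_map`, `label_map`, `pixel_size`, `delta_water`,
#'   `materials`.
#' @examples
#' ph <- make_phantom(32, default_phantom_spec(32), background = "water")
#' range(ph$mu_map)
#' @export
make_phantom <- function(width, spec = list(), background = "background",
                         materials = pcct_materials(), pixel_size = 1) {
  width <- as.integer(width)
  if (width < 8) stop("phantom width must be at least 8 pixels")
  mat_row <- function(name) {
    k <- match(name, materials$material)
    if (is.na(k)) stop("unknown material: ", name)
    materials[k, ]
  }
  bg <- mat_row(background)
  delta <- matrix(bg$delta, width, width)
  mu <- matrix(bg$mu, width, width)
  eps <- matrix(bg$epsilon, width, width)
  lab <- matrix(bg$label, width, width)
  # pixel-center coordinates, origin at the image center
  xc <- seq_len(width) - 0.5 - width / 2
  X <- matrix(xc, width, width)
  Y <- matrix(xc, width, width, byrow = TRUE)
  for (e in spec) {
    if (max(abs(e$center)) + max(e$axes) > width / 2)
      stop("ellipse extends outside the image (center ",
           paste(signif(e$center, 3), collapse = ", "),
           ", axes ", paste(signif(e$axes, 3), collapse = ", "), ")")
    m <- mat_row(e$material)
    dx <- X - e$center[1]; dy <- Y - e$center[2]
    u <- (dx * cos(e$rotation) + dy * sin(e$rotation)) / e$axes[1]
    v <- (-dx * sin(e$rotation) + dy * cos(e$rotation)) / e$axes[2]
    inside <- (u * u + v * v) <= 1
    delta[inside] <- m$delta
    mu[inside] <- m$mu
    eps[inside] <- m$epsilon
    lab[inside] <- m$label
  }
  structure(list(
    delta_map = delta, mu_map = mu, epsilon_map = eps, label_map = lab,
    pixel_size = pixel_size,
    delta_water = if (identical(bg$class, "water")) bg$delta else 0,
    materials = materials
  ), class = "pcct_phantom")
}

#' The default study phantom
#'
#' [make_phantom()] with [default_phantom_spec()] on a water-bath
#' background.
#'
#' @param width image width in pixels.
#' @inheritParams make_phantom
#' @return A `pcct_phantom`.
#' @export
default_phantom <- function(width = 128, materials = pcct_materials(),
                            pixel_size = 1) {
  make_phantom(width, default_phantom_spec(width), background = "water",
               materials = materials, pixel_size = pixel_size)
}

#' @export
print.pcct_phantom <- function(x, ...) {
  w <- dim(x$delta_map)
  cat("pcct phantom:", w[1], "x", w[2], "pixels, pixel size",
      x$pixel_size, "\n")
  tab <- table(factor(x$label_map, levels = sort(unique(x$materials$label)),
                      labels = unique(x$materials$class[order(x$materials$label)])))
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  delta in [%.3g, %.3g], mu in [%.3g, %.3g], delta_water = %.3g\n",
              min(x$delta_map), max(x$delta_map), min(x$mu_map),
              max(x$mu_map), x$delta_water))
  invisible(x)
}

#' Ground-truth phase-channel image of a phantom
#'
#' The quantity the SIR phase reconstruction estimates: the water-referenced
#' refractive decrement scaled by the interferometer fringe constant,
#' `rho = fringe_scale * (delta - delta_water)`.
#'
#' @param phantom a `pcct_phantom`.
#' @param config an [acquisition_config()] providing `fringe_scale`.
#' @return A `pcct_volume` with quantity `"rho"`.
#' @export
phantom_rho <- function(phantom, config) {
  pcct_volume(config$fringe_scale * (phantom$delta_map - phantom$delta_water),
              pixel_size = phantom$pixel_size, quantity = "rho")
}
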