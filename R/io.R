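# Array artifacts are stored as 32-bit multipage TIFF plus a JSON metadata
# sidecar (<name>.json). The TIFF samples are fixed-point: values are
# affinely mapped onto [0, 1] with the offset/scale recorded in the
# sidecar; the observed round-trip quantization is below 1e-8 of the
# value range, comparable to 32-bit float precision. Non-finite
# entries (infinite variances of invalid pixels) are recorded as index
# lists in the sidecar and restored on read.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

.encode_pages <- function(x) {
  fin <- is.finite(x)
  vmin <- if (any(fin)) min(x[fin]) else 0
  vmax <- if (any(fin)) max(x[fin]) else 0
  y <- x
  y[!fin] <- vmin
  if (vmax > vmin) y <- (y - vmin) / (vmax - vmin) else y[] <- 0
  list(data = y, vmin = vmin, vmax = vmax,
       idx_posinf = which(x == Inf), idx_neginf = which(x == -Inf),
       idx_nan = which(is.na(x)))
}

.decode_pages <- function(y, meta) {
  x <- y * (meta$vmax - meta$vmin) + meta$vmin
  x[unlist(meta$idx_posinf)] <- Inf
  x[unlist(meta$idx_neginf)] <- -Inf
  x[unlist(meta$idx_nan)] <- NaN
  x
}

.write_tiff_array <- function(x, path, meta = list()) {
  enc <- .encode_pages(x)
  d <- dim(enc$data)
  pages <- if (length(d) == 2) list(enc$data)
           else lapply(seq_len(d[2]), function(j) enc$data[, j, ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta$dim <- d
  meta$vmin <- enc$vmin; meta$vmax <- enc$vmax
  meta$idx_posinf <- enc$idx_posinf
  meta$idx_neginf <- enc$idx_neginf
  meta$idx_nan <- enc$idx_nan
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.read_tiff_array <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(side))
    stop("metadata sidecar missing for ", path, " (expected ", side, ")")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  if (length(d) == 2) {
    y <- pages[[1]]
  } else {
    y <- array(0, dim = d)
    for (j in seq_len(d[2])) y[, j, ] <- pages[[j]]
  }
  if (!all(dim(y) == d))
    stop("array shape in ", path, " does not match its sidecar metadata")
  list(values = .decode_pages(y, meta), meta = meta)
}

.geometry_meta <- function(geometry) {
  list(n_angles = geometry$n_angles, angles = geometry$angles,
       n_det = geometry$n_det, det_spacing = geometry$det_spacing,
       image_shape = geometry$image_shape, pixel_size = geometry$pixel_size)
}

.geometry_from_meta <- function(gm) {
  projection_geometry(image_shape = as.integer(unlist(gm$image_shape)),
                      angles = as.numeric(unlist(gm$angles)),
                      n_det = as.integer(gm$n_det),
                      det_spacing = gm$det_spacing,
                      pixel_size = gm$pixel_size)
}

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; stamped into every artifact
#' sidecar so outputs can be traced to the configuration that produced
#' them.
#'
#' @param config any JSON-serializable list.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, null = "null")
  unname(tools::md5sum(f))
}

#' Write / read a reconstructed volume
#'
#' 32-bit TIFF with a JSON sidecar carrying dimensions, pixel size,
#' quantity tag and optional configuration hash. Reading without the
#' sidecar is an error (never silent defaults).
#'
#' @param volume a `pcct_volume`.
#' @param path output `.tif` path.
#' @param config_hash optional provenance hash stored in the sidecar.
#' @return `path`, invisibly (write); a `pcct_volume` (read).
#' @export
write_volume <- function(volume, path, config_hash = NULL) {
  stopifnot(inherits(volume, "pcct_volume"))
  .write_tiff_array(volume$values, path,
                    list(type = "volume", quantity = volume$quantity,
                         pixel_size = volume$pixel_size,
                         config_hash = config_hash))
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  r <- .read_tiff_array(path)
  if (!identical(r$meta$type, "volume"))
    stop(path, " is not a volume artifact (type = ", r$meta$type, ")")
  pcct_volume(r$values, pixel_size = r$meta$pixel_size,
              quantity = r$meta$quantity)
}

#' Write / read a sinogram
#'
#' @param sinogram `n_angles x n_det` matrix.
#' @param path output `.tif` path.
#' @param geometry a [projection_geometry()], stored in the sidecar.
#' @param kind sinogram kind tag (e.g. `"dphase"`, `"transmission-log"`,
#'   `"weight"`, `"mask"`).
#' @param config_hash optional provenance hash.
#' @return `path` invisibly (write); list with `values`, `geometry`,
#'   `kind` (read).
#' @export
write_sinogram <- function(sinogram, path, geometry, kind = "dphase",
                           config_hash = NULL) {
  sinogram <- .check_sino(sinogram, geometry)
  .write_tiff_array(sinogram, path,
                    list(type = "sinogram", kind = kind,
                         geometry = .geometry_meta(geometry),
                         config_hash = config_hash))
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  r <- .read_tiff_array(path)
  if (!identical(r$meta$type, "sinogram"))
    stop(path, " is not a sinogram artifact (type = ", r$meta$type, ")")
  list(values = r$values, geometry = .geometry_from_meta(r$meta$geometry),
       kind = r$meta$kind)
}

#' Write / read a phase-stepping scan
#'
#' The intensity array (angle x step x detector) is stored as one TIFF
#' page per phase step; step positions, grating period, photon metadata
#' and the geometry go to the sidecar.
#'
#' @param scan a `pcct_scan`.
#' @param path output `.tif` path.
#' @param config_hash optional provenance hash.
#' @return `path` invisibly (write); a `pcct_scan` (read; the simulator's
#'   ground-truth attachment is not persisted).
#' @export
write_scan <- function(scan, path, config_hash = NULL) {
  stopifnot(inherits(scan, "pcct_scan"))
  .write_tiff_array(scan$intensities, path,
                    list(type = "scan",
                         step_positions = scan$step_positions,
                         grating_period = scan$grating_period,
                         photon_count = scan$photon_count,
                         visibility = scan$visibility,
                         geometry = .geometry_meta(scan$geometry),
                         config_hash = config_hash))
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  r <- .read_tiff_array(path)
  if (!identical(r$meta$type, "scan"))
    stop(path, " is not a scan artifact (type = ", r$meta$type, ")")
  structure(list(intensities = r$values,
                 step_positions = as.numeric(unlist(r$meta$step_positions)),
                 grating_period = r$meta$grating_period,
                 photon_count = r$meta$photon_count,
                 visibility = r$meta$visibility,
                 geometry = .geometry_from_meta(r$meta$geometry),
                 truth = NULL), class = "pcct_scan")
}

#' Write / read an extracted signal triplet
#'
#' Seven TIFF pages: transmission, differential phase, dark field, their
#' three variance maps, and the validity mask.
#'
#' @param signals a `pcct_signals`.
#' @param path output `.tif` path.
#' @param config_hash optional provenance hash.
#' @return `path` invisibly (write); a `pcct_signals` (read).
#' @export
write_signals <- function(signals, path, config_hash = NULL) {
  stopifnot(inherits(signals, "pcct_signals"))
  ch <- c("transmission", "dphase", "darkfield", "var_transmission",
          "var_dphase", "var_darkfield")
  arr <- array(0, dim = c(nrow(signals$dphase), length(ch) + 1,
                          ncol(signals$dphase)))
  for (k in seq_along(ch)) arr[, k, ] <- signals[[ch[k]]]
  arr[, length(ch) + 1, ] <- signals$valid + 0
  .write_tiff_array(arr, path,
                    list(type = "signals", channels = c(ch, "valid"),
                         geometry = .geometry_meta(signals$geometry),
                         config_hash = config_hash))
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  r <- .read_tiff_array(path)
  if (!identical(r$meta$type, "signals"))
    stop(path, " is not a signals artifact (type = ", r$meta$type, ")")
  ch <- unlist(r$meta$channels)
  out <- list()
  for (k in seq_along(ch)) out[[ch[k]]] <- r$values[, k, ]
  out$valid <- out$valid > 0.5
  out$geometry <- .geometry_from_meta(r$meta$geometry)
  structure(out, class = "pcct_signals")
}
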