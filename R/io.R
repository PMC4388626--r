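#' Persistence of complex images, masks and fixtures
#'
#' Complex arrays are stored as full-precision JSON (dimensions plus real
#' and imaginary vectors); masks as 0/255 grayscale PNG with a JSON
#' sidecar recording the generation parameters; fixtures as a directory
#' with a manifest. Round-trips are exact for the JSON containers and
#' exact for the binary mask.
#'
#' @name persistence
NULL

#' Write / read a complex image
#'
#' @param x complex matrix.
#' @param path output path (`.json`).
#' @return `write_complex_image` returns `path` invisibly;
#'   `read_complex_image` returns the complex matrix.
#' @export
write_complex_image <- function(x, path) {
  stopifnot(is.matrix(x))
  obj <- list(dims = dim(x), real = as.vector(Re(x)), imag = as.vector(Im(x)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_complex_image
#' @param path input path.
#' @export
read_complex_image <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  matrix(complex(real = obj$real, imaginary = obj$imag),
         obj$dims[1], obj$dims[2])
}

#' Write / read a sampling mask as PNG plus JSON sidecar
#'
#' @param mask a [generate_mask()] result.
#' @param path output PNG path; the sidecar is written at `<path>.json`.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   `sampling_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sampling_mask"))
  png::writePNG(mask$grid * 1, path)
  meta <- mask[setdiff(names(mask), "grid")]
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(grid = img > 0.5, M = as.integer(meta$M),
         sampling_fraction = meta$sampling_fraction,
         shape = as.integer(meta$shape), pattern = meta$pattern,
         center_fraction = meta$center_fraction,
         density_exponent = meta$density_exponent, seed = meta$seed),
    class = "sampling_mask"
  )
}

#' Persist / load a simulation fixture
#'
#' Writes `image.json`, `mask.png` (+ sidecar), `samples.json` and a
#' `manifest.json` under `dir`.
#'
#' @param fixture a [make_fixture()] result.
#' @param dir output directory (created if absent).
#' @return `write_fixture` returns `dir` invisibly; `read_fixture`
#'   returns a `cs_fixture`.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "cs_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_complex_image(fixture$image, file.path(dir, "image.json"))
  write_mask(fixture$mask, file.path(dir, "mask.png"))
  y <- fixture$kdata$samples
  jsonlite::write_json(
    list(real = Re(y), imag = Im(y),
         noise_sigma = fixture$kdata$noise_sigma),
    file.path(dir, "samples.json"), digits = NA, auto_unbox = FALSE)
  jsonlite::write_json(fixture$spec, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  image <- read_complex_image(file.path(dir, "image.json"))
  mask <- read_mask(file.path(dir, "mask.png"))
  sm <- jsonlite::read_json(file.path(dir, "samples.json"),
                            simplifyVector = TRUE)
  spec <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  kdata <- structure(
    list(samples = complex(real = sm$real, imaginary = sm$imag),
         mask = mask, noise_sigma = sm$noise_sigma[1]),
    class = "kspace_data"
  )
  structure(list(image = image, mask = mask, kdata = kdata, spec = spec),
            class = "cs_fixture")
}

#' Write a magnitude image as grayscale PNG
#'
#' @param x complex image; its magnitude is rescaled to \[0, 1\].
#' @param path output path.
#' @export
write_magnitude_png <- function(x, path) {
  m <- Mod(x)
  rng <- range(m)
  if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
  png::writePNG(m, path)
  invisible(path)
}
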