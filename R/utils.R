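#' @keywords internal
"_PACKAGE"

# ---- validation helpers ----------------------------------------------------

stop_gwovit <- function(msg, class) {
  stop(structure(class = c(class, "gwovit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_gwovit(sprintf("`%s` must be an H x W x 3 array", arg), "invalid_image")
  if (anyNA(img) || min(img) < -1e-6 || max(img) > 255 + 1e-6)
    stop_gwovit(sprintf("`%s` must have finite values in [0, 255]", arg),
                "invalid_image")
  invisible(img)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# ---- reproducible RNG streams ----------------------------------------------

#' Run code under a temporary RNG state
#'
#' Seeds the global RNG with `seed`, evaluates `expr`, and restores the
#' previous RNG state afterwards, so library code never perturbs the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of arbitrary key parts, used to derive independent
# per-item RNG streams from one dataset-level seed.
stream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# ---- image file I/O ---------------------------------------------------------

#' Read an RGB image file
#'
#' Reads a PNG file into the package's working representation: an
#' H x W x 3 numeric array with intensities in \[0, 255\].
#'
#' @param path file path.
#' @return numeric H x W x 3 array in \[0, 255\].
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Write an RGB image file
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param path destination PNG path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(clip255(img) / 255, path)
  invisible(path)
}

# Round an image to the 8-bit grid it would have after a PNG round trip.
quantize255 <- function(img) round(clip255(img))
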