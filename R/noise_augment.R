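#' Salt-and-pepper noise augmentation
#'
#' Corrupts an image with impulse noise: each pixel is independently
#' replaced with probability `factor`; a replaced pixel becomes white (255)
#' with probability `salt_share` and black (0) otherwise. Pixels not
#' selected for replacement are returned bit-identical. For color arrays the
#' replacement is decided per pixel and applied to all channels together, so
#' the impulses are pure black/white as in real sensor dropouts.
#'
#' The augmentation never modifies its input in place; callers keep the
#' clean originals for downstream morphometry.
#'
#' @param image H x W matrix or H x W x C array, intensities in 0-255.
#' @param factor replacement probability in `[0, 1]` (the "noise factor";
#'   the reference setting for training-set augmentation is 0.2).
#' @param salt_share fraction of replaced pixels set to white, default 0.5.
#' @param seed optional integer seed for reproducible noise.
#' @return an array of the same shape and mode as `image`.
#' @examples
#' img <- matrix(128, 8, 8)
#' noisy <- sp_noise(img, factor = 0.2, seed = 1)
#' mean(noisy != img)
#' @export
sp_noise <- function(image, factor, salt_share = 0.5, seed = NULL) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0 || factor > 1)
    stop("noise factor must be a single probability in [0, 1]")
  if (salt_share < 0 || salt_share > 1)
    stop("salt_share must lie in [0, 1]")
  stopifnot(is.numeric(image))
  if (any(image < 0 | image > 255)) stop("intensities must lie in [0, 255]")
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% 2:3))
    stop("image must be an H x W matrix or H x W x C array")
  h <- d[1]; w <- d[2]
  draw <- function() {
    replace <- matrix(stats::runif(h * w) < factor, h, w)
    salt <- matrix(stats::runif(h * w) < salt_share, h, w)
    list(replace = replace, value = ifelse(salt, 255, 0))
  }
  rs <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (is.integer(image)) storage.mode(rs$value) <- "integer"
  out <- image
  if (length(d) == 2L) {
    out[rs$replace] <- rs$value[rs$replace]
  } else {
    for (k in seq_len(d[3])) {
      ch <- out[, , k]
      ch[rs$replace] <- rs$value[rs$replace]
      out[, , k] <- ch
    }
  }
  out
}

#' Augment an image directory with salt-and-pepper noise
#'
#' Reads every PNG/JPEG in `in_dir`, applies [sp_noise()] and writes the
#' corrupted copies as PNG into `out_dir` (originals untouched). Per-file
#' seeds are derived deterministically from `seed` and the file order.
#'
#' @param in_dir,out_dir input and output directories.
#' @inheritParams sp_noise
#' @return character vector of written paths, invisibly.
#' @export
augment_dir <- function(in_dir, out_dir, factor = 0.2, salt_share = 0.5,
                        seed = 0) {
  if (!dir.exists(in_dir)) stop("input directory not found: ", in_dir)
  files <- list.files(in_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(length(files))
  for (i in seq_along(files)) {
    img <- read_image(file.path(in_dir, files[i]))
    noisy <- sp_noise(img, factor, salt_share, seed = seed + i - 1L)
    out[i] <- file.path(out_dir,
                        paste0(tools::file_path_sans_ext(files[i]), ".png"))
    write_image(noisy, out[i])
  }
  invisible(out)
}
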