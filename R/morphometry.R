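#' Crop an image to a bounding box
#'
#' Extracts the region covered by a 0-based half-open box, clipping the box
#' to the image extent first; the returned region has shape
#' `(ymax - ymin, xmax - xmin)` after clipping. A box with no overlap is an
#' error.
#'
#' @param image H x W matrix or H x W x C array.
#' @param box a single-row box data.frame ([bbox()]).
#' @return the cropped image region.
#' @export
crop_box <- function(image, box) {
  stopifnot(is.numeric(image))
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% 2:3)) stop("image must be 2D or 3D")
  validate_boxes(box)
  stopifnot(nrow(box) == 1L)
  h <- d[1]; w <- d[2]
  x0 <- max(box$xmin, 0L); y0 <- max(box$ymin, 0L)
  x1 <- min(box$xmax, w); y1 <- min(box$ymax, h)
  if (x0 >= x1 || y0 >= y1)
    stop("bounding box does not overlap the image extent")
  if (length(d) == 2L) image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  else image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
}

#' Convert an image to grayscale
#'
#' 3-channel input is reduced with ITU-R BT.601 luma
#' (`0.299 R + 0.587 G + 0.114 B`), rounded half up to the integer 0-255
#' scale; single-channel input passes through bit-identical.
#'
#' @param image H x W matrix or H x W x 3 array, values in 0-255.
#' @return H x W numeric matrix.
#' @export
to_gray <- function(image) {
  stopifnot(is.numeric(image))
  if (any(image < 0 | image > 255)) stop("intensities must lie in [0, 255]")
  d <- dim(image)
  if (is.null(d)) stop("image must be a matrix or 3D array")
  if (length(d) == 2L) return(image)
  if (length(d) == 3L && d[3] == 1L) return(image[, , 1L])
  if (length(d) == 3L && d[3] == 3L) {
    y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    return(floor(y + 0.5))  # round half up
  }
  stop("expected 1 or 3 channels, got ", if (length(d) == 3L) d[3] else "?")
}

#' Binarize a grayscale image at a fixed threshold
#'
#' Pixels strictly greater than `threshold` become white (1, seed);
#' all others — including pixels exactly at the threshold — become black
#' (0, background). The default threshold is 120 on the 0-255 scale.
#'
#' @param gray H x W matrix, values in 0-255.
#' @param threshold intensity threshold in `[0, 255]`.
#' @return H x W integer matrix over \{0, 1\}.
#' @examples
#' binarize(matrix(c(0, 255, 130, 119), 2, 2))
#' @export
binarize <- function(gray, threshold = 120) {
  stopifnot(is.numeric(gray), is.matrix(gray))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single intensity in [0, 255]")
  if (any(gray < 0 | gray > 255)) stop("intensities must lie in [0, 255]")
  m <- (gray > threshold) + 0L
  dim(m) <- dim(gray)
  m
}

#' Count white pixels of a binary image
#'
#' @param bin binary matrix over \{0, 1\} ([binarize()]).
#' @return integer foreground pixel count.
#' @export
count_white <- function(bin) {
  stopifnot(is.numeric(bin))
  if (!all(bin %in% c(0L, 1L))) stop("not a binary image: values outside {0, 1}")
  as.integer(sum(bin))
}

#' Growth series container
#'
#' Per-dish sequence of (hours, white-pixel count). Times must be strictly
#' increasing and counts non-negative.
#'
#' @param dish_id character identifier.
#' @param time_h numeric hours (the regression's x).
#' @param count white-pixel counts (the regression's Y).
#' @return object of class `growth_series` (a data.frame with attribute
#'   `dish_id`).
#' @export
growth_series <- function(dish_id, time_h, count) {
  stopifnot(is.character(dish_id), length(dish_id) == 1L,
            length(time_h) == length(count), length(time_h) >= 1L)
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (any(count < 0)) stop("counts must be non-negative")
  structure(data.frame(time_h = as.numeric(time_h),
                       count = as.numeric(count)),
            dish_id = dish_id, class = c("growth_series", "data.frame"))
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> dish %s: %d samples, t = %g..%g h\n",
              attr(x, "dish_id"), nrow(x), min(x$time_h), max(x$time_h)))
  print(as.data.frame(x), ...)
  invisible(x)
}

# nearest-center track of one seed through a frame sequence; returns the
# row index of the tracked box in each frame
track_boxes <- function(frames, init_index = 1L) {
  centers <- function(b) cbind((b$xmin + b$xmax) / 2, (b$ymin + b$ymax) / 2)
  idx <- integer(length(frames))
  b0 <- frames[[1]]$boxes
  if (nrow(b0) < init_index) stop("initial box index out of range")
  idx[1] <- init_index
  prev <- centers(b0)[init_index, ]
  for (k in seq_along(frames)[-1]) {
    b <- frames[[k]]$boxes
    if (nrow(b) == 0L)
      stop("no boxes to track in frame ", frames[[k]]$image_id)
    cc <- centers(b)
    d <- sqrt((cc[, 1] - prev[1])^2 + (cc[, 2] - prev[2])^2)
    near <- which(d == min(d))
    if (length(near) > 1L)
      stop("ambiguous track in frame ", frames[[k]]$image_id,
           ": two boxes equally near the tracked seed")
    idx[k] <- near
    prev <- cc[near, ]
  }
  idx
}

#' Assemble a white-pixel growth series from annotated frames
#'
#' The measurement core: for each requested hour, the nearest frame (within
#' half the acquisition interval) is selected, the tracked seed's box is
#' cropped out, converted to gray, binarized at `threshold`, and its white
#' pixels counted. The default grid samples hours 24 to 48 at 1-h steps —
#' most seeds only start germinating about a day in, so earlier frames
#' carry no growth signal.
#'
#' Tracking selects box `init_index` in the first sampled frame, then
#' follows nearest box centers frame to frame; pass a `track` function
#' `(annotated_frame) -> row index` to override (e.g. manual selection).
#'
#' @param frames list of `list(frame = annotated_frame, image = matrix)`
#'   in any order; ordered by `time_h` internally.
#' @param dish_id identifier for the output series.
#' @param start_h,step_h,end_h sampling grid in hours (defaults 24, 1, 48).
#' @param threshold binarization threshold (default 120).
#' @param init_index row of the box to track in the first sampled frame.
#' @param track optional override: function mapping an [annotated_frame()]
#'   to the row index of the box to measure.
#' @return a [growth_series()].
#' @export
assemble_series <- function(frames, dish_id = "dish", start_h = 24,
                            step_h = 1, end_h = 48, threshold = 120,
                            init_index = 1L, track = NULL) {
  if (length(frames) == 0L) stop("empty frame list")
  times <- vapply(frames, function(f) f$frame$time_h, numeric(1))
  o <- order(times)
  frames <- frames[o]; times <- times[o]
  grid <- seq(start_h, end_h, by = step_h)
  if (length(grid) < 1L) stop("empty sampling grid")
  interval <- if (length(times) > 1L) stats::median(diff(times)) else Inf
  pick <- integer(length(grid))
  for (i in seq_along(grid)) {
    d <- abs(times - grid[i])
    j <- which.min(d)
    if (d[j] > interval / 2 + 1e-9)
      stop(sprintf("missing time point: no frame within %.3g h of t = %g h",
                   interval / 2, grid[i]))
    pick[i] <- j
  }
  sel <- frames[pick]
  ann <- lapply(sel, `[[`, "frame")
  idx <- if (is.null(track)) track_boxes(ann, init_index)
         else vapply(ann, track, integer(1))
  counts <- vapply(seq_along(sel), function(i) {
    box <- ann[[i]]$boxes[idx[i], , drop = FALSE]
    count_white(binarize(to_gray(crop_box(sel[[i]]$image, box)), threshold))
  }, integer(1))
  growth_series(dish_id, grid, counts)
}

#' Load an image + annotation directory pair as measurable frames
#'
#' Pairs every VOC XML in `ann_dir` with the same-named image in `img_dir`.
#'
#' @param img_dir directory of PNG/JPEG frames.
#' @param ann_dir directory of VOC XML annotations.
#' @param labels recognized labels, passed to [read_voc()].
#' @return list of `list(frame, image)` suitable for [assemble_series()].
#' @export
load_frames <- function(img_dir, ann_dir, labels = default_labels) {
  if (!dir.exists(ann_dir)) stop("annotation directory not found: ", ann_dir)
  if (!dir.exists(img_dir)) stop("image directory not found: ", img_dir)
  xmls <- list.files(ann_dir, pattern = "\\.xml$", full.names = TRUE)
  if (length(xmls) == 0L) stop("no XML annotations in ", ann_dir)
  lapply(xmls, function(p) {
    fr <- read_voc(p, labels = labels)
    base <- tools::file_path_sans_ext(basename(p))
    cand <- file.path(img_dir, paste0(base, c(".png", ".jpg", ".jpeg")))
    img <- cand[file.exists(cand)]
    if (length(img) == 0L) stop("no image found for annotation ", base)
    list(frame = fr, image = to_gray(read_image(img[1])))
  })
}
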