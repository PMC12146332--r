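#' Bounding boxes
#'
#' Axis-aligned pixel-coordinate rectangles with a class label. The internal
#' convention is 0-based and half-open: a box (xmin, ymin, xmax, ymax) covers
#' pixel columns `xmin..xmax-1` and rows `ymin..ymax-1`, so its width is
#' exactly `xmax - xmin`. Pascal VOC files, which are 1-based with inclusive
#' boundaries, are converted on read/write ([read_voc()], [write_voc()]).
#'
#' @param xmin,ymin,xmax,ymax integer pixel coordinates (vectorized).
#' @param label character class labels, recycled to length.
#' @return a `data.frame` with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `label`, one row per box.
#' @examples
#' bbox(0, 0, 10, 10, "germinated")
#' @export
bbox <- function(xmin, ymin, xmax, ymax, label = "ungerminated") {
  b <- data.frame(xmin = as.integer(xmin), ymin = as.integer(ymin),
                  xmax = as.integer(xmax), ymax = as.integer(ymax),
                  label = as.character(label), stringsAsFactors = FALSE)
  validate_boxes(b)
  b
}

validate_boxes <- function(b) {
  stopifnot(is.data.frame(b),
            all(c("xmin", "ymin", "xmax", "ymax", "label") %in% names(b)))
  if (nrow(b) == 0L) return(invisible(b))
  if (any(b$xmin < 0) || any(b$ymin < 0))
    stop("bounding-box coordinates must be non-negative")
  if (any(b$xmin >= b$xmax) || any(b$ymin >= b$ymax))
    stop("degenerate bounding box: require xmin < xmax and ymin < ymax")
  invisible(b)
}

empty_boxes <- function() {
  data.frame(xmin = integer(), ymin = integer(), xmax = integer(),
             ymax = integer(), label = character(), stringsAsFactors = FALSE)
}

#' Annotated frame
#'
#' One time point of a dish: an image identifier, the acquisition time in
#' hours since the start of the experiment, and the seed bounding boxes.
#'
#' @param image_id character scalar, unique within a dataset.
#' @param time_h non-negative hours since experiment start.
#' @param boxes a box data.frame as returned by [bbox()] (possibly 0 rows).
#' @param size optional `c(height, width)` of the underlying image.
#' @return object of class `annotated_frame`.
#' @export
annotated_frame <- function(image_id, time_h = 0, boxes = empty_boxes(),
                            size = NULL) {
  stopifnot(is.character(image_id), length(image_id) == 1L,
            is.numeric(time_h), length(time_h) == 1L, time_h >= 0)
  validate_boxes(boxes)
  structure(list(image_id = image_id, time_h = as.numeric(time_h),
                 boxes = boxes, size = size),
            class = "annotated_frame")
}

#' @export
print.annotated_frame <- function(x, ...) {
  cat(sprintf("<annotated_frame> %s  t = %g h  (%d box%s)\n", x$image_id,
              x$time_h, nrow(x$boxes), if (nrow(x$boxes) == 1) "" else "es"))
  if (nrow(x$boxes)) print(x$boxes)
  invisible(x)
}

#' @export
format.annotated_frame <- function(x, ...) {
  sprintf("annotated_frame(%s, %g h, %d boxes)", x$image_id, x$time_h,
          nrow(x$boxes))
}

default_labels <- c("germinated", "ungerminated")

#' Read a Pascal VOC annotation file
#'
#' Parses one VOC XML file into an [annotated_frame()]. VOC stores 1-based
#' inclusive pixel coordinates; they are converted to the internal 0-based
#' half-open convention, so a VOC box `(1, 1, 10, 10)` becomes the internal
#' box `(0, 0, 10, 10)` of width 10. Objects whose `<name>` is not in
#' `labels` are skipped with a warning, or rejected when `strict = TRUE`.
#'
#' The frame's acquisition time is taken from a `<time_h>` child of the root
#' (an extension written by [write_voc()]); absent that, it defaults to 0.
#'
#' @param xml_path path to the XML file.
#' @param labels recognized class labels.
#' @param strict if `TRUE`, an unrecognized label is an error.
#' @return an [annotated_frame()].
#' @export
read_voc <- function(xml_path, labels = default_labels, strict = FALSE) {
  if (!file.exists(xml_path)) stop("annotation file not found: ", xml_path)
  doc <- tryCatch(xml2::read_xml(xml_path),
                  error = function(e) stop("malformed VOC XML in '", xml_path,
                                           "': ", conditionMessage(e)))
  num1 <- function(node, xp) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) NA_real_
    else as.numeric(xml2::xml_text(n))
  }
  image_id <- {
    fn <- xml2::xml_find_first(doc, "./filename")
    if (inherits(fn, "xml_missing")) tools::file_path_sans_ext(basename(xml_path))
    else tools::file_path_sans_ext(xml2::xml_text(fn))
  }
  time_h <- num1(doc, "./time_h")
  if (is.na(time_h)) time_h <- 0
  h <- num1(doc, "./size/height"); w <- num1(doc, "./size/width")
  size <- if (!is.na(h) && !is.na(w)) c(h, w) else NULL

  objs <- xml2::xml_find_all(doc, "./object")
  rows <- lapply(objs, function(o) {
    lab <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    if (!lab %in% labels) {
      msg <- sprintf("skipping object with unrecognized label '%s' in %s",
                     lab, xml_path)
      if (strict) stop(msg) else warning(msg, call. = FALSE)
      return(NULL)
    }
    # VOC 1-based inclusive -> 0-based half-open
    data.frame(xmin = num1(o, "./bndbox/xmin") - 1,
               ymin = num1(o, "./bndbox/ymin") - 1,
               xmax = num1(o, "./bndbox/xmax"),
               ymax = num1(o, "./bndbox/ymax"),
               label = lab, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  boxes <- if (length(rows)) do.call(rbind, rows) else empty_boxes()
  boxes$xmin <- as.integer(boxes$xmin); boxes$ymin <- as.integer(boxes$ymin)
  boxes$xmax <- as.integer(boxes$xmax); boxes$ymax <- as.integer(boxes$ymax)
  validate_boxes(boxes)
  annotated_frame(image_id, time_h, boxes, size)
}

#' Write a Pascal VOC annotation file
#'
#' Inverse of [read_voc()]: internal 0-based half-open boxes are written in
#' VOC's 1-based inclusive dialect, and the acquisition time is stored in a
#' `<time_h>` extension element so that frames round-trip exactly.
#'
#' @param frame an [annotated_frame()].
#' @param xml_path output path.
#' @return `xml_path`, invisibly.
#' @export
write_voc <- function(frame, xml_path) {
  stopifnot(inherits(frame, "annotated_frame"))
  validate_boxes(frame$boxes)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", paste0(frame$image_id, ".png"))
  xml2::xml_add_child(doc, "time_h", format(frame$time_h, digits = 15))
  if (!is.null(frame$size)) {
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", as.character(frame$size[2]))
    xml2::xml_add_child(sz, "height", as.character(frame$size[1]))
    xml2::xml_add_child(sz, "depth", "1")
  }
  for (i in seq_len(nrow(frame$boxes))) {
    b <- frame$boxes[i, ]
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", b$label)
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(b$xmin + 1L))
    xml2::xml_add_child(bb, "ymin", as.character(b$ymin + 1L))
    xml2::xml_add_child(bb, "xmax", as.character(b$xmax))
    xml2::xml_add_child(bb, "ymax", as.character(b$ymax))
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Deterministic 7:2:1 dataset split
#'
#' Splits `n_items` indices into train/test/validation sets. With the
#' default 7:2:1 ratios the training count is `floor(0.7 N)` and the
#' remainder is divided exactly 2:1 between test and validation, any
#' leftover item going to the test set; for N = 8148 this yields
#' 5703 / 1630 / 815. Assignment is a seeded random permutation, so the
#' same `(n_items, seed)` always produces the same split.
#'
#' @param n_items number of items (non-negative integer).
#' @param ratios length-3 positive weights, default `c(7, 2, 1)`.
#' @param seed integer RNG seed (default 0).
#' @return list with `counts` (named integer vector `train`, `test`, `val`)
#'   and `assignment` (character vector of length `n_items` over
#'   `"train"/"test"/"val"`, in original item order).
#' @examples
#' split_dataset(10)$counts
#' @export
split_dataset <- function(n_items, ratios = c(7, 2, 1), seed = 0) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 0 ||
      n_items != floor(n_items))
    stop("n_items must be a non-negative integer")
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  n <- as.integer(n_items)
  w <- ratios / sum(ratios)
  n_train <- floor(w[1] * n)
  rem <- n - n_train
  # remainder split ratios[2]:ratios[3]; leftover goes to test
  n_val <- floor(rem * ratios[3] / (ratios[2] + ratios[3]))
  n_test <- rem - n_val
  counts <- c(train = as.integer(n_train), test = as.integer(n_test),
              val = as.integer(n_val))
  perm <- if (n > 0) with_seed(seed, sample.int(n)) else integer()
  assignment <- character(n)
  assignment[perm] <- rep(c("train", "test", "val"), counts)
  list(counts = counts, assignment = assignment)
}

#' Write split manifests as plain-text file lists
#'
#' @param ids character vector of item identifiers.
#' @param split result of [split_dataset()] for `length(ids)` items.
#' @param dir output directory; `train.txt`, `test.txt`, `val.txt` written.
#' @return named character vector of the three paths, invisibly.
#' @export
write_split_manifests <- function(ids, split, dir) {
  stopifnot(length(ids) == length(split$assignment))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(train = file.path(dir, "train.txt"),
             test = file.path(dir, "test.txt"),
             val = file.path(dir, "val.txt"))
  for (s in names(paths))
    writeLines(ids[split$assignment == s], paths[[s]])
  invisible(paths)
}
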