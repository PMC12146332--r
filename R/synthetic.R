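#' Sprout growth laws
#'
#' Radicle length (pixels) as a function of time since germination onset.
#' `growth_cubic` gives `c3*dt^3 + c2*dt^2 + c1*dt` clamped at 0 (the family
#' the fitting stage is expected to recover); `growth_logistic` gives a
#' saturating curve `L / (1 + exp(-k (dt - tm)))`. Both return 0 before
#' onset (`dt < 0`).
#'
#' @param c3,c2,c1 cubic coefficients (length in pixels, dt in hours).
#' @param L,k,tm logistic asymptote (px), rate (1/h) and midpoint (h).
#' @return a vectorized function `dt -> length in pixels`.
#' @export
growth_cubic <- function(c3, c2, c1) {
  force(c3); force(c2); force(c1)
  f <- function(dt) ifelse(dt < 0, 0, pmax(0, ((c3 * dt + c2) * dt + c1) * dt))
  attr(f, "law") <- list(family = "cubic", c3 = c3, c2 = c2, c1 = c1)
  f
}

#' @rdname growth_cubic
#' @export
growth_logistic <- function(L, k, tm) {
  force(L); force(k); force(tm)
  f <- function(dt) ifelse(dt < 0, 0, L / (1 + exp(-k * (dt - tm))))
  attr(f, "law") <- list(family = "logistic", L = L, k = k, tm = tm)
  f
}

#' Specify one synthetic seed
#'
#' Geometry and kinetics of a single seed in a synthetic dish: an ellipse
#' body plus a straight constant-width radicle stroke whose length follows
#' `growth` after onset `t0`. A positive `shrink_rate` linearly shrinks the
#' body axes after onset, emulating the drying-out confound seen in real
#' time-lapses where the sprout grows while the seed body shrinks, so the
#' fitting stage can be exercised on non-monotone area series.
#'
#' @param center `c(x, y)` in continuous 0-based pixel coordinates.
#' @param axes `c(a, b)` ellipse semi-axes in pixels, both > 0.
#' @param t0 germination onset, hours.
#' @param growth growth law from [growth_cubic()] / [growth_logistic()].
#' @param sprout_width stroke width in pixels (default 3).
#' @param sprout_dir direction of the radicle ray, radians (default 0).
#' @param intensity body/sprout gray level, default 200 (above the 120
#'   binarization threshold).
#' @param shrink_rate fractional axis shrinkage per hour after `t0`
#'   (default 0; > 0 reproduces the shrinkage confound).
#' @return object of class `seed_spec`.
#' @export
seed_spec <- function(center, axes, t0, growth = growth_cubic(0, 0, 1),
                      sprout_width = 3, sprout_dir = 0, intensity = 200,
                      shrink_rate = 0) {
  stopifnot(length(center) == 2L, length(axes) == 2L, all(axes > 0),
            t0 >= 0, is.function(growth), sprout_width > 0,
            intensity >= 0, intensity <= 255, shrink_rate >= 0)
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 t0 = t0, growth = growth, sprout_width = sprout_width,
                 sprout_dir = sprout_dir, intensity = intensity,
                 shrink_rate = shrink_rate),
            class = "seed_spec")
}

#' Specify a synthetic germination time-lapse
#'
#' A full scene: image geometry, acquisition grid (48 h at 30-min intervals
#' by default, i.e. 97 frames), a dark-cloth background, an optional Petri
#' dish ring, the seeds and optional impulse noise. Intensities default to
#' background 15 and ring 60 — both below the 120 threshold — and seed
#' bodies 200, so on noise-free scenes binarization at 120 recovers the
#' generator's exact foreground mask.
#'
#' @param width,height image size in pixels.
#' @param seeds list of [seed_spec()] objects; all must fit in the image.
#' @param frame_interval hours between frames (default 0.5).
#' @param duration total duration in hours (default 48).
#' @param background background gray level (default 15).
#' @param dish optional `list(center = c(x, y), radius, intensity = 60,
#'   thickness = 2)` ring.
#' @param noise optional `list(factor, salt_share = 0.5)`; applied to the
#'   rendered image only, after ground truth is recorded.
#' @param visibility_threshold radicle length (px) above which a seed is
#'   labeled `"germinated"` (default 2).
#' @param id dish identifier used in image ids (default `"dish"`).
#' @param seed integer RNG seed for the noise stream.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width, height, seeds, frame_interval = 0.5,
                       duration = 48, background = 15, dish = NULL,
                       noise = NULL, visibility_threshold = 2,
                       id = "dish", seed = 0) {
  stopifnot(width >= 4, height >= 4, frame_interval > 0, duration > 0,
            background >= 0, background <= 255, length(seeds) >= 1)
  for (s in seeds) {
    stopifnot(inherits(s, "seed_spec"))
    if (s$center[1] - s$axes[1] < 0 || s$center[1] + s$axes[1] > width ||
        s$center[2] - s$axes[2] < 0 || s$center[2] + s$axes[2] > height)
      stop("seed body does not fit inside the image extent")
  }
  if (!is.null(noise)) {
    stopifnot(is.list(noise), !is.null(noise$factor))
    noise$salt_share <- noise$salt_share %||% 0.5
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 seeds = seeds, frame_interval = frame_interval,
                 duration = duration, background = background, dish = dish,
                 noise = noise, visibility_threshold = visibility_threshold,
                 id = id, seed = as.integer(seed)),
            class = "scene_spec")
}

# pixel-center coordinate grids (continuous 0-based; pixel (r,c) center
# at x = c - 0.5, y = r - 0.5)
scene_grid <- function(spec) {
  x <- matrix(rep(seq_len(spec$width) - 0.5, each = spec$height),
              spec$height, spec$width)
  y <- matrix(rep(seq_len(spec$height) - 0.5, times = spec$width),
              spec$height, spec$width)
  list(x = x, y = y)
}

# logical mask of one seed (body + radicle) at time t
seed_mask <- function(s, t, grid) {
  shrink <- if (t > s$t0 && s$shrink_rate > 0)
    max(0.05, 1 - s$shrink_rate * (t - s$t0)) else 1
  a <- s$axes[1] * shrink; b <- s$axes[2] * shrink
  dx <- grid$x - s$center[1]; dy <- grid$y - s$center[2]
  mask <- (dx / a)^2 + (dy / b)^2 <= 1
  len <- s$growth(t - s$t0)
  if (len > 0) {
    ct <- cos(s$sprout_dir); st <- sin(s$sprout_dir)
    # stroke starts on the ellipse boundary along the ray direction; the
    # rounded tip is included in the stated length so that the stroke's
    # area stays close to width * length
    rb <- a * b / sqrt((b * ct)^2 + (a * st)^2)
    p0 <- s$center + rb * c(ct, st)
    seg <- max(0, len - s$sprout_width / 2)
    px <- grid$x - p0[1]; py <- grid$y - p0[2]
    proj <- pmin(pmax(px * ct + py * st, 0), seg)
    d2 <- (px - proj * ct)^2 + (py - proj * st)^2
    mask <- mask | d2 <= (s$sprout_width / 2)^2
  }
  list(mask = mask, length = len)
}

#' Render one frame of a synthetic scene
#'
#' Draws background, optional dish ring, and every seed as a filled ellipse
#' plus its radicle stroke. Ground truth (exact foreground mask, per-seed
#' areas, tight bounding boxes, germination labels) is recorded before any
#' noise is applied.
#'
#' @param spec a [scene_spec()].
#' @param t time in hours, within `[0, duration]`.
#' @param apply_noise apply the scene's noise config to the image
#'   (default `TRUE`; the truth is always noise-free).
#' @return list with `image` (H x W matrix, 0-255), `frame`
#'   ([annotated_frame()] with one box per seed), `true_mask` (logical
#'   H x W), `areas` (integer per-seed foreground pixel counts) and
#'   `lengths` (radicle lengths in px).
#' @export
render_frame <- function(spec, t, apply_noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > spec$duration)
    stop("t must lie in [0, ", spec$duration, "] hours")
  grid <- scene_grid(spec)
  img <- matrix(spec$background, spec$height, spec$width)
  if (!is.null(spec$dish)) {
    d <- spec$dish
    thick <- d$thickness %||% 2
    r <- sqrt((grid$x - d$center[1])^2 + (grid$y - d$center[2])^2)
    img[abs(r - d$radius) <= thick / 2] <- d$intensity %||% 60
  }
  n <- length(spec$seeds)
  true_mask <- matrix(FALSE, spec$height, spec$width)
  areas <- integer(n); lengths <- numeric(n)
  boxes <- vector("list", n)
  for (i in seq_len(n)) {
    s <- spec$seeds[[i]]
    sm <- seed_mask(s, t, grid)
    img[sm$mask] <- s$intensity
    true_mask <- true_mask | sm$mask
    areas[i] <- sum(sm$mask)
    lengths[i] <- sm$length
    rc <- which(sm$mask, arr.ind = TRUE)
    lab <- if (sm$length > spec$visibility_threshold) "germinated"
           else "ungerminated"
    boxes[[i]] <- bbox(min(rc[, 2]) - 1L, min(rc[, 1]) - 1L,
                       max(rc[, 2]), max(rc[, 1]), lab)
  }
  image_id <- sprintf("%s_t%05.1fh", spec$id, t)
  frame <- annotated_frame(image_id, t, do.call(rbind, boxes),
                           size = c(spec$height, spec$width))
  if (apply_noise && !is.null(spec$noise)) {
    frame_seed <- spec$seed + as.integer(round(t / spec$frame_interval)) + 1L
    img <- sp_noise(img, spec$noise$factor, spec$noise$salt_share,
                    seed = frame_seed)
  }
  list(image = img, frame = frame, true_mask = true_mask,
       areas = areas, lengths = lengths)
}

#' Render a full synthetic time-lapse stack
#'
#' Frames at `t = 0, interval, 2*interval, ..., duration` (97 frames for
#' the default 48 h / 0.5 h grid). Per-frame ground-truth areas are exact
#' foreground pixel counts taken before noise. Identical specs (including
#' the seed) render bit-identical stacks.
#'
#' @inheritParams render_frame
#' @return list of class `germ_stack`: elements as in [render_frame()] plus
#'   `time_h`, one per frame.
#' @export
render_stack <- function(spec, apply_noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  times <- seq(0, spec$duration, by = spec$frame_interval)
  frames <- lapply(times, function(t) {
    fr <- render_frame(spec, t, apply_noise = apply_noise)
    fr$time_h <- t
    fr
  })
  structure(frames, class = "germ_stack", id = spec$id)
}

#' Ground-truth table of a rendered stack
#'
#' @param stack a `germ_stack` from [render_stack()].
#' @return data.frame with columns `image_id`, `time_h`, `seed_id`,
#'   `true_area`, `label`.
#' @export
stack_truth <- function(stack) {
  stopifnot(inherits(stack, "germ_stack"))
  do.call(rbind, lapply(stack, function(fr) {
    n <- length(fr$areas)
    data.frame(image_id = fr$frame$image_id, time_h = fr$time_h,
               seed_id = seq_len(n), true_area = fr$areas,
               label = fr$frame$boxes$label, stringsAsFactors = FALSE)
  }))
}

#' Write a rendered stack to disk
#'
#' PNG images under `images/`, VOC XML under `annotations/` and the
#' ground-truth table as `truth.csv`, all beneath `out_dir`.
#'
#' @param stack a `germ_stack`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_stack <- function(stack, out_dir) {
  stopifnot(inherits(stack, "germ_stack"))
  img_dir <- file.path(out_dir, "images")
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(ann_dir, showWarnings = FALSE, recursive = TRUE)
  for (fr in stack) {
    write_image(fr$image, file.path(img_dir, paste0(fr$frame$image_id, ".png")))
    write_voc(fr$frame, file.path(ann_dir, paste0(fr$frame$image_id, ".xml")))
  }
  utils::write.csv(stack_truth(stack), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
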