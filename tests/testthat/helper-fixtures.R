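# shared fixtures: published dish equations, small scenes, brute-force oracles

# published per-dish cubic growth equations (descending coefficients) and
# their printed first derivatives; dishes 6-8 carry typographical slips in
# the printed derivatives, so only 1-5 are exact-reproduction references
dish_cubics <- list(
  d1 = c(0.062, -4.9082, 147.9527, 2144.1588),
  d2 = c(0.0603, -2.2675, -9.5724, 3729.579),
  d3 = c(0.0046, 1.0051, -57.4411, 4141.1599),
  d4 = c(-0.0712, 8.3181, -277.671, 6509.3051),
  d5 = c(-0.0886, 9.7247, -314.9538, 7424.7836),
  d6 = c(-0.1153, 15.6859, -559.5365, 10383.6654),
  d7 = c(0.1096, -10.9386, 387.634, -719.1204),
  d8 = c(-0.2138, 24.1921, -836.4996, 12029.3196)
)
dish_derivatives_printed <- list(
  d1 = c(0.186, -9.8164, 147.9527),
  d2 = c(0.1809, -4.535, -9.5724),
  d3 = c(0.0138, 2.0102, -57.4411),
  d4 = c(-0.2136, 16.6362, -277.671),
  d5 = c(-0.2658, 19.4494, -314.9538)
)

# one-seed scene small enough to render 97 frames quickly
make_scene <- function(noise = NULL, shrink_rate = 0, id = "t1", seed = 0,
                       t0 = 20, growth = growth_cubic(0.0008, 0.01, 0.2)) {
  scene_spec(64, 64,
             list(seed_spec(center = c(22, 22), axes = c(7, 5), t0 = t0,
                            growth = growth, sprout_width = 3,
                            sprout_dir = 0.6, shrink_rate = shrink_rate)),
             noise = noise, id = id, seed = seed)
}

as_measurable <- function(stack) {
  lapply(stack, function(fr) list(frame = fr$frame, image = fr$image))
}

random_frame <- function(n_boxes, image_id = "rt", w = 200, h = 150) {
  if (n_boxes == 0) return(annotated_frame(image_id, 0, size = c(h, w)))
  xmin <- sample.int(w - 20, n_boxes); ymin <- sample.int(h - 20, n_boxes)
  bw <- sample(1:19, n_boxes, TRUE); bh <- sample(1:19, n_boxes, TRUE)
  lab <- sample(c("germinated", "ungerminated"), n_boxes, TRUE)
  annotated_frame(image_id, runif(1, 0, 48),
                  bbox(xmin, ymin, xmin + bw, ymin + bh, lab),
                  size = c(h, w))
}

# brute-force maximum bipartite matching size under an IoU threshold
max_matching_bruteforce <- function(dets, gts, thr) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0L)
  iou_mat <- outer(seq_len(nd), seq_len(ng), Vectorize(function(i, j)
    iou(dets[i, , drop = FALSE], gts[j, , drop = FALSE])))
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1L) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    recurse(i + 1L, used, count)  # leave detection i unmatched
    for (j in seq_len(ng)) if (!used[j] && iou_mat[i, j] >= thr) {
      used[j] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(ng), 0L)
  best
}

# independent AP oracle: explicit envelope then rectangle integration over
# every recall step (no shared code with average_precision)
ap_bruteforce <- function(tp_sorted, n_gt) {
  if (n_gt == 0 || length(tp_sorted) == 0) return(0)
  cum_tp <- cumsum(tp_sorted); cum_fp <- cumsum(!tp_sorted)
  rec <- cum_tp / n_gt
  prec <- cum_tp / (cum_tp + cum_fp)
  env <- vapply(seq_along(prec), function(i) max(prec[i:length(prec)]),
                numeric(1))
  prev_r <- 0; total <- 0
  for (i in seq_along(rec)) {
    total <- total + (rec[i] - prev_r) * env[i]
    prev_r <- rec[i]
  }
  total
}
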