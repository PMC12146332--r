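test_that("iou covers identity, disjoint and partial overlap", {
  a <- bbox(0, 0, 10, 10)
  expect_equal(iou(a, a), 1.0)
  expect_equal(iou(a, bbox(20, 20, 30, 30)), 0.0)
  expect_equal(iou(a, bbox(5, 0, 15, 10)), 50 / 150)
  expect_equal(iou(a, bbox(10, 0, 20, 10)), 0.0)  # touching, half-open
})

test_that("greedy matching implements the one-to-one protocol", {
  gt <- bbox(0, 0, 10, 10)
  d1 <- detections("im", "g", 0.9, bbox(0, 0, 10, 10, "g"))
  led <- match_detections(d1, gt, 0.5)
  expect_equal(sum(led$tp), 1L); expect_equal(led$fn, 0L)

  # duplicate detections: only the higher-confidence one is a TP
  d2 <- detections(c("im", "im"), "g", c(0.6, 0.9),
                   bbox(c(0, 1), c(0, 1), c(10, 10), c(10, 10), "g"))
  led2 <- match_detections(d2, gt, 0.5)
  expect_equal(led2$tp, c(FALSE, TRUE))
  expect_equal(led2$fn, 0L)

  expect_error(match_detections(
    detections(c("a", "b"), "g", c(0.5, 0.5),
               bbox(c(0, 0), c(0, 0), c(5, 5), c(5, 5))), gt, 0.5),
    "single image_id")
})

test_that("greedy TP count equals brute-force matching on separated scenes", {
  # well-separated layouts (each detection overlaps at most one truth):
  # greedy is provably optimal there, so the brute-force maximum must agree
  set.seed(21)
  for (rep in 1:30) {
    n_gt <- sample(1:4, 1)
    gx <- (seq_len(n_gt) - 1) * 40
    gts <- bbox(gx, 0, gx + 20, 20)
    n_d <- sample(1:5, 1)
    src <- sample(seq_len(n_gt), n_d, TRUE)
    jit <- sample(0:12, n_d, TRUE)
    dets <- detections(rep("im", n_d), "g", runif(n_d),
                       bbox(gx[src] + jit, jit, gx[src] + 20 + jit,
                            20 + jit, "g"))
    for (thr in c(0.3, 0.5, 0.7)) {
      led <- match_detections(dets, gts, thr)
      expect_equal(sum(led$tp), max_matching_bruteforce(dets, gts, thr))
      expect_lte(sum(led$tp), n_gt)
    }
  }
})

test_that("greedy never exceeds the brute-force optimum on random scenes", {
  set.seed(22)
  for (rep in 1:20) {
    n_gt <- sample(1:4, 1); n_d <- sample(1:5, 1)
    gts <- bbox(sample(0:60, n_gt), sample(0:60, n_gt),
                sample(61:100, n_gt), sample(61:100, n_gt))
    dets <- detections(rep("im", n_d), "g", runif(n_d),
                       bbox(sample(0:60, n_d), sample(0:60, n_d),
                            sample(61:100, n_d), sample(61:100, n_d), "g"))
    led <- match_detections(dets, gts, 0.5)
    expect_lte(sum(led$tp), max_matching_bruteforce(dets, gts, 0.5))
  }
})

test_that("precision/recall are exact ratios with NA sentinels", {
  led <- structure(list(tp = c(TRUE, TRUE, TRUE, FALSE),
                        confidence = c(0.9, 0.8, 0.7, 0.6),
                        matched_gt = c(1L, 2L, 3L, NA), n_gt = 5,
                        fn = 2, iou_thr = 0.5), class = "match_ledger")
  pr <- precision_recall(led)
  expect_equal(unname(pr["precision"]), 0.75)
  expect_equal(unname(pr["recall"]), 0.6)
  empty <- structure(list(tp = logical(0), confidence = numeric(0),
                          matched_gt = integer(0), n_gt = 0, fn = 0,
                          iou_thr = 0.5), class = "match_ledger")
  expect_true(all(is.na(precision_recall(empty))))
})

test_that("average precision integrates the envelope exactly", {
  gt2 <- bbox(c(0, 40), c(0, 0), c(10, 50), c(10, 10))
  # one correct detection out of two truths: recall tops out at 0.5
  d <- detections("im", "g", 0.9, bbox(0, 0, 10, 10, "g"))
  led <- match_detections(d, gt2, 0.5)
  expect_equal(average_precision(pr_curve(list(led))), 0.5)

  # single correct detection on a single truth
  d1 <- detections("im", "g", 0.8, bbox(0, 0, 10, 10, "g"))
  led1 <- match_detections(d1, bbox(0, 0, 10, 10), 0.5)
  expect_equal(average_precision(pr_curve(list(led1))), 1.0)

  # random scenarios against the independent envelope integrator
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(1:8, 1); n_gt <- sample(1:6, 1)
    tp <- sample(c(TRUE, FALSE), n, TRUE)
    tp[seq_len(n)][cumsum(tp) > n_gt] <- FALSE  # at most n_gt TPs
    conf <- sort(runif(n), decreasing = TRUE)
    led <- structure(list(tp = tp, confidence = conf,
                          matched_gt = rep(NA_integer_, n), n_gt = n_gt,
                          fn = n_gt - sum(tp), iou_thr = 0.5),
                     class = "match_ledger")
    curve <- pr_curve(list(led))
    expect_equal(average_precision(curve), ap_bruteforce(tp, n_gt),
                 tolerance = 1e-12)
    # envelope property: interpolated precision non-increasing in recall
    p_env <- rev(cummax(rev(curve$precision)))
    expect_true(all(diff(p_env) <= 1e-12))
  }
})

test_that("AP is non-increasing in the IoU threshold", {
  set.seed(24)
  gts <- bbox(c(0, 30, 60), c(0, 0, 0), c(20, 50, 80), c(20, 20, 20))
  dets <- detections(rep("im", 3), "g", c(0.9, 0.8, 0.7),
                     bbox(c(2, 33, 70), c(2, 3, 0), c(22, 53, 90),
                          c(22, 23, 20), "g"))
  aps <- vapply(seq(0.3, 0.9, 0.1), function(thr)
    average_precision(pr_curve(list(match_detections(dets, gts, thr)))),
    numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
  expect_true(all(aps >= 0 & aps <= 1))
})

test_that("a perfect detector scores 1 everywhere", {
  sc <- make_scene(id = "pd")
  fr <- render_frame(sc, 40)$frame
  dets <- detections(fr$image_id, fr$boxes$label, 0.99, fr$boxes)
  ev <- evaluate_detections(dets, list(fr))
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1)
  expect_true(all(ev$map_per_iou == 1)); expect_equal(ev$map, 1)
})

test_that("mean_ap averages classes and thresholds as stated", {
  expect_equal(mean_ap(c(0.8, 0.6)), 0.7)
  expect_equal(mean(c(1.0, 0.5)), 0.75)
  expect_error(mean_ap(numeric(0)), "empty")
})

test_that("germination_rate rounds half up to one decimal", {
  expect_equal(germination_rate(2820, 11858)$rate, 23.8)
  expect_equal(germination_rate(3018, 11858)$rate, 25.5)
  expect_equal(germination_rate(0, 100)$rate, 0.0)
  expect_equal(germination_rate(1, 400)$rate, 0.3)  # 0.25 rounds up
  expect_error(germination_rate(5, 0), "positive")
})

test_that("detections round-trip through the TSV exchange format", {
  d <- detections(c("a", "a", "b"), c("g", "u", "g"), c(0.9, 0.5, 0.7),
                  bbox(c(0, 5, 10), c(0, 5, 10), c(10, 15, 20),
                       c(10, 15, 20)))
  path <- file.path(tempdir(), "dets.tsv")
  write_detections(d, path)
  expect_equal(read_detections(path), d)
})
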