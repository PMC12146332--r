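test_that("pre-onset frames are ungerminated ellipses of the exact area", {
  sc <- make_scene(t0 = 20)
  fr <- render_frame(sc, 10)
  expect_equal(fr$frame$boxes$label, "ungerminated")
  expect_equal(fr$lengths, 0)
  # discrete ellipse area: count pixel centers inside the ellipse directly
  s <- sc$seeds[[1]]
  xs <- rep(seq_len(64) - 0.5, each = 64); ys <- rep(seq_len(64) - 0.5, 64)
  area <- sum(((xs - s$center[1]) / s$axes[1])^2 +
              ((ys - s$center[2]) / s$axes[2])^2 <= 1)
  expect_equal(fr$areas, area)
  expect_equal(sum(fr$true_mask), area)
})

test_that("shrink-free growth gives monotone mask areas", {
  sc <- make_scene()
  ts <- seq(20, 48, by = 4)
  areas <- vapply(ts, function(t) sum(render_frame(sc, t)$areas), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("bounding boxes are the tight boxes of the rendered masks", {
  set.seed(9)
  for (i in 1:50) {
    sc <- scene_spec(48, 40,
      list(seed_spec(center = c(runif(1, 12, 36), runif(1, 12, 28)),
                     axes = c(runif(1, 3, 6), runif(1, 3, 6)),
                     t0 = runif(1, 0, 30),
                     growth = growth_cubic(0, 0, runif(1, 0.1, 0.6)),
                     sprout_width = runif(1, 2, 4),
                     sprout_dir = runif(1, 0, 2 * pi))),
      id = sprintf("rb%02d", i))
    fr <- render_frame(sc, runif(1, 0, 48))
    rc <- which(fr$true_mask, arr.ind = TRUE)
    expect_equal(fr$frame$boxes$xmin, min(rc[, 2]) - 1L)
    expect_equal(fr$frame$boxes$ymin, min(rc[, 1]) - 1L)
    expect_equal(fr$frame$boxes$xmax, max(rc[, 2]))
    expect_equal(fr$frame$boxes$ymax, max(rc[, 1]))
  }
})

test_that("stack has the full acquisition grid and is deterministic", {
  sc <- make_scene(noise = list(factor = 0.1), seed = 4)
  stk1 <- render_stack(sc)
  expect_length(stk1, 97)
  expect_equal(vapply(stk1, `[[`, numeric(1), "time_h"), seq(0, 48, 0.5))
  stk2 <- render_stack(sc)
  expect_identical(lapply(stk1, `[[`, "image"), lapply(stk2, `[[`, "image"))
})

test_that("sprout area matches width x length analytically", {
  sc <- make_scene(growth = growth_cubic(0, 0, 1), t0 = 10)  # 1 px/h
  s <- sc$seeds[[1]]
  base <- sum(render_frame(sc, 10)$areas)
  for (t in c(25, 35, 48)) {
    len <- t - 10
    extra <- sum(render_frame(sc, t)$areas) - base
    expect_lt(abs(extra - len * s$sprout_width) / (len * s$sprout_width), 0.1)
  }
})

test_that("each seed's label flips exactly once, when length exceeds 2 px", {
  sc <- make_scene()
  stk <- render_stack(sc)
  labs <- vapply(stk, function(fr) fr$frame$boxes$label, character(1))
  lens <- vapply(stk, function(fr) fr$lengths, numeric(1))
  flips <- sum(labs[-1] != labs[-length(labs)])
  expect_equal(flips, 1L)
  expect_equal(labs == "germinated", lens > sc$visibility_threshold)
})

test_that("shrinkage produces non-monotone area series", {
  sc <- make_scene(shrink_rate = 0.02)
  stk <- render_stack(sc)
  areas <- vapply(stk, function(fr) sum(fr$areas), numeric(1))
  expect_true(any(diff(areas) < 0))
})

test_that("write_stack emits images, annotations and a truth table", {
  sc <- make_scene(id = "ws")
  sc$duration <- 4  # short stack for I/O
  stk <- render_stack(sc)
  out <- file.path(tempdir(), "ws_stack")
  write_stack(stk, out)
  pngs <- list.files(file.path(out, "images"), pattern = "\\.png$")
  xmls <- list.files(file.path(out, "annotations"), pattern = "\\.xml$")
  expect_length(pngs, 9); expect_length(xmls, 9)
  truth <- read.csv(file.path(out, "truth.csv"))
  expect_equal(nrow(truth), 9)
  expect_named(truth, c("image_id", "time_h", "seed_id", "true_area", "label"))
  # PNG round-trip preserves exact intensities
  img <- read_image(file.path(out, "images", pngs[1]))
  expect_identical(img, stk[[1]]$image)
})
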