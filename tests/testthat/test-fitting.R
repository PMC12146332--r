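test_that("r_squared matches its definition and the linear-LS identity", {
  y <- c(1, 2, 3, 5)
  expect_equal(r_squared(y, y), 1.0)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0.0)
  # hand least-squares line for y on x = 1:4:
  # slope = Sxy/Sxx = 6.5/5 = 1.3, intercept = 2.75 - 1.3*2.5 = -0.5
  yhat <- 1.3 * (1:4) - 0.5
  both <- r_squared(y, yhat, form = "both")
  expect_equal(unname(both["explained"]), unname(both["residual"]),
               tolerance = 1e-12)
  expect_error(r_squared(rep(2, 4), rep(2, 4)), "constant")
})

test_that("evaluate_poly is Horner-exact against a naive power sum", {
  expect_equal(evaluate_poly(c(1, 0, 0), 3), 9)
  expect_equal(evaluate_poly(dish_cubics$d1, 0), 2144.1588)
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1), -5, 5)
    x <- runif(1, -10, 10)
    naive <- sum(p * x^(rev(seq_along(p)) - 1))
    expect_equal(evaluate_poly(p, x), naive, tolerance = 1e-9)
  }
})

test_that("differentiate applies the power rule and is linear", {
  expect_equal(unclass(differentiate(c(5))), 0)
  expect_equal(unclass(differentiate(c(2, 0, 1))), c(4, 0))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(4, -3, 3); q <- runif(4, -3, 3)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    lhs <- unclass(differentiate(a * p + b * q))
    rhs_p <- unclass(differentiate(p)); rhs_q <- unclass(differentiate(q))
    expect_equal(lhs, a * rhs_p + b * rhs_q, tolerance = 1e-12)
  }
})

test_that("printed dish derivatives 1-5 equal exact differentiation", {
  for (d in names(dish_derivatives_printed)) {
    expect_equal(unclass(differentiate(dish_cubics[[d]])),
                 dish_derivatives_printed[[d]], tolerance = 1e-12,
                 label = d)
  }
})

test_that("fit_family recovers exact generating laws", {
  x <- 1:10
  ser_exp <- growth_series("e", x, 2 * exp(0.5 * x))
  fe <- fit_family(ser_exp, "exponential")
  expect_equal(unname(fe$parameters["a"]), 2, tolerance = 1e-10)
  expect_equal(unname(fe$parameters["b"]), 0.5, tolerance = 1e-10)
  expect_equal(fe$r2, 1, tolerance = 1e-9)

  # 4 points from a cubic: order-3 fit interpolates exactly
  p <- c(0.5, -2, 3, 10)
  xs <- c(1, 3, 6, 9)
  fc <- fit_family(growth_series("c", xs, evaluate_poly(p, xs)), "polynomial")
  expect_equal(unclass(fc$coefficients), p, tolerance = 1e-8)

  fp <- fit_family(growth_series("p", x, 3 * x^1.5), "power")
  expect_equal(unname(fp$parameters), c(3, 1.5), tolerance = 1e-10)
  fl <- fit_family(growth_series("l", x, 7 * log(x) + 2), "logarithmic")
  expect_equal(unname(fl$parameters), c(7, 2), tolerance = 1e-10)
})

test_that("fit_family rejects unusable inputs", {
  ser <- growth_series("z", c(1, 2, 3), c(0, 1, 2))
  expect_error(fit_family(ser, "exponential"), "y > 0")
  expect_error(fit_family(ser, "polynomial", order = 3),
               "as many points as parameters")
  ser_neg_x <- growth_series("nx", c(-1, 1, 2, 3, 4), c(1, 2, 3, 4, 5))
  expect_error(fit_family(ser_neg_x, "logarithmic"), "x > 0")
})

test_that("noisy planted cubics are recovered within 3 standard errors", {
  x <- 24:48
  set.seed(13)
  ok <- vapply(1:40, function(i) {
    p <- dish_cubics[[(i - 1) %% 8 + 1]]
    y <- evaluate_poly(p, x)
    yn <- round(y + rnorm(length(x), 0, 0.01 * diff(range(y))))
    best <- select_best(growth_series("r", x, pmax(yn, 1)))
    if (best$family != "polynomial") return(FALSE)
    lf <- stats::lm(yn ~ x + I(x^2) + I(x^3))
    se <- stats::coef(summary(lf))[, 2]
    all(abs(stats::coef(lf) - rev(p)) <= 3 * se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("select_best prefers fewer parameters on ties and explains rejections", {
  x <- 24:48
  lin <- growth_series("lin", x, 40 * x + 3500)
  best <- select_best(lin, candidates = c("linear", "polynomial"))
  expect_equal(best$family, "linear")

  # quartic with a planted downturn at the right edge is disqualified
  pq <- c(-0.01, 0.8, -15, 120, 4000)  # derivative at 48 is negative
  expect_lt(evaluate_poly(differentiate(pq), 48), 0)
  ser_q <- growth_series("q", x, evaluate_poly(pq, x) -
                           min(evaluate_poly(pq, x)) + 10)
  expect_error(select_best(ser_q, candidates = "polynomial", order = 4),
               "disqualified")
  tab <- attr(select_best(ser_q, candidates = c("linear", "polynomial"),
                          order = 4), "candidates")
  expect_match(tab$status[tab$family == "polynomial"], "decreasing")
})

test_that("potential_curve locates peaks exactly and on the hourly grid", {
  # concave derivative: vertex -b/(2a) inside the domain
  f4 <- structure(list(family = "polynomial", order = 3,
                       coefficients = poly_coeffs(dish_cubics$d4),
                       x = 24:48), class = "growth_fit")
  pc4 <- potential_curve(f4, domain = c(25, 48))
  d4 <- dish_derivatives_printed$d4
  vertex <- -d4[2] / (2 * d4[1])
  expect_equal(unname(pc4$peak["t"]), vertex, tolerance = 1e-9)
  expect_equal(unname(pc4$peak_hourly["t"]), 39)

  # convex derivative: maximum sits at an endpoint
  f1 <- structure(list(family = "polynomial", order = 3,
                       coefficients = poly_coeffs(dish_cubics$d1),
                       x = 24:48), class = "growth_fit")
  pc1 <- potential_curve(f1, domain = c(25, 48))
  expect_equal(unname(pc1$peak["t"]), 48)

  expect_error(potential_curve(f4, domain = c(30, 30)), "degenerate")
  flin <- structure(list(family = "polynomial",
                         coefficients = poly_coeffs(c(2, 1)), x = 1:5),
                    class = "growth_fit")
  expect_error(potential_curve(flin), "degree")
})

test_that("reports mirror the published table layouts", {
  sc <- make_scene(id = "rep1")
  ser <- assemble_series(as_measurable(render_stack(sc)), dish_id = "rep1")
  slist <- list(rep1 = ser)
  ft <- fit_report(slist)
  expect_setequal(names(ft), c("dish", "family", "r2", "expression"))
  expect_equal(nrow(ft), 5)
  dt <- derivative_report(slist)
  expect_equal(dt$family, "polynomial")
  expect_match(dt$derivative, "x\\^2")
  expect_true(dt$peak_t >= 24 && dt$peak_t <= 48)
})
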