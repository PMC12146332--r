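#' Polynomial coefficient vectors
#'
#' Coefficients in descending degree order, `c(c_k, ..., c_1, c_0)`.
#' Leading zeros are trimmed (the zero polynomial is kept as a single 0).
#'
#' @param coef numeric vector, descending powers.
#' @return object of class `poly_coeffs`.
#' @examples
#' differentiate(poly_coeffs(c(1, 0, -2, 5)))  # 3x^2 - 2
#' @export
poly_coeffs <- function(coef) {
  stopifnot(is.numeric(coef), length(coef) >= 1L)
  nz <- which(coef != 0)
  coef <- if (length(nz)) coef[nz[1]:length(coef)] else 0
  structure(as.numeric(coef), class = "poly_coeffs")
}

#' @export
print.poly_coeffs <- function(x, ...) {
  cat("<poly_coeffs>", format_poly(x), "\n")
  invisible(x)
}

poly_degree <- function(p) length(unclass(p)) - 1L

#' Differentiate a polynomial
#'
#' Power-rule first derivative; a degree-k input yields degree
#' `max(k - 1, 0)` (constants differentiate to the zero polynomial).
#'
#' @param p a [poly_coeffs()] (or bare descending coefficient vector).
#' @return a `poly_coeffs`.
#' @export
differentiate <- function(p) {
  p <- unclass(poly_coeffs(p))
  k <- length(p) - 1L
  if (k == 0L) return(poly_coeffs(0))
  poly_coeffs(p[seq_len(k)] * (k:1))
}

#' Evaluate a polynomial (Horner scheme)
#'
#' @param p a [poly_coeffs()] (or bare descending coefficient vector).
#' @param x numeric vector of evaluation points.
#' @return numeric vector of values.
#' @export
evaluate_poly <- function(p, x) {
  p <- unclass(poly_coeffs(p))
  out <- rep(p[1], length(x))
  for (c_i in p[-1]) out <- out * x + c_i
  out
}

#' Format a polynomial as an equation string
#'
#' @param p a [poly_coeffs()].
#' @param digits decimals in the printed coefficients (default 4, matching
#'   published fit tables).
#' @return character scalar like `"0.062x^3-4.9082x^2+147.9527x+2144.1588"`.
#' @export
format_poly <- function(p, digits = 4) {
  p <- unclass(poly_coeffs(p))
  k <- length(p) - 1L
  terms <- character(0)
  for (i in seq_along(p)) {
    d <- k - i + 1L
    c_i <- round(p[i], digits)
    if (c_i == 0 && length(p) > 1L) next
    mag <- format(abs(c_i), scientific = FALSE, trim = TRUE)
    x_part <- if (d == 0) "" else if (d == 1) "x" else paste0("x^", d)
    sign_part <- if (length(terms) == 0L) (if (c_i < 0) "-" else "")
                 else (if (c_i < 0) "-" else "+")
    terms <- c(terms, paste0(sign_part, mag, x_part))
  }
  if (length(terms) == 0L) "0" else paste(terms, collapse = "")
}

#' Coefficient of determination
#'
#' The primary form is explained-over-total sum of squares,
#' `sum((yhat - mean(y))^2) / sum((y - mean(y))^2)`. The familiar residual
#' form `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` is available via
#' `form`; the two coincide for linear least squares with intercept but can
#' diverge (the explained form may exceed 1) for fits that are not least
#' squares on the original scale, e.g. log-linearized exponentials.
#'
#' @param y observations (length >= 2, not constant).
#' @param yhat fitted values, same length.
#' @param form `"explained"` (default), `"residual"`, or `"both"` (named
#'   vector of the two).
#' @return numeric scalar, or named length-2 vector for `form = "both"`.
#' @export
r_squared <- function(y, yhat, form = c("explained", "residual", "both")) {
  form <- match.arg(form)
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("R^2 undefined: y is constant")
  expl <- sum((yhat - mean(y))^2) / sst
  resid <- 1 - sum((y - yhat)^2) / sst
  switch(form, explained = expl, residual = resid,
         both = c(explained = expl, residual = resid))
}

fit_families <- c("exponential", "linear", "logarithmic", "power",
                  "polynomial")

n_params_of <- function(family, order) {
  if (family == "polynomial") order + 1L else 2L
}

#' Fit one candidate equation family to a growth series
#'
#' Families and their estimators:
#' \describe{
#'   \item{linear}{`y = a x + b`, ordinary least squares.}
#'   \item{polynomial}{degree-`order` OLS on raw powers of x (default
#'     cubic).}
#'   \item{logarithmic}{`y = a ln(x) + b`, OLS of y on ln x (x > 0).}
#'   \item{exponential}{`y = a e^(b x)`, log-linearized: OLS of ln y on x
#'     (y > 0).}
#'   \item{power}{`y = a x^b`, log-linearized: OLS of ln y on ln x
#'     (x, y > 0).}
#' }
#' R-squared is always scored on the original y scale (both forms, see
#' [r_squared()]); log-linearized families are deterministic and
#' reproducible, at the price of an explained/total R-squared that is not
#' guaranteed to stay below 1.
#'
#' @param series a [growth_series()].
#' @param family one of `"exponential"`, `"linear"`, `"logarithmic"`,
#'   `"power"`, `"polynomial"`.
#' @param order polynomial degree (default 3, the reference choice).
#' @return object of class `growth_fit`: family, parameters, `coefficients`
#'   (a [poly_coeffs()] for linear/polynomial), fitted values, both
#'   R-squared forms (`r2` is the explained/total form), and the data.
#' @export
fit_family <- function(series, family = fit_families, order = 3) {
  family <- match.arg(family)
  stopifnot(inherits(series, "growth_series"))
  x <- series$time_h; y <- series$count
  np <- n_params_of(family, order)
  if (length(x) < np)
    stop(sprintf("%s fit needs at least as many points as parameters (%d < %d)",
                 family, length(x), np))
  if (family %in% c("logarithmic", "power") && any(x <= 0))
    stop(family, " fit requires all x > 0")
  if (family %in% c("exponential", "power") && any(y <= 0))
    stop(family, " fit (log-linearized) requires all y > 0")

  params <- coefs <- NULL
  yhat <- switch(family,
    linear = {
      f <- stats::lm.fit(cbind(x = x, 1), y)
      params <- c(a = unname(f$coefficients[1]), b = unname(f$coefficients[2]))
      coefs <- poly_coeffs(unname(f$coefficients))
      params["a"] * x + params["b"]
    },
    polynomial = {
      X <- outer(x, order:0, `^`)
      f <- stats::lm.fit(X, y)
      coefs <- poly_coeffs(unname(f$coefficients))
      params <- stats::setNames(unname(f$coefficients),
                                paste0("c", order:0))
      evaluate_poly(coefs, x)
    },
    logarithmic = {
      f <- stats::lm.fit(cbind(lx = log(x), 1), y)
      params <- c(a = unname(f$coefficients[1]), b = unname(f$coefficients[2]))
      params["a"] * log(x) + params["b"]
    },
    exponential = {
      f <- stats::lm.fit(cbind(x = x, 1), log(y))
      params <- c(a = exp(unname(f$coefficients[2])),
                  b = unname(f$coefficients[1]))
      params["a"] * exp(params["b"] * x)
    },
    power = {
      f <- stats::lm.fit(cbind(lx = log(x), 1), log(y))
      params <- c(a = exp(unname(f$coefficients[2])),
                  b = unname(f$coefficients[1]))
      params["a"] * x^params["b"]
    })
  r2 <- r_squared(y, yhat, form = "both")
  structure(list(family = family, order = if (family == "polynomial") order
                   else NULL,
                 parameters = params, coefficients = coefs,
                 fitted = unname(yhat), x = x, y = y,
                 r2 = unname(r2["explained"]),
                 r2_residual = unname(r2["residual"]),
                 n_params = np,
                 dish_id = attr(series, "dish_id")),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> dish %s: %s  R^2 = %.4f (residual %.4f)\n",
              x$dish_id %||% "?", fit_equation(x), x$r2, x$r2_residual))
  invisible(x)
}

#' Human-readable equation of a fitted model
#'
#' @param fit a `growth_fit`.
#' @param digits printed decimals (default 4).
#' @return character scalar, e.g. `"3886e^(0.0099x)"`.
#' @export
fit_equation <- function(fit, digits = 4) {
  p <- round(fit$parameters, digits)
  switch(fit$family,
    linear = format_poly(fit$coefficients, digits),
    polynomial = format_poly(fit$coefficients, digits),
    exponential = sprintf("%se^(%sx)", p["a"], p["b"]),
    logarithmic = sprintf("%sln(x)%s%s", p["a"],
                          if (p["b"] < 0) "" else "+", p["b"]),
    power = sprintf("%sx^%s", p["a"], p["b"]))
}

# analytic derivative of the fitted mean curve at x
fit_derivative_at <- function(fit, x) {
  p <- fit$parameters
  switch(fit$family,
    linear = rep(unname(p["a"]), length(x)),
    polynomial = evaluate_poly(differentiate(fit$coefficients), x),
    exponential = unname(p["a"] * p["b"]) * exp(unname(p["b"]) * x),
    logarithmic = unname(p["a"]) / x,
    power = unname(p["a"] * p["b"]) * x^(unname(p["b"]) - 1))
}

#' Fit all candidate families and select the best by R-squared
#'
#' Every requested family is fitted; candidates whose fitted curve is
#' decreasing at the right edge of the data (`d/dx fitted < 0` at
#' `max(time)`) are disqualified when `monotone_check` is on — germinating
#' seeds do not shrink on aggregate, and this rule is what excludes
#' quartic-and-higher polynomials whose tails turn downward. Among the
#' survivors the highest explained/total R-squared wins; when two
#' candidates agree within `1e-12`, the one with fewer parameters is
#' preferred.
#'
#' @param series a [growth_series()].
#' @param candidates character vector of families ([fit_family()]); default
#'   all five.
#' @param order polynomial degree for the `"polynomial"` candidate.
#' @param monotone_check disqualify curves decreasing at the right edge
#'   (default `TRUE`).
#' @return the winning `growth_fit`, with attribute `"candidates"` — a
#'   data.frame of every family's R-squared and status.
#' @export
select_best <- function(series, candidates = fit_families, order = 3,
                        monotone_check = TRUE) {
  stopifnot(length(candidates) >= 1L)
  t_max <- max(series$time_h)
  rows <- list(); fits <- list()
  for (fam in candidates) {
    fit <- tryCatch(fit_family(series, fam, order = order),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[fam]] <- data.frame(family = fam, r2 = NA_real_,
                                r2_residual = NA_real_, n_params = NA_integer_,
                                status = paste("unfittable:",
                                               conditionMessage(fit)),
                                stringsAsFactors = FALSE)
      next
    }
    status <- "ok"
    if (monotone_check && fit_derivative_at(fit, t_max) < 0)
      status <- "disqualified: fitted curve decreasing at t_max"
    rows[[fam]] <- data.frame(family = fam, r2 = fit$r2,
                              r2_residual = fit$r2_residual,
                              n_params = fit$n_params, status = status,
                              stringsAsFactors = FALSE)
    if (status == "ok") fits[[fam]] <- fit
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  if (length(fits) == 0L)
    stop("all candidates disqualified or unfittable:\n",
         paste(sprintf("  %s: %s", tab$family, tab$status), collapse = "\n"))
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  nps <- vapply(fits, `[[`, numeric(1), "n_params")
  best_r2 <- max(r2s)
  tied <- which(r2s >= best_r2 - 1e-12)
  winner <- tied[which.min(nps[tied])]
  out <- fits[[winner]]
  attr(out, "candidates") <- tab
  out
}

#' Germination-potential curve of a polynomial fit
#'
#' The first derivative of the fitted polynomial is the rate of
#' morphological change — the germination potential. Its maximum over the
#' closed time domain is located exactly: candidate points are the domain
#' endpoints and the real critical points of the derivative (for a concave
#' quadratic derivative, the vertex `-b/(2a)` clipped to the domain). A
#' grid-argmax peak over whole hours is reported alongside, since rate
#' peaks are often read off hourly-sampled curves.
#'
#' @param fit a `growth_fit` with `family = "polynomial"` (or `"linear"`)
#'   of degree >= 2, or a bare [poly_coeffs()] of the growth curve.
#' @param domain `c(t_min, t_max)` hours; defaults to the fitted data range.
#' @return object of class `potential_curve`: `derivative`
#'   ([poly_coeffs()]), `domain`, `peak` (`c(t, value)`, exact) and
#'   `peak_hourly` (argmax over whole hours in the domain).
#' @export
potential_curve <- function(fit, domain = NULL) {
  if (inherits(fit, "growth_fit")) {
    if (is.null(fit$coefficients))
      stop("potential_curve requires a polynomial (or linear) fit")
    p <- fit$coefficients
    domain <- domain %||% range(fit$x)
  } else {
    p <- poly_coeffs(fit)
    if (is.null(domain)) stop("domain required when passing raw coefficients")
  }
  if (poly_degree(p) < 2L)
    stop("growth polynomial must have degree >= 2 for a rate curve")
  if (length(domain) != 2L || domain[1] >= domain[2])
    stop("degenerate domain: need t_min < t_max")
  d <- differentiate(p)
  cand <- domain
  dd <- differentiate(d)
  if (poly_degree(dd) >= 1L || unclass(dd)[1] != 0) {
    rts <- polyroot(rev(unclass(dd)))
    re <- Re(rts)[abs(Im(rts)) < 1e-8]
    cand <- c(cand, re[re > domain[1] & re < domain[2]])
  }
  vals <- evaluate_poly(d, cand)
  i <- which.max(vals)
  hours <- seq(ceiling(domain[1]), floor(domain[2]))
  hv <- evaluate_poly(d, hours)
  j <- which.max(hv)
  structure(list(derivative = d, domain = as.numeric(domain),
                 peak = c(t = cand[i], value = vals[i]),
                 peak_hourly = c(t = hours[j], value = hv[j])),
            class = "potential_curve")
}

#' @export
print.potential_curve <- function(x, ...) {
  cat(sprintf(
    "<potential_curve> d/dt = %s on [%g, %g] h\n  peak %.4f px/h at t = %.2f h (hourly grid: t = %g h)\n",
    format_poly(x$derivative), x$domain[1], x$domain[2],
    x$peak["value"], x$peak["t"], x$peak_hourly["t"]))
  invisible(x)
}

#' Tabulate fits for several dishes
#'
#' `fit_report` mirrors a fit-comparison table (dish, family, R-squared,
#' expression); `derivative_report` mirrors a growth-equation /
#' derivative-equation table for the winning polynomial of each dish.
#'
#' @param series_list named list of [growth_series()] objects.
#' @param candidates,order passed to [fit_family()] / [select_best()].
#' @return a data.frame.
#' @export
fit_report <- function(series_list, candidates = fit_families, order = 3) {
  do.call(rbind, lapply(names(series_list), function(id) {
    do.call(rbind, lapply(candidates, function(fam) {
      fit <- tryCatch(fit_family(series_list[[id]], fam, order = order),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      data.frame(dish = id, family = fam, r2 = round(fit$r2, 2),
                 expression = fit_equation(fit), stringsAsFactors = FALSE)
    }))
  }))
}

#' @rdname fit_report
#' @param monotone_check passed to [select_best()].
#' @export
derivative_report <- function(series_list, candidates = fit_families,
                              order = 3, monotone_check = TRUE) {
  do.call(rbind, lapply(names(series_list), function(id) {
    best <- select_best(series_list[[id]], candidates, order = order,
                        monotone_check = monotone_check)
    pc <- if (!is.null(best$coefficients) &&
              poly_degree(best$coefficients) >= 2L)
      potential_curve(best) else NULL
    data.frame(dish = id, family = best$family,
               equation = fit_equation(best), r2 = round(best$r2, 2),
               derivative = if (is.null(pc)) NA_character_
                            else format_poly(pc$derivative),
               peak_t = if (is.null(pc)) NA_real_ else unname(pc$peak["t"]),
               peak_t_hourly = if (is.null(pc)) NA_real_
                               else unname(pc$peak_hourly["t"]),
               stringsAsFactors = FALSE)
  }))
}
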