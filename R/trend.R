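#' Fit a developmental trend
#'
#' Least-squares fits of per-animal values against age: a straight line, a
#' four-parameter logistic (sigmoid)
#' \deqn{y = bottom + (top - bottom) / (1 + exp(-k (x - v50)))}
#' or a fourth-order polynomial. The sigmoid is fitted with
#' Levenberg-Marquardt least squares from a grid of starting values
#' (multi-start) to avoid local minima. \eqn{r^2 = 1 - SS_{res}/SS_{tot}};
#' for constant responses \eqn{r^2} is 0 by convention and the fit is flat.
#'
#' @param x ages in postnatal days.
#' @param y per-animal values.
#' @param model \code{"linear"}, \code{"sigmoid"} or \code{"poly4"}.
#' @return list with \code{model}, named \code{coefficients}, \code{r2},
#'   \code{fitted} values and a \code{predict} function of age.
#' @export
fit_trend <- function(x, y, model = c("linear", "sigmoid", "poly4")) {
  model <- match.arg(model)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n_par <- switch(model, linear = 2L, sigmoid = 4L, poly4 = 5L)
  if (length(x) < n_par + 1L)
    stop("need at least ", n_par + 1L, " points for a ", model, " fit")
  ss_tot <- sum((y - mean(y))^2)

  if (ss_tot == 0) {
    pred <- function(age) rep(mean(y), length(age))
    co <- switch(model,
                 linear = c(intercept = mean(y), slope = 0),
                 sigmoid = c(bottom = mean(y), top = mean(y), k = 0,
                             v50 = mean(x)),
                 poly4 = c(b0 = mean(y), b1 = 0, b2 = 0, b3 = 0, b4 = 0))
    return(list(model = model, coefficients = co, r2 = 0,
                fitted = pred(x), predict = pred))
  }

  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    co <- c(intercept = unname(stats::coef(fit)[1L]),
            slope = unname(stats::coef(fit)[2L]))
    pred <- function(age) co[["intercept"]] + co[["slope"]] * age
  } else if (model == "poly4") {
    fit <- stats::lm(y ~ x + I(x^2) + I(x^3) + I(x^4))
    b <- unname(stats::coef(fit))
    co <- stats::setNames(b, paste0("b", 0:4))
    pred <- function(age) b[1L] + b[2L] * age + b[3L] * age^2 +
      b[4L] * age^3 + b[5L] * age^4
  } else {
    sig <- function(age, p)
      p[1L] + (p[2L] - p[1L]) / (1 + exp(-p[3L] * (age - p[4L])))
    best <- NULL; best_ss <- Inf
    starts <- expand.grid(k = c(0.5, 1, 2, 4, -1),
                          v50 = stats::quantile(x, c(0.25, 0.5, 0.75),
                                                names = FALSE))
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + exp(-k * (x - v50))),
          start = list(bottom = min(y), top = max(y),
                       k = starts$k[i], v50 = starts$v50[i]),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ss <- sum(stats::residuals(fit)^2)
      if (ss < best_ss) { best <- fit; best_ss <- ss }
    }
    if (is.null(best))
      stop("sigmoid fit did not converge from any starting value")
    p <- unname(stats::coef(best)[c("bottom", "top", "k", "v50")])
    co <- stats::setNames(p, c("bottom", "top", "k", "v50"))
    pred <- function(age) sig(age, p)
  }
  fitted <- pred(x)
  r2 <- 1 - sum((y - fitted)^2) / ss_tot
  list(model = model, coefficients = co, r2 = r2, fitted = fitted,
       predict = pred)
}
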