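# Prediction-equation machinery: ordinary least squares wrapped in a
# compact model object, and SAS-style stepwise selection ranked by
# (significance, R^2, RMSE).

#' Fit a prediction equation by ordinary least squares
#'
#' Least-squares fit of a response on a table of predictors, reported the
#' way feed energy prediction equations are tabulated: intercept,
#' coefficients, `R^2 = 1 - SSE/SST`, `RMSE = sqrt(SSE / (n - k - 1))`
#' (the residual standard error), and the overall-F p-value.
#'
#' @param y numeric response vector, or a formula (with `X` then the
#'   data frame it refers to).
#' @param X data frame of predictors; `NULL` or zero columns fits the
#'   intercept-only model (R^2 = 0, RMSE = sample SD of `y`, p `NA`).
#' @param response name used for the response in printing.
#' @return Object of class `energy_model`: list with `response`,
#'   `predictors`, `intercept`, `coefficients`, `r2`, `rmse`, `p_value`,
#'   `n`, and the underlying `lm` fit.
#' @examples
#' d <- data.frame(adf = c(4.3, 6.1, 4.8, 4.7, 4.6), ne = c(9.2, 7.9, 8.9, 9.7, 11.6))
#' m <- ols_fit(d$ne, d["adf"], response = "ne")
#' coef(m)
#' @export
ols_fit <- function(y, X = NULL, response = "y") {
  if (inherits(y, "formula")) {
    mf <- stats::model.frame(y, data = X)
    response <- names(mf)[1]
    X <- mf[, -1, drop = FALSE]
    y <- mf[[1]]
  }
  if (!is.numeric(y)) stop("'y' must be numeric")
  n <- length(y)
  k <- if (is.null(X)) 0L else ncol(X)
  if (n <= k + 1) stop("need n > k + 1 observations to fit ", k, " predictor(s)")

  if (k == 0) {
    fit <- stats::lm(y ~ 1)
    rmse <- stats::sd(y)
    mdl <- list(response = response, predictors = character(0),
                intercept = mean(y), coefficients = numeric(0),
                r2 = 0, rmse = rmse, p_value = NA_real_, n = n, fit = fit)
    class(mdl) <- "energy_model"
    return(mdl)
  }

  d <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(stats::reformulate(colnames(X), ".y"), data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear predictors dropped by least squares: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  s <- suppressWarnings(summary(fit)) # silence the perfect-fit notice
  fstat <- s$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  mdl <- list(
    response = response,
    predictors = colnames(X),
    intercept = unname(cf[1]),
    coefficients = cf[-1],
    r2 = s$r.squared,
    rmse = s$sigma,
    p_value = unname(p),
    n = n,
    fit = fit
  )
  class(mdl) <- "energy_model"
  mdl
}

#' Render a model as an equation string
#'
#' @param x an `energy_model`.
#' @param digits coefficient digits.
#' @return Character scalar like `"ne = 4.35 - 3.92 adf + 1.24 tdf"`.
#' @export
format_equation <- function(x, digits = 2) {
  stopifnot(inherits(x, "energy_model"))
  rhs <- formatC(x$intercept, format = "f", digits = digits)
  for (i in seq_along(x$coefficients)) {
    b <- x$coefficients[i]
    rhs <- paste0(rhs, if (b < 0) " - " else " + ",
                  formatC(abs(b), format = "f", digits = digits), " ",
                  names(x$coefficients)[i])
  }
  paste(x$response, "=", rhs)
}

#' @export
print.energy_model <- function(x, ...) {
  cat(format_equation(x), "\n")
  cat(sprintf("  n = %d, R2 = %.3f, RMSE = %.3f, p = %s\n",
              x$n, x$r2, x$rmse,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' @export
summary.energy_model <- function(object, ...) {
  print(object)
  if (length(object$predictors)) print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.energy_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
predict.energy_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$fit))
  if (length(object$predictors) == 0) {
    return(rep(object$intercept, NROW(newdata)))
  }
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss)) stop("newdata lacks predictor(s): ", paste(miss, collapse = ", "))
  as.vector(object$intercept +
              as.matrix(newdata[, object$predictors, drop = FALSE]) %*%
              object$coefficients)
}

#' @export
residuals.energy_model <- function(object, ...) stats::residuals(object$fit)

# partial-F p-value for adding `var` to the model with predictors `sel`
.partial_f_p <- function(d, response, sel, var) {
  base <- stats::lm(stats::reformulate(if (length(sel)) sel else "1", response),
                    data = d)
  full <- stats::lm(stats::reformulate(c(sel, var), response), data = d)
  p <- tryCatch(stats::anova(base, full)[2, "Pr(>F)"],
                error = function(e) NA_real_)
  if (is.null(p) || !is.finite(p)) NA_real_ else p
}

#' Stepwise construction of a prediction equation
#'
#' SAS-style stepwise selection: at each step the candidate with the
#' smallest partial-F p-value enters if below `slentry`; after each
#' entry, any retained term whose partial p-value exceeds `slstay`
#' leaves. Selection stops when no term can enter or leave, when a step
#' would revisit an earlier model (the classical stepwise cycling guard),
#' or when `max_terms` is reached. The procedure is deterministic given
#' the candidate order; partial-F ties are broken by candidate list
#' order.
#'
#' All models visited along the path are returned, ranked by
#' (overall-F significance at 0.05, R^2 descending, RMSE ascending); the
#' top-ranked model is the selected prediction equation.
#'
#' @param data data frame holding the response and candidates.
#' @param response response column name.
#' @param candidates candidate predictor names, in priority order.
#' @param slentry significance level a candidate needs to enter.
#' @param slstay significance level a retained term needs to stay.
#' @param max_terms maximum number of terms in the model.
#' @return Object of class `stepwise_selection`: list with `best` (an
#'   [ols_fit()] model), `models` (all visited models, ranked), `path`
#'   (data frame of enter/remove actions with p-values), and the
#'   configuration.
#' @examples
#' path <- system.file("extdata", "barley10.csv", package = "sowcal")
#' comp <- read_composition_table(path, basis = "dm")
#' comp$ne <- c(9.22, 7.85, 8.88, 9.66, 11.61, 8.49, 11.18, 9.95, 10.95, 11.85)
#' sel <- stepwise_select(comp, "ne", c("cp", "ndf", "adf", "ash", "ee",
#'                                      "starch", "idf", "sdf", "tdf"))
#' sel$best
#' @export
stepwise_select <- function(data, response, candidates,
                            slentry = 0.25, slstay = 0.15,
                            max_terms = Inf) {
  if (!(slentry > 0 && slentry <= 1)) stop("'slentry' must lie in (0, 1]")
  if (!(slstay > 0 && slstay <= 1)) stop("'slstay' must lie in (0, 1]")
  d <- as.data.frame(data)
  miss <- setdiff(c(response, candidates), names(d))
  if (length(miss)) stop("columns not found: ", paste(miss, collapse = ", "))
  n <- nrow(d)
  if (n <= 3) stop("need more than 3 observations for stepwise selection")

  sel <- character(0)
  seen <- ""
  path <- data.frame(action = character(0), variable = character(0),
                     p = numeric(0), stringsAsFactors = FALSE)
  fit_current <- function() {
    ols_fit(d[[response]], if (length(sel)) d[, sel, drop = FALSE] else NULL,
            response = response)
  }
  models <- list()
  state_key <- function(s) paste(sort(s), collapse = ",")

  repeat {
    changed <- FALSE
    # entry step: needs residual df after the addition
    rem <- setdiff(candidates, sel)
    if (length(rem) && length(sel) < max_terms && n > length(sel) + 2) {
      ps <- vapply(rem, function(v) .partial_f_p(d, response, sel, v),
                   numeric(1))
      ps <- ps[is.finite(ps)]
      if (length(ps) && min(ps) < slentry) {
        v <- names(ps)[which.min(ps)]
        key <- state_key(c(sel, v))
        if (!key %in% seen) {
          sel <- c(sel, v)
          seen <- c(seen, key)
          path <- rbind(path, data.frame(action = "enter", variable = v,
                                         p = min(ps)))
          models[[length(models) + 1]] <- fit_current()
          changed <- TRUE
        }
      }
    }
    # removal step(s)
    repeat {
      if (!length(sel)) break
      m <- stats::lm(stats::reformulate(sel, response), data = d)
      pt <- suppressWarnings(summary(m))$coefficients[-1, 4]
      names(pt) <- sel
      pt[!is.finite(pt)] <- 0 # exact fits: terms are perfectly significant
      if (max(pt) <= slstay) break
      v <- names(pt)[which.max(pt)]
      key <- state_key(setdiff(sel, v))
      if (key %in% seen) break
      sel <- setdiff(sel, v)
      seen <- c(seen, key)
      path <- rbind(path, data.frame(action = "remove", variable = v,
                                     p = max(pt)))
      models[[length(models) + 1]] <- fit_current()
      changed <- TRUE
    }
    if (!changed) break
  }

  if (!length(models)) {
    warning("no candidate met the entry criterion; returning intercept-only model",
            call. = FALSE)
    models <- list(fit_current())
  }
  sig <- vapply(models, function(m) !is.na(m$p_value) && m$p_value < 0.05,
                logical(1))
  r2 <- vapply(models, `[[`, numeric(1), "r2")
  rmse <- vapply(models, `[[`, numeric(1), "rmse")
  ord <- order(!sig, -r2, rmse)
  models <- models[ord]

  structure(list(best = models[[1]], models = models, path = path,
                 response = response, candidates = candidates,
                 slentry = slentry, slstay = slstay, n = n),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat(sprintf("Stepwise selection for '%s' (n = %d, entry %.2f / stay %.2f)\n",
              x$response, x$n, x$slentry, x$slstay))
  if (nrow(x$path)) {
    for (i in seq_len(nrow(x$path))) {
      cat(sprintf("  %s %-12s p = %.4f\n", x$path$action[i],
                  x$path$variable[i], x$path$p[i]))
    }
  } else {
    cat("  (no variable entered)\n")
  }
  cat("Selected equation:\n  ")
  print(x$best)
  invisible(x)
}

#' Descriptive statistics
#'
#' Mean, sample standard deviation (n-1), coefficient of variation
#' (`100 x sd / mean`), minimum, and maximum.
#'
#' @param values numeric vector.
#' @return Named numeric vector `mean`, `sd`, `cv`, `min`, `max`, `n`.
#' @export
describe <- function(values) {
  if (!is.numeric(values) || !length(values)) stop("'values' must be non-empty numeric")
  s <- if (length(values) > 1) stats::sd(values) else NA_real_
  c(mean = mean(values), sd = s,
    cv = if (is.na(s) || mean(values) == 0) NA_real_ else 100 * s / mean(values),
    min = min(values), max = max(values), n = length(values))
}
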