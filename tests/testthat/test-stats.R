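# brute-force two-variable Pearson r, the oracle for pearson_matrix()
brute_r <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("pearson_matrix equals the brute-force oracle on all pairs", {
  tab <- barley_table()
  vars <- c("cp", "ndf", "adf", "ash", "ee", "starch", "idf", "sdf", "tdf",
            "de", "me", "ne")
  cm <- pearson_matrix(tab, variables = vars)
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      expect_equal(cm$r[i, j], brute_r(tab[[vars[i]]], tab[[vars[j]]]),
                   tolerance = 1e-12)
    }
  }
  # two-sided p from the t transform agrees with cor.test
  ct <- stats::cor.test(tab$adf, tab$ne)
  expect_equal(cm$p["adf", "ne"], ct$p.value, tolerance = 1e-9)
  expect_true(isSymmetric(cm$r))
  expect_equal(diag(cm$r), rep(1, length(vars)), ignore_attr = TRUE)
})

test_that("fibre-block correlations match the reference analysis", {
  tab <- barley_table()
  cm <- pearson_matrix(tab, variables = c("ndf", "adf", "hemicellulose",
                                          "idf", "sdf", "tdf"))
  expect_equal(cm$r["idf", "tdf"], 0.97, tolerance = 0.005)
  expect_equal(cm$r["adf", "idf"], 0.94, tolerance = 0.005)
  expect_equal(cm$r["hemicellulose", "ndf"], 0.99, tolerance = 0.005)
  expect_equal(cm$r["adf", "tdf"], 0.92, tolerance = 0.005)
  s <- correlation_stars(cm)
  expect_equal(s["idf", "tdf"], "**")
})

test_that("degenerate correlation inputs are reported, not computed", {
  d <- data.frame(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2), c = c(4, 3, 2, 2))
  expect_warning(cm <- pearson_matrix(d), "zero-variance")
  expect_true(all(is.na(cm$r["b", ])))
  expect_false(is.na(cm$r["a", "c"]))
  expect_error(pearson_matrix(d[1:2, ]), "at least 3")
  d$a[1] <- NA
  expect_error(suppressWarnings(pearson_matrix(d)), "missing values")
})

test_that("ols_fit matches the normal-equations closed form", {
  set.seed(7)
  n <- 12
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- 1.5 + 2 * X$x1 - 0.7 * X$x2 + rnorm(n, 0, 0.3)
  m <- ols_fit(y, X)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(unname(coef(m)), as.vector(beta), tolerance = 1e-9)
  sse <- sum((y - Xm %*% beta)^2)
  expect_equal(m$r2, 1 - sse / sum((y - mean(y))^2), tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(sse / (n - 3)), tolerance = 1e-9)

  # exact linear response: perfect fit
  y2 <- 2 + 3 * X$x1
  m2 <- ols_fit(y2, X["x1"])
  expect_equal(m2$r2, 1, tolerance = 1e-12)
  expect_equal(m2$rmse, 0, tolerance = 1e-9)

  # intercept-only: R2 = 0, RMSE = sample SD
  m0 <- ols_fit(y, NULL)
  expect_equal(m0$r2, 0)
  expect_equal(m0$rmse, sd(y), tolerance = 1e-12)
  expect_true(is.na(m0$p_value))

  # collinear predictors are a structured error naming the column
  X$x3 <- X$x1 + X$x2
  expect_error(ols_fit(y, X), "collinear.*x3")
  expect_error(ols_fit(y[1:3], X[1:3, ]), "n > k \\+ 1")
})

test_that("energy_model methods behave like a fitted model object", {
  tab <- barley_table()
  m <- ols_fit(tab$ne, tab[, c("adf", "tdf")], response = "ne")
  expect_s3_class(m, "energy_model")
  expect_named(coef(m), c("(Intercept)", "adf", "tdf"))
  expect_equal(predict(m, tab), unname(fitted(m$fit)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(length(residuals(m)), 10)
  expect_match(format_equation(m), "ne = 4.33 - 3.92 adf \\+ 1.24 tdf")
  expect_error(predict(m, tab[, "adf", drop = FALSE]), "lacks predictor")
})

test_that("prediction equation for NE matches the reference fit statistics", {
  tab <- barley_table()
  m <- ols_fit(tab$ne, tab[, c("adf", "tdf")], response = "ne")
  expect_equal(m$r2, 0.66, tolerance = 0.01)
  expect_equal(m$rmse, 0.90, tolerance = 0.01)
  expect_equal(m$intercept, 4.35, tolerance = 0.02)
  expect_equal(unname(m$coefficients["adf"]), -3.92, tolerance = 0.005)
  expect_equal(unname(m$coefficients["tdf"]), 1.24, tolerance = 0.005)
  expect_equal(m$n, 10)
})

test_that("stepwise selection reproduces the published equation on the fixtures", {
  tab <- barley_table()
  sel <- stepwise_select(tab, "ne", c("cp", "ndf", "adf", "ash", "ee",
                                      "starch", "idf", "sdf", "tdf"))
  expect_setequal(sel$best$predictors, c("adf", "tdf"))
  expect_equal(sel$path$variable[1:2], c("adf", "tdf"))
  expect_equal(sel$best$r2, 0.66, tolerance = 0.01)
})

test_that("stepwise limits behave like the SAS procedure", {
  tab <- barley_table()
  cands <- c("cp", "adf", "ash", "tdf")
  # slentry near zero: nothing enters, intercept-only with a warning
  expect_warning(
    s0 <- stepwise_select(tab, "ne", cands, slentry = 1e-9, slstay = 1e-9),
    "no candidate")
  expect_length(s0$best$predictors, 0)

  # slentry = slstay = 1: all candidates enter, in partial-F order
  s1 <- stepwise_select(tab, "ne", cands, slentry = 1, slstay = 1)
  entered <- s1$path$variable[s1$path$action == "enter"]
  expect_setequal(entered, cands)
  # the first entrant is the smallest single-predictor partial-F p
  p1 <- vapply(cands, function(v) {
    summary(lm(stats::reformulate(v, "ne"), data = tab))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(entered[1], names(which.min(p1)))

  # a candidate collinear with the response is selected with R2 = 1
  tab$clone <- 2 * tab$ne + 1
  sc <- stepwise_select(tab, "ne", c("clone", "cp"))
  expect_equal(sc$best$predictors, "clone")
  expect_equal(sc$best$r2, 1, tolerance = 1e-9)

  expect_error(stepwise_select(tab, "ne", "nope"), "not found")
  expect_error(stepwise_select(tab[1:3, ], "ne", "cp"), "more than 3")
})

test_that("stepwise first-entry decision matches the brute-force rule", {
  # under a pure-noise response, entry happens iff the smallest
  # single-candidate partial-F p is below slentry, and the same variable
  # is chosen
  set.seed(99)
  ranges <- list(cp = c(9.29, 14.26), adf = c(3.65, 6.07),
                 ash = c(2.10, 3.62), starch = c(44.01, 57.71))
  n_enter <- 0
  reps <- 120
  for (i in seq_len(reps)) {
    d <- as.data.frame(lapply(ranges, function(rg) runif(10, rg[1], rg[2])))
    d$y <- rnorm(10)
    p <- vapply(names(ranges), function(v) {
      summary(lm(stats::reformulate(v, "y"), data = d))$coefficients[2, 4]
    }, numeric(1))
    s <- suppressWarnings(stepwise_select(d, "y", names(ranges),
                                          slentry = 0.15, slstay = 0.15))
    if (min(p) < 0.15) {
      n_enter <- n_enter + 1
      expect_equal(s$path$variable[1], names(which.min(p)))
    } else {
      expect_equal(nrow(s$path), 0)
    }
  }
  # multiplicity makes the family-wise entry rate land well above the
  # per-test 0.15 but below 1 - (1 - 0.15)^4 under independence
  expect_gt(n_enter / reps, 0.15)
  expect_lt(n_enter / reps, 0.65)
})

test_that("descriptive statistics use the sample SD convention", {
  expect_equal(describe(rep(5, 4))[["sd"]], 0)
  expect_equal(describe(rep(5, 4))[["cv"]], 0)
  expect_true(is.na(describe(3)[["sd"]]))
  d <- describe(c(2, 4, 6))
  expect_equal(d[["mean"]], 4)
  expect_equal(d[["sd"]], 2)
  expect_equal(d[["cv"]], 50)
  be <- read_fixture("barley_energy.csv")
  expect_equal(describe(be$me_de_pct)[["mean"]], 92.40, tolerance = 0.005)
  expect_equal(describe(be$ne_me_pct)[["mean"]], 70.4, tolerance = 0.05)
})
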