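test_that("residualization leaves orthogonal variables centred and zeroes exact fits", {
  set.seed(1)
  n <- 40
  tab <- data.frame(sex = rep(c(0, 1), n / 2), age_5mo = rnorm(n, 152, 7),
                    likelihood = rbinom(n, 1, 0.5))
  # variable orthogonal (in sample) to all covariates: residualize only centres it
  X <- stats::model.matrix(~ sex + age_5mo + likelihood, tab)
  v <- rnorm(n)
  v_orth <- stats::lm.fit(X, v)$residuals + 5          # orthogonal + offset
  tab$v1 <- v_orth
  tab$v2 <- 2 * tab$sex - 0.5 * tab$age_5mo + 3        # exact covariate function
  out <- residualize(tab, c("v1", "v2"))
  expect_equal(out$v1, v_orth - mean(v_orth), tolerance = 1e-10)
  expect_equal(out$v2, rep(0, n), tolerance = 1e-10)
  # planted partial correlation survives residualization
  z <- rnorm(n)
  tab$v3 <- 0.8 * tab$age_5mo + z
  tab$y <- 2 * z + rnorm(n, 0, 0.3)
  out2 <- residualize(tab, c("v3", "y"))
  expect_gt(cor(out2$v3, out2$y), 0.8)
  # rank-deficient covariates error
  tab$dup <- tab$sex
  expect_error(residualize(tab, "v1", covariates = c("sex", "dup")),
               "rank-deficient")
})

test_that("subset enumeration is exhaustive (2^p, empty and full included)", {
  subs <- infantfc:::enumerate_subsets(3)
  expect_length(subs, 8)
  expect_true(any(vapply(subs, length, 1L) == 0))
  expect_true(any(vapply(subs, function(s) identical(s, 1:3), TRUE)))
  # matches an independent enumeration via combn
  canon <- sort(vapply(subs, function(s) paste(s, collapse = ","), ""))
  brute <- sort(unlist(lapply(0:3, function(k)
    if (k == 0) "" else apply(utils::combn(3, k), 2, paste, collapse = ","))))
  expect_equal(canon, brute)
  expect_length(infantfc:::enumerate_subsets(12), 4096)
})

test_that("selection finds a planted strong predictor among 12 candidates", {
  hits <- 0; freqs <- integer(0)
  for (r in 1:5) {
    set.seed(100 + r)
    n <- 60
    X <- matrix(rnorm(n * 12), n, dimnames = list(NULL, modeling_variable_names()))
    y <- X[, "theta_nonsocial_far"] + rnorm(n)  # standardized beta = 1
    tab <- cbind(as.data.frame(X), ados_css_total = y)
    sel <- cv_subset_selection(tab, folds = 10, repeats = 1, seed = r)
    hits <- hits + ("theta_nonsocial_far" %in% sel$selected)
    freqs <- c(freqs, sel$variable_frequency[["theta_nonsocial_far"]])
    expect_equal(sel$n_subsets, 4096)
    expect_length(sel$selected, 5)
  }
  expect_equal(hits, 5)
  expect_gte(stats::median(freqs), 95)
})

test_that("selection is deterministic given its seed and errors on bad input", {
  set.seed(2)
  tab <- data.frame(matrix(rnorm(20 * 3), 20))
  names(tab) <- c("a", "b", "c")
  tab$ados_css_total <- rnorm(20)
  s1 <- cv_subset_selection(tab, candidates = c("a", "b", "c"), folds = 5,
                            repeats = 2, seed = 11)
  s2 <- cv_subset_selection(tab, candidates = c("a", "b", "c"), folds = 5,
                            repeats = 2, seed = 11)
  expect_identical(s1$mean_cv_r2, s2$mean_cv_r2)
  expect_identical(s1$selected, s2$selected)
  expect_error(cv_subset_selection(tab[1:3, ], candidates = c("a", "b"),
                                   folds = 5), "complete cases")
  expect_error(cv_subset_selection(tab, candidates = character(0)), "empty")
})

test_that("main-effect fit recovers exact fits and the worked eta^2 formula", {
  set.seed(3)
  n <- 50
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), sex = rbinom(n, 1, 0.5),
                    likelihood = rbinom(n, 1, 0.5), age_5mo = rnorm(n, 152, 7))
  tab$ados_css_total <- 2 + tab$x1 - 0.5 * tab$x2
  # base R warns about the deliberately perfect fit
  fit <- suppressWarnings(fit_main_model(tab, predictors = c("x1", "x2")))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$ss_residual, 0, tolerance = 1e-20)
  expect_equal(unname(fit$coefficients[c("x1", "x2")]), c(1, -0.5))
  # partial eta^2 agrees with the SS identity on noisy data
  tab$ados_css_total <- tab$ados_css_total + rnorm(n)
  fit2 <- fit_main_model(tab, predictors = c("x1", "x2"))
  a <- fit2$anova
  for (term in fit2$terms) {
    expect_equal(fit2$partial_eta2[[term]],
                 a$sum_sq[a$term == term] /
                   (a$sum_sq[a$term == term] + fit2$ss_residual))
  }
})

test_that("Type-II SS of the last-entered predictor equals its sequential SS", {
  set.seed(4)
  n <- 45
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$y <- tab$a - tab$b + 0.5 * tab$c + rnorm(n)
  fit <- infantfc:::fit_ols(tab, c("a", "b", "c"), "y")
  seq_ss <- stats::anova(stats::lm(y ~ a + b + c, tab))["c", "Sum Sq"]
  expect_equal(fit$anova$sum_sq[fit$anova$term == "c"], seq_ss)
})

test_that("null outcomes keep per-predictor type-I error near alpha", {
  set.seed(5)
  reps <- 150; n <- 40; alpha <- 0.05
  rej <- 0; total <- 0
  for (r in 1:reps) {
    tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), sex = rbinom(n, 1, 0.5),
                      likelihood = rbinom(n, 1, 0.5),
                      age_5mo = rnorm(n, 152, 7),
                      ados_css_total = rnorm(n))
    fit <- fit_main_model(tab, predictors = c("x1", "x2"))
    rej <- rej + sum(fit$p_values[c("x1", "x2")] < alpha)
    total <- total + 2
  }
  expect_lt(abs(rej / total - alpha), 2.58 * sqrt(alpha * (1 - alpha) / total) + 0.01)
})

test_that("moderation recovers a stratum-specific slope and nests the main model", {
  set.seed(6)
  n <- 120
  tab <- data.frame(x = rnorm(n), sex = rbinom(n, 1, 0.5),
                    likelihood = rep(c(0, 1), each = n / 2),
                    age_5mo = rnorm(n, 152, 7))
  tab$ados_css_total <- 1 + 1.5 * tab$x * tab$likelihood + rnorm(n)  # EL-only slope
  main <- fit_main_model(tab, predictors = "x")
  mod <- fit_moderation_model(tab, predictors = "x")
  expect_gte(mod$r_squared, main$r_squared)
  b <- mod$coefficients[["likelihood:x"]]
  se <- summary(mod$model)$coefficients["likelihood:x", "Std. Error"]
  expect_lt(abs(b - 1.5), 1.96 * se * 1.5)
  expect_lt(mod$p_values[["likelihood:x"]], 0.01)
  tab$likelihood <- 1
  expect_error(fit_moderation_model(tab, predictors = "x"), "constant")
})

test_that("ANOVA comparison shows orthogonal additions leaving SS untouched", {
  set.seed(7)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- x1 + 0.5 * x2 + rnorm(n)
  # z exactly orthogonal (in sample) to intercept, x1, x2
  z0 <- rnorm(n)
  z <- stats::lm.fit(cbind(1, x1, x2), z0)$residuals
  tab <- data.frame(x1 = x1, x2 = x2, z = z, y = y)
  f0 <- infantfc:::fit_ols(tab, c("x1", "x2"), "y")
  f1 <- infantfc:::fit_ols(tab, c("x1", "x2", "z"), "y")
  cmp <- compare_models_anova(f0, f1)
  expect_equal(cmp$ss_without[cmp$term == "x1"], cmp$ss_with[cmp$term == "x1"])
  expect_equal(cmp$ss_without[cmp$term == "x2"], cmp$ss_with[cmp$term == "x2"])
  expect_equal(cmp$term, c("x1", "x2", "z", "Residuals", "df"))
  # a collinear addition shrinks the overlapping predictor's partial SS
  tab$w <- x1 + rnorm(n, 0, 0.4)
  f2 <- infantfc:::fit_ols(tab, c("x1", "x2", "w"), "y")
  cmp2 <- compare_models_anova(f0, f2)
  expect_lt(cmp2$ss_with[cmp2$term == "x1"], cmp2$ss_without[cmp2$term == "x1"])
  expect_error(compare_models_anova(f1, f0), "not nested")
})

test_that("the LR test matches lmtest and is null-distributed", {
  set.seed(8)
  n <- 43
  tab <- data.frame(x = rnorm(n), z = rnorm(n))
  tab$y <- tab$x + rnorm(n)
  red <- infantfc:::fit_ols(tab, "x", "y")
  full <- infantfc:::fit_ols(tab, c("x", "z"), "y")
  lr <- lr_test(red, full)
  expect_equal(lr$df, 1)
  ora <- lmtest::lrtest(red$model, full$model)
  expect_equal(lr$chi2, ora$Chisq[2], tolerance = 1e-10)
  expect_equal(lr$p, ora$`Pr(>Chisq)`[2], tolerance = 1e-10)
  # identical models: chi2 = 0, p = 1
  same <- lr_test(red, red)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # null chi-square behaviour of a pure-noise addition
  chis <- vapply(1:200, function(r) {
    tb <- data.frame(x = rnorm(n), z = rnorm(n))
    tb$y <- tb$x + rnorm(n)
    lr_test(infantfc:::fit_ols(tb, "x", "y"),
            infantfc:::fit_ols(tb, c("x", "z"), "y"))$chi2
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 0.35)                 # E[chi2_1] = 1
  expect_lt(suppressWarnings(stats::ks.test(chis, stats::pchisq, df = 1)$statistic), 0.12)
  # informative additions are detected at n = 43 scale
  tab$y2 <- tab$x + 0.6 * tab$z + rnorm(n)
  lr2 <- lr_test(infantfc:::fit_ols(tab, "x", "y2"),
                 infantfc:::fit_ols(tab, c("x", "z"), "y2"))
  expect_lt(lr2$p, 0.05)
})

test_that("the motion-score association selects 5 variables and finds plants", {
  set.seed(9)
  n <- 49
  X <- matrix(rnorm(n * 12), n, dimnames = list(NULL, modeling_variable_names()))
  tab <- as.data.frame(X)
  tab$gmls <- 0.9 * tab$gamma_social_far + rnorm(n, 0, 0.8)
  res <- gmls_association(tab, folds = 7, repeats = 2, seed = 3)
  expect_length(res$selection$selected, 5)
  expect_true("gamma_social_far" %in% res$selection$selected)
  expect_lt(res$fit$p_values[["gamma_social_far"]], 0.05)
  expect_false("likelihood" %in% res$fit$terms)  # no covariates in this fit
})

test_that("CV R^2 ranks a predictive subset above the intercept-only model", {
  set.seed(10)
  n <- 50
  tab <- data.frame(x = rnorm(n))
  tab$ados_css_total <- 2 * tab$x + rnorm(n)
  sel <- cv_subset_selection(tab, candidates = "x", folds = 5, repeats = 3,
                             seed = 1)
  expect_gt(sel$mean_cv_r2[2], sel$mean_cv_r2[1])  # {x} beats {}
})
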