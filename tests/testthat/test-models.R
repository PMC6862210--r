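feat0 <- c(Tr3_mean = 0, Tr5_mean = 0, DTr3 = 0, DTr5 = 0)

test_that("published equation reproduces its printed arithmetic", {
  expect_equal(lda_score(feat0), -2.05)
  expect_equal(lda_score(c(Tr3_mean = 1, Tr5_mean = 1, DTr3 = 0, DTr5 = 0)),
               -3.80)
  expect_equal(lda_score(c(Tr3_mean = 0, Tr5_mean = 0, DTr3 = 1, DTr5 = 0)),
               -1.04)
  expect_error(lda_score(c(Tr3_mean = 1)), "missing feature")
})

test_that("the score is exactly affine in each coordinate", {
  set.seed(13)
  model <- ec_published_model()
  base <- feat0
  for (rep in 1:10) {
    x <- stats::setNames(stats::rnorm(4), names(feat0))
    for (f in names(feat0)) {
      delta <- stats::runif(1, -5, 5)
      shifted <- x
      shifted[f] <- x[f] + delta
      expect_equal(lda_score(shifted, model) - lda_score(x, model),
                   delta * model$coefficients[[f]], tolerance = 1e-12)
    }
  }
})

test_that("classification thresholds scores with ties negative", {
  expect_equal(classify(0.5), 1L)
  expect_equal(classify(-2.05), -1L)
  expect_equal(classify(0.0), -1L)
  expect_equal(classify(c(1, -1, 0)), c(1L, -1L, -1L))
})

test_that("labels are invariant under joint positive rescaling", {
  set.seed(17)
  model <- ec_published_model()
  X <- as.data.frame(matrix(stats::rnorm(200), ncol = 4,
                            dimnames = list(NULL, names(feat0))))
  for (c_scale in c(0.01, 3, 250)) {
    scaled <- linear_model(model$coefficients * c_scale,
                           model$intercept * c_scale)
    expect_equal(classify(lda_score(X, scaled)),
                 classify(lda_score(X, model)))
  }
})

test_that("refit discriminant finds a planted single-feature signal", {
  pairs <- gaussian_pairs(n_per_class = 150, shift = c(DTr3 = 5), seed = 19)
  model <- fit_lda(pairs, split_seed = 19)
  std_coef <- abs(model$coefficients) *
    vapply(names(model$coefficients), function(f) stats::sd(pairs[[f]]),
           numeric(1))
  expect_equal(names(which.max(std_coef)), "DTr3")
  expect_gte(model$metadata$train_accuracy, 95)
  expect_gte(model$metadata$validation_accuracy, 95)
})

test_that("refit agrees with an independent discriminant implementation", {
  skip_if_not_installed("MASS")
  pairs <- gaussian_pairs(n_per_class = 120,
                          shift = c(DTr3 = 3, Tr5_mean = -2), seed = 23)
  feats <- c("Tr3_mean", "Tr5_mean", "DTr3", "DTr5")
  model <- fit_lda(pairs)  # no split: fit on all rows, like the oracle
  ref <- MASS::lda(pairs[, feats], grouping = factor(pairs$label))
  w_ref <- ref$scaling[, 1]
  # directions must be proportional (sign fixed by positive class)
  ratio <- model$coefficients[feats] / w_ref
  if (ratio[1] < 0) ratio <- -ratio
  expect_equal(unname(ratio / ratio[1]), rep(1, 4), tolerance = 1e-6)
})

test_that("identical class distributions flag a degenerate direction", {
  pairs <- gaussian_pairs(n_per_class = 200, shift = c(DTr3 = 0), seed = 29)
  expect_warning(model <- fit_lda(pairs), "near-zero|degenerate")
  expect_true(model$metadata$degenerate)
})

test_that("singular pooled covariance suggests regularization", {
  pairs <- gaussian_pairs(n_per_class = 50, seed = 31)
  pairs$Tr5_mean <- pairs$Tr3_mean  # exact collinearity
  expect_error(fit_lda(pairs), "regularize")
  model <- fit_lda(pairs, regularize = 1e-6)
  expect_s3_class(model, "linear_model")
})

test_that("refitting on labels generated by the published rule recovers it", {
  set.seed(37)
  feats <- names(feat0)
  X <- as.data.frame(matrix(stats::rnorm(4000 * 4, sd = 3), ncol = 4,
                            dimnames = list(NULL, feats)))
  truth <- classify(lda_score(X, ec_published_model()))
  pairs <- cbind(data.frame(sequence_id = paste0("s", seq_len(nrow(X))),
                            class_id = "1.1"),
                 X, data.frame(label = truth))
  train <- seq_len(3000)
  model <- fit_lda(pairs[train, ])
  held <- pairs[-train, ]
  agree <- mean(classify(lda_score(held[, feats], model)) == held$label)
  expect_gte(agree, 0.99)
})

test_that("perceptron learns separable data and is seed-deterministic", {
  pairs <- gaussian_pairs(n_per_class = 100, shift = c(DTr3 = 8), seed = 41)
  m1 <- fit_mlp(pairs, hidden = 9, seed = 5, max_epochs = 300)
  expect_equal(m1$train_accuracy, 100)
  expect_equal(m1$n_parameters, 4 * 9 + 9 + 9 * 2 + 2)  # 4-9-2 topology

  m2 <- fit_mlp(pairs, hidden = 9, seed = 5, max_epochs = 300)
  expect_identical(m1$fit$wts, m2$fit$wts)
})

test_that("a single hidden unit cannot solve an XOR arrangement", {
  set.seed(43)
  n <- 60
  grid <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  X <- grid[rep(seq_len(4), each = n), ]
  pairs <- data.frame(
    sequence_id = paste0("s", seq_len(4 * n)), class_id = "1.1",
    Tr3_mean = X$a + stats::rnorm(4 * n, sd = 0.05),
    Tr5_mean = X$b + stats::rnorm(4 * n, sd = 0.05),
    DTr3 = 0, DTr5 = 0,
    label = ifelse(X$a * X$b > 0, 1L, -1L)
  )
  suppressWarnings(m <- fit_mlp(pairs, hidden = 1, seed = 7,
                                max_epochs = 400))
  expect_lt(m$train_accuracy, 100)
})

test_that("sensitivity analysis ranks the features the model leans on", {
  pairs <- gaussian_pairs(n_per_class = 200, shift = c(DTr3 = 4), seed = 47)
  only_dtr3 <- linear_model(c(Tr3_mean = 0, Tr5_mean = 0,
                              DTr3 = 2, DTr5 = 0), intercept = -4)
  sens <- sensitivity_analysis(only_dtr3, pairs)
  expect_equal(names(sens)[1], "DTr3")
  expect_equal(unname(sens[c("Tr3_mean", "Tr5_mean", "DTr5")]),
               rep(1, 3), tolerance = 1e-9)

  # planted importance ordering: labels generated by a model with graded
  # coefficients over iid features; neutralizing a heavier feature flips
  # more labels, so the ranking must recover the coefficient order
  set.seed(49)
  feats <- c("Tr3_mean", "Tr5_mean", "DTr3", "DTr5")
  X <- as.data.frame(matrix(stats::rnorm(500 * 4), ncol = 4,
                            dimnames = list(NULL, feats)))
  planted <- linear_model(c(Tr3_mean = 3, Tr5_mean = 1.5,
                            DTr3 = 0.5, DTr5 = 0.05), intercept = 0)
  planted_pairs <- cbind(
    data.frame(sequence_id = paste0("s", 1:500), class_id = "1.1"),
    X, data.frame(label = classify(lda_score(X, planted))))
  sens2 <- sensitivity_analysis(planted, planted_pairs)
  expect_true(attr(sens2, "flagged"))  # zero baseline error
  expect_equal(names(sens2), feats)

  # permutation variant preserves the leading predictor
  sens3 <- sensitivity_analysis(only_dtr3, pairs, method = "permutation",
                                seed = 1)
  expect_equal(names(sens3)[1], "DTr3")
})

test_that("models survive a JSON round trip", {
  dir <- withr::local_tempdir()
  pairs <- gaussian_pairs(n_per_class = 60, shift = c(DTr3 = 6), seed = 53)

  lda_path <- file.path(dir, "lda.json")
  write_model(ec_published_model(), lda_path)
  back <- read_model(lda_path)
  expect_equal(back$coefficients, ec_published_model()$coefficients)
  expect_equal(back$intercept, -2.05)

  mlp <- fit_mlp(pairs, hidden = 3, seed = 9, max_epochs = 200)
  mlp_path <- file.path(dir, "mlp.json")
  write_model(mlp, mlp_path)
  back2 <- read_model(mlp_path)
  feats <- c("Tr3_mean", "Tr5_mean", "DTr3", "DTr5")
  expect_equal(score_pairs(back2, pairs[, feats]),
               score_pairs(mlp, pairs[, feats]), tolerance = 1e-8)
})

test_that("the packaged published model loads and scores", {
  path <- system.file("extdata", "published_model.json", package = "srnec")
  expect_true(nzchar(path))
  model <- read_model(path)
  expect_equal(lda_score(feat0, model), -2.05)
})
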