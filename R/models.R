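#' Construct a linear discriminant scoring model
#'
#' @param coefficients Named numeric vector of feature coefficients.
#' @param intercept Numeric intercept.
#' @param metadata Optional list stored with the model.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(coefficients, intercept, metadata = list()) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))), all(is.finite(coefficients)),
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  structure(list(coefficients = coefficients, intercept = intercept,
                 metadata = metadata),
            class = "linear_model")
}

#' The published enzyme-subclass discriminant equation
#'
#' The four-variable linear score
#' `EC = -0.95 <Tr3> - 0.80 <Tr5> - 0.80 DTr5 + 1.01 DTr3 - 2.05`,
#' where `<Tr_k>` is the candidate class's mean trace descriptor of order
#' `k` and `DTr_k` the sequence's deviation from it. A positive score at
#' the default threshold 0 classifies the pair as enzyme-of-class.
#'
#' @return A `linear_model` with the published coefficients.
#' @examples
#' lda_score(c(Tr3_mean = 0, Tr5_mean = 0, DTr3 = 0, DTr5 = 0),
#'           ec_published_model())  # -2.05
#' @export
ec_published_model <- function() {
  linear_model(
    coefficients = c(Tr3_mean = -0.95, Tr5_mean = -0.80,
                     DTr5 = -0.80, DTr3 = 1.01),
    intercept = -2.05,
    metadata = list(source = "published four-variable discriminant")
  )
}

#' @export
print.linear_model <- function(x, ...) {
  cat("Linear discriminant model\n")
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %-10s % .6g\n", nm, x$coefficients[[nm]]))
  }
  cat(sprintf("  %-10s % .6g\n", "intercept", x$intercept))
  invisible(x)
}

#' Score pair features with the linear discriminant
#'
#' @param features Named numeric vector, or a `data.frame` whose columns
#'   include every model coefficient name (one score per row).
#' @param model A `linear_model`; default the published equation.
#' @return Numeric score(s).
#' @export
lda_score <- function(features, model = ec_published_model()) {
  stopifnot(inherits(model, "linear_model"))
  nms <- names(model$coefficients)
  if (is.data.frame(features)) {
    absent <- setdiff(nms, names(features))
    if (length(absent)) {
      stop("missing feature(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(features[, nms, drop = FALSE])
  } else {
    absent <- setdiff(nms, names(features))
    if (length(absent)) {
      stop("missing feature(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    X <- matrix(as.numeric(features[nms]), nrow = 1,
                dimnames = list(NULL, nms))
  }
  if (any(!is.finite(X))) stop("non-finite feature value", call. = FALSE)
  as.numeric(X %*% model$coefficients + model$intercept)
}

#' Threshold a discriminant score into a class label
#'
#' @param score Numeric score(s).
#' @param threshold Decision threshold; scores strictly above it classify
#'   `+1`, everything else (including exact ties) `-1`.
#' @return Integer label(s) in `{+1, -1}`.
#' @export
classify <- function(score, threshold = 0) {
  stopifnot(all(is.finite(score)))
  ifelse(score > threshold, 1L, -1L)
}

#' Score pair features with any fitted model
#'
#' Generic over the package's model classes: the linear discriminant
#' scores with [lda_score()]; the perceptron scores with the margin
#' between its two softmax outputs (probability of `+1` minus
#' probability of `-1`), so positive scores favour the pair under either
#' model type.
#'
#' @param model A `linear_model` or `mlp_model`.
#' @param features `data.frame` containing the model's feature columns.
#' @return Numeric score per row.
#' @export
score_pairs <- function(model, features) UseMethod("score_pairs", model)

#' @export
score_pairs.linear_model <- function(model, features) {
  lda_score(features, model)
}

#' @export
score_pairs.mlp_model <- function(model, features) {
  X <- as.matrix(features[, model$feature_names, drop = FALSE])
  p <- stats::predict(model$fit, X)
  # score = logit-style margin: P(+1) - P(-1), positive favours the pair
  as.numeric(p[, "1"] - p[, "-1"])
}

# Feature columns of a pair table (everything but ids and label).
pair_feature_names <- function(pairs) {
  setdiff(names(pairs), c("sequence_id", "class_id", "label"))
}

# Seeded 70/30 split of row indices; returns logical "in training" mask.
split_mask <- function(n, fraction = 0.70, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  idx <- sample.int(n, size = floor(fraction * n))
  seq_len(n) %in% idx
}

#' Refit the linear discriminant on pair records
#'
#' Two-class Fisher discriminant on the pair features: direction
#' `w = S_w^-1 (mu_pos - mu_neg)` with `S_w` the pooled within-class
#' covariance, the sign oriented so the positive (enzyme-of-class, `+1`)
#' class scores positive, and the intercept set by a one-dimensional
#' search along the discriminant for the cut with minimal training error
#' (the classical pooled-mean midpoint is only optimal for balanced,
#' symmetric classes). Degeneracy — no statistically detectable class
#' separation — is flagged via a Hotelling T-squared test on the mean
#' difference. A seeded 70/30 split is used to report training/validation
#' accuracy in the model metadata; the discriminant itself is fitted on
#' the training portion.
#'
#' @param pairs Pair `data.frame` from [make_pairs()] with a `label` column.
#' @param split_seed Seed for the 70/30 train/validation split; `NULL`
#'   fits on all rows and skips the validation report.
#' @param regularize Ridge term added to the pooled covariance diagonal
#'   (fraction of its mean diagonal); use when the covariance is singular.
#' @return A `linear_model` with metadata `train_accuracy`,
#'   `validation_accuracy` (percent), `n_train`, `n_validation`,
#'   `split_seed`, and `degenerate` (near-zero direction flag).
#' @export
fit_lda <- function(pairs, split_seed = NULL, regularize = 0) {
  feats <- pair_feature_names(pairs)
  stopifnot(length(feats) >= 1L, "label" %in% names(pairs))
  y <- pairs$label
  if (!all(sort(unique(y)) %in% c(-1L, 1L)) || length(unique(y)) != 2L) {
    stop("both labels (+1/-1) must be present", call. = FALSE)
  }
  if (min(table(y)) < 5L) {
    stop("need at least 5 records per label", call. = FALSE)
  }
  train <- if (is.null(split_seed)) rep(TRUE, nrow(pairs)) else {
    m <- split_mask(nrow(pairs), 0.70, split_seed)
    # guard: both labels must survive the split
    if (length(unique(y[m])) < 2L) rep(TRUE, nrow(pairs)) else m
  }
  X <- as.matrix(pairs[train, feats, drop = FALSE])
  yt <- y[train]
  mu_pos <- colMeans(X[yt == 1L, , drop = FALSE])
  mu_neg <- colMeans(X[yt == -1L, , drop = FALSE])
  n_pos <- sum(yt == 1L); n_neg <- sum(yt == -1L)
  Sw <- ((n_pos - 1) * stats::cov(X[yt == 1L, , drop = FALSE]) +
         (n_neg - 1) * stats::cov(X[yt == -1L, , drop = FALSE])) /
        (n_pos + n_neg - 2)
  if (regularize > 0) {
    Sw <- Sw + diag(regularize * mean(diag(Sw)), ncol(Sw))
  }
  w <- tryCatch(solve(Sw, mu_pos - mu_neg), error = function(e) {
    stop("pooled within-class covariance is singular; ",
         "retry with regularize > 0", call. = FALSE)
  })
  # Hotelling T^2 on the mean difference: no detectable separation
  # means the direction is estimation noise
  p <- length(w)
  n_all <- n_pos + n_neg
  d2 <- sum(w * (mu_pos - mu_neg))
  degenerate <- FALSE
  if (n_all - p - 1 > 0) {
    t2 <- (n_pos * n_neg / n_all) * d2
    f_stat <- t2 * (n_all - p - 1) / ((n_all - 2) * p)
    degenerate <- stats::pf(f_stat, p, n_all - p - 1,
                            lower.tail = FALSE) > 0.05
  }
  if (degenerate) {
    warning("near-zero discriminant direction: classes are indistinguishable",
            call. = FALSE)
  }
  # orient so the positive class has the larger mean score
  if (sum(w * (mu_pos - mu_neg)) < 0) w <- -w
  # intercept: minimal-training-error cut along the discriminant
  s <- as.numeric(X %*% w)
  ord <- order(s)
  s_sorted <- s[ord]
  y_sorted <- yt[ord]
  # errors when the cut sits after position i (scores <= cut -> -1)
  pos_below <- cumsum(y_sorted == 1L)
  neg_above <- sum(y_sorted == -1L) - cumsum(y_sorted == -1L)
  errs <- c(sum(y_sorted == -1L), pos_below + neg_above)
  cuts <- c(s_sorted[1] - 1,
            (s_sorted + c(s_sorted[-1], s_sorted[length(s_sorted)] + 2)) / 2)
  midpoint <- sum(w * (mu_pos + mu_neg) / 2)
  # cuts inside a run of tied scores do not realise the assumed split
  valid <- c(TRUE, c(s_sorted[-1] > s_sorted[-length(s_sorted)], TRUE))
  errs[!valid] <- Inf
  best <- which(errs == min(errs))
  cut <- cuts[best[which.min(abs(cuts[best] - midpoint))]]
  b <- -cut
  model <- linear_model(stats::setNames(as.numeric(w), feats), b)
  pred <- classify(lda_score(pairs[, feats, drop = FALSE], model))
  meta <- list(
    train_accuracy = 100 * mean(pred[train] == y[train]),
    validation_accuracy = if (all(train)) NA_real_
      else 100 * mean(pred[!train] == y[!train]),
    n_train = sum(train), n_validation = sum(!train),
    split_seed = split_seed, degenerate = degenerate,
    feature_names = feats
  )
  model$metadata <- meta
  model
}

#' Fit a one-hidden-layer perceptron on pair records
#'
#' A 4-h-2 multilayer perceptron (four pair features, `hidden` units, two
#' softmax outputs) trained on cross-entropy via [nnet::nnet()]. Weight
#' initialisation and the internal 70/30 train/validation split are both
#' driven by `seed`, so a fixed seed reproduces the fitted weights exactly.
#'
#' @param pairs Pair `data.frame` with a `label` column.
#' @param hidden Hidden-layer size (the published topology uses 9).
#' @param seed RNG seed for initial weights and the split.
#' @param max_epochs Optimiser iteration cap; non-convergence raises a
#'   warning and returns the best weights found.
#' @return An `mlp_model`: list with `fit` (the nnet object), `hidden`,
#'   `feature_names`, `n_parameters`, `seed`, `train_accuracy`,
#'   `validation_accuracy` (percent).
#' @export
fit_mlp <- function(pairs, hidden = 9L, seed = 1L, max_epochs = 200L) {
  stopifnot(hidden >= 1L)
  feats <- pair_feature_names(pairs)
  y <- factor(pairs$label, levels = c(-1L, 1L))
  if (nlevels(droplevels(y)) < 2L) {
    stop("both labels (+1/-1) must be present", call. = FALSE)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  train <- split_mask(nrow(pairs), 0.70)
  if (length(unique(y[train])) < 2L) train <- rep(TRUE, nrow(pairs))
  X <- as.matrix(pairs[, feats, drop = FALSE])
  Y <- nnet::class.ind(y)
  fit <- nnet::nnet(X[train, , drop = FALSE], Y[train, , drop = FALSE],
                    size = hidden, softmax = TRUE, maxit = max_epochs,
                    trace = FALSE)
  if (isTRUE(fit$convergence == 1)) {
    warning("perceptron did not converge within max_epochs; ",
            "returning best weights found", call. = FALSE)
  }
  model <- structure(
    list(fit = fit, hidden = as.integer(hidden), feature_names = feats,
         n_parameters = length(fit$wts), seed = seed),
    class = "mlp_model")
  pred <- classify(score_pairs(model, as.data.frame(X)))
  model$train_accuracy <- 100 * mean(pred[train] == pairs$label[train])
  model$validation_accuracy <- if (all(train)) NA_real_
    else 100 * mean(pred[!train] == pairs$label[!train])
  model
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Perceptron %d-%d-2 (%d parameters), train acc %.2f%%\n",
              length(x$feature_names), x$hidden, x$n_parameters,
              x$train_accuracy))
  invisible(x)
}

# Model loss on a pair table: misclassification rate of the thresholded
# score against the pair labels (uniform across model types, so
# sensitivity ratios compare like with like).
model_error <- function(model, pairs) {
  feats <- pair_feature_names(pairs)
  pred <- classify(score_pairs(model, pairs[, feats, drop = FALSE]))
  mean(pred != pairs$label)
}

#' Predictor importance by sensitivity analysis
#'
#' For each feature, the model's misclassification error on the pair
#' labels is recomputed with that feature neutralized — replaced by its
#' column mean (default) or permuted — and reported as the ratio to the
#' baseline error. Ratios well above 1 mark important predictors; a
#' feature the model ignores has ratio exactly 1. If the baseline error
#' is zero (a perfectly fitted model), ratios are taken against a floor
#' of 1e-8 — the ordering is still informative — and the result carries
#' attribute `flagged = TRUE`.
#'
#' @param model A `linear_model` or `mlp_model`.
#' @param pairs Pair `data.frame` with a `label` column.
#' @param method `"mean-substitution"` (default) or `"permutation"`.
#' @param seed Seed for the permutation method.
#' @return Named numeric vector of sensitivity ratios, sorted descending
#'   (most important predictor first).
#' @export
sensitivity_analysis <- function(model, pairs,
                                 method = c("mean-substitution",
                                            "permutation"),
                                 seed = 1L) {
  method <- match.arg(method)
  feats <- pair_feature_names(pairs)
  base <- model_error(model, pairs)
  flagged <- base < 1e-8
  base <- max(base, 1e-8)
  if (method == "permutation") {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  sens <- vapply(feats, function(f) {
    perturbed <- pairs
    perturbed[[f]] <- if (method == "mean-substitution") {
      mean(pairs[[f]])
    } else {
      sample(pairs[[f]])
    }
    max(model_error(model, perturbed), 1e-8) / base
  }, numeric(1))
  out <- sort(sens, decreasing = TRUE)
  if (flagged) attr(out, "flagged") <- TRUE
  out
}

#' Write a model to a JSON file
#'
#' Schema: `{type: "lda"|"mlp", coefficients|weights, metadata}`. The MLP
#' is stored as its flat weight vector plus topology, enough to rebuild
#' the scoring function.
#'
#' @param model `linear_model` or `mlp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "linear_model")) {
    obj <- list(type = "lda",
                coefficients = as.list(model$coefficients),
                intercept = model$intercept,
                metadata = model$metadata)
  } else if (inherits(model, "mlp_model")) {
    obj <- list(type = "mlp",
                hidden = model$hidden,
                feature_names = model$feature_names,
                weights = model$fit$wts,
                metadata = list(seed = model$seed,
                                n_parameters = model$n_parameters,
                                train_accuracy = model$train_accuracy))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model from a JSON file
#'
#' @param path Path written by [write_model()], or the packaged published
#'   model (`system.file("extdata", "published_model.json",
#'   package = "srnec")`).
#' @return `linear_model` or `mlp_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "lda")) {
    linear_model(unlist(obj$coefficients), obj$intercept,
                 metadata = if (is.null(obj$metadata)) list()
                            else as.list(obj$metadata))
  } else if (identical(obj$type, "mlp")) {
    feats <- obj$feature_names
    net <- nnet::nnet(matrix(0, 4, length(feats),
                             dimnames = list(NULL, feats)),
                      nnet::class.ind(factor(c(-1, 1, -1, 1),
                                             levels = c(-1, 1))),
                      size = obj$hidden, softmax = TRUE, maxit = 0,
                      trace = FALSE)
    net$wts <- obj$weights
    structure(list(fit = net, hidden = obj$hidden, feature_names = feats,
                   n_parameters = length(obj$weights),
                   seed = obj$metadata$seed,
                   train_accuracy = obj$metadata$train_accuracy,
                   validation_accuracy = NA_real_),
              class = "mlp_model")
  } else {
    stop("unknown model type in ", path, call. = FALSE)
  }
}
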