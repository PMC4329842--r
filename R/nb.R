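#' Fit a Gaussian Naive Bayes model
#'
#' Naive Bayes assumes the attributes are conditionally independent
#' given the class, so the joint likelihood factorises into per-attribute
#' terms.  For numeric attributes each term is a Gaussian whose mean and
#' variance are estimated per attribute and per class from the training
#' examples; class priors are the empirical class frequencies unless
#' overridden.  Classification compares the posterior-odds ratio
#'
#' \deqn{\frac{P(c=1)\prod_i P(x_i \mid c=1)}
#'            {P(c=0)\prod_i P(x_i \mid c=0)} > \theta}
#'
#' against the decision threshold `theta` (default 1): the residue is
#' called binding when the ratio strictly exceeds `theta`.  All products
#' are evaluated as sums of logs, so 100-240-attribute windows do not
#' underflow.
#'
#' Per-attribute variances are floored at
#' `max(var_floor_abs, var_floor_rel * range)` where `range` is the
#' attribute's spread in the training data; this keeps attributes that
#' are constant within a class from producing infinite likelihood
#' ratios.
#'
#' @param train An [encoded_dataset()] containing both classes.
#' @param theta Decision threshold on the posterior-odds ratio
#'   (default 1).
#' @param priors Optional numeric `c(p0, p1)` overriding the empirical
#'   class priors (must be positive and sum to 1); e.g. `c(0.5, 0.5)`
#'   forces the decision boundary to ignore class imbalance.
#' @param var_floor_rel,var_floor_abs Variance floor parameters (see
#'   Details).
#' @return Object of class `nb_model`.
#' @export
nb_fit <- function(train, theta = 1, priors = NULL,
                   var_floor_rel = 1e-9, var_floor_abs = 1e-12) {
  stopifnot(inherits(train, "encoded_dataset"), theta > 0)
  x <- train$features
  y <- train$labels
  if (ncol(x) == 0L) stop("training data has zero attributes",
                          call. = FALSE)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    stop("training data must contain both classes (got ", n1,
         " positive, ", n0, " negative examples)", call. = FALSE)
  }
  if (is.null(priors)) {
    priors <- c(n0, n1) / (n0 + n1)
  } else {
    stopifnot(length(priors) == 2L, all(priors > 0),
              abs(sum(priors) - 1) < 1e-8)
  }
  rng <- apply(x, 2, max) - apply(x, 2, min)
  floor_v <- pmax(var_floor_abs, var_floor_rel * rng)
  mv <- function(cls) {
    xc <- x[cls, , drop = FALSE]
    mu <- colMeans(xc)
    v <- if (nrow(xc) > 1L) apply(xc, 2, stats::var) else rep(0, ncol(xc))
    list(mu = mu, var = pmax(v, floor_v))
  }
  p0 <- mv(!y); p1 <- mv(y)
  structure(list(prior_0 = priors[1], prior_1 = priors[2],
                 mu_0 = p0$mu, var_0 = p0$var,
                 mu_1 = p1$mu, var_1 = p1$var,
                 theta = theta,
                 attribute_names = train$attribute_names,
                 n_attributes = ncol(x),
                 n_train = c(negative = n0, positive = n1)),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat("nb_model: ", x$n_attributes, " Gaussian attributes per class, ",
      "priors P(1)=", signif(x$prior_1, 4),
      ", theta=", x$theta, "\n", sep = "")
  invisible(x)
}

as_feature_matrix <- function(model, x) {
  if (inherits(x, "encoded_dataset")) x <- x$features
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_attributes) {
    stop("feature dimension ", ncol(x), " does not match model (",
         model$n_attributes, " attributes)", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  x
}

#' Log posterior-odds ratio of a Naive Bayes model
#'
#' Computes `log P(c=1) - log P(c=0) + sum_i [log N(x_i; mu_i1, var_i1)
#' - log N(x_i; mu_i0, var_i0)]` entirely in log space.
#'
#' @param model An `nb_model`.
#' @param x Feature vector, feature matrix (rows = examples) or
#'   [encoded_dataset()].
#' @return Numeric vector of log posterior-odds ratios, one per example.
#' @export
nb_log_ratio <- function(model, x) {
  x <- as_feature_matrix(model, x)
  ll1 <- stats::dnorm(x,
                      matrix(model$mu_1, nrow(x), ncol(x), byrow = TRUE),
                      matrix(sqrt(model$var_1), nrow(x), ncol(x),
                             byrow = TRUE), log = TRUE)
  ll0 <- stats::dnorm(x,
                      matrix(model$mu_0, nrow(x), ncol(x), byrow = TRUE),
                      matrix(sqrt(model$var_0), nrow(x), ncol(x),
                             byrow = TRUE), log = TRUE)
  log(model$prior_1) - log(model$prior_0) + rowSums(ll1 - ll0)
}

#' Predict binding labels with a Naive Bayes model
#'
#' Labels an example positive when the posterior-odds ratio strictly
#' exceeds `theta`; a ratio exactly equal to `theta` is classified
#' negative.
#'
#' @inheritParams nb_log_ratio
#' @param theta Decision threshold; defaults to the value stored in the
#'   model.
#' @return Data frame of class `nb_prediction` with columns `log_ratio`,
#'   `score` (`exp(log_ratio)`, the posterior-odds value) and `label`
#'   (logical).
#' @export
nb_predict <- function(model, x, theta = model$theta) {
  stopifnot(theta > 0)
  lr <- nb_log_ratio(model, x)
  structure(data.frame(log_ratio = lr, score = exp(lr),
                       label = lr > log(theta)),
            class = c("nb_prediction", "data.frame"))
}

#' Serialize a Naive Bayes model to a versioned JSON file
#'
#' Stores priors, per-class Gaussian parameters, attribute names, theta
#' and (optionally) the attached normalizer and encoding configuration,
#' at full numeric precision so that a reloaded model reproduces every
#' prediction bit for bit.
#'
#' @param model An `nb_model` (optionally carrying `$normalizer`,
#'   `$encoder`, `$window_k`, `$padding` attached by [cmd_train()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  m <- unclass(model)
  if (!is.null(m$normalizer)) m$normalizer <- unclass(m$normalizer)
  payload <- list(format = "mplig-nb-model", version = 1L, model = m)
  # I(17) = 17 significant digits: doubles survive the text round-trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized Naive Bayes model
#'
#' @param path File written by [write_nb_model()].
#' @return An `nb_model`.
#' @export
read_nb_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mplig-nb-model")) {
    stop("'", path, "' is not an mplig model file", call. = FALSE)
  }
  m <- payload$model
  m$n_train <- unlist(m$n_train)
  if (!is.null(m$normalizer)) {
    m$normalizer <- structure(m$normalizer, class = "normalizer")
  }
  structure(m, class = "nb_model")
}

# ---- discrete-likelihood mode (frequency tables) ----------------------
# Used to validate the ratio rule against exhaustive evaluation of the
# joint P(c) * prod_i P(x_i | c) on small categorical problems; the
# production classifier is the Gaussian one above.

nb_fit_discrete <- function(x_df, y) {
  stopifnot(is.data.frame(x_df), sum(y) > 0, sum(!y) > 0)
  tabs <- lapply(x_df, function(col) {
    lv <- sort(unique(col))
    t1 <- vapply(lv, function(v) mean(col[y] == v), 0)
    t0 <- vapply(lv, function(v) mean(col[!y] == v), 0)
    list(levels = lv, p1 = t1, p0 = t0)
  })
  list(prior_1 = mean(y), prior_0 = mean(!y), tables = tabs)
}

nb_ratio_discrete <- function(model, x_row) {
  num <- model$prior_1
  den <- model$prior_0
  for (i in seq_along(model$tables)) {
    tb <- model$tables[[i]]
    j <- match(x_row[[i]], tb$levels)
    num <- num * tb$p1[j]
    den <- den * tb$p0[j]
  }
  num / den   # may be Inf / NaN on zero counts; callers use small cases
}
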