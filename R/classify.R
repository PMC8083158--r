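#' Construct a base classifier with the study's fixed hyperparameters
#'
#' Returns a learner object exposing `fit(x, y)` and `score(model, newx)`,
#' where `x` is a samples x features matrix of (z-scored) expression, `y`
#' are `"R"`/`"NR"` labels, and the score is a number in [0, 1], larger
#' meaning more responder-like. Methods and settings:
#'
#' * `svm` — linear-kernel support vector machine, balanced class weights;
#'   the signed decision value is mapped to [0, 1] by a logistic transform.
#' * `rf` — random forest, 30 trees, balanced per-class stratified
#'   subsampling (each tree draws `min(class sizes)` samples per class with
#'   replacement); score = fraction of responder votes.
#' * `ridge` — ridge regression of the +/-1-coded label with regularization
#'   strength 1.0; logistic transform of the continuous output.
#' * `bnb` — Bernoulli naive Bayes: features binarized at 0 (i.e. above or
#'   below the training-fold mean after z-scoring), additive smoothing 1.0,
#'   uniform class priors; score = posterior probability of `R`.
#' * `mlp` — multilayer perceptron, one hidden layer of 30 logistic units,
#'   L2 weight decay 0.001, cross-entropy loss; score = output activation.
#'
#' Stochastic methods (`rf`, `mlp`) reset the RNG to `seed` at every fit, so
#' a learner's predictions are deterministic functions of the data.
#'
#' @param method one of `"svm"`, `"rf"`, `"ridge"`, `"bnb"`, `"mlp"` (long
#'   aliases such as `"linear-SVM"`, `"random-forest"`,
#'   `"binomial-naive-Bayes"`, `"multilayer-perceptron"` are accepted).
#' @param seed integer seed recorded in the learner and applied before each
#'   stochastic fit.
#' @return object of class `base_learner` with elements `method`, `seed`,
#'   `fit` and `score`.
#' @export
build_classifier <- function(method, seed = 1L) {
  key <- c("linear-svm" = "svm", "svm" = "svm",
           "random-forest" = "rf", "rf" = "rf",
           "ridge" = "ridge", "ridge-regression" = "ridge", "rr" = "ridge",
           "binomial-naive-bayes" = "bnb", "bnb" = "bnb",
           "multilayer-perceptron" = "mlp", "mlp" = "mlp")
  m <- key[tolower(method)]
  .assert(!is.na(m), "unknown method: ", method)
  seed <- as.integer(seed)
  fit <- switch(m,
    svm = function(x, y) .fit_svm(x, y),
    rf = function(x, y) { set.seed(seed); .fit_rf(x, y) },
    ridge = function(x, y) .fit_ridge(x, y),
    bnb = function(x, y) .fit_bnb(x, y),
    mlp = function(x, y) { set.seed(seed); .fit_mlp(x, y) })
  score <- switch(m,
    svm = .score_svm, rf = .score_rf, ridge = .score_ridge,
    bnb = .score_bnb, mlp = .score_mlp)
  structure(list(method = unname(m), seed = seed, fit = fit,
                 score = function(model, newx)
                   pmin(1, pmax(0, score(model, newx)))),
            class = "base_learner")
}

.as_factor_y <- function(y) factor(y, levels = c("NR", "R"))

.fit_svm <- function(x, y) {
  yf <- .as_factor_y(y)
  tab <- table(yf)
  wts <- as.numeric(length(yf) / (2 * tab))
  names(wts) <- names(tab)
  e1071::svm(x, yf, kernel = "linear", scale = FALSE, class.weights = wts)
}
.as_row_matrix <- function(newx) {
  if (is.matrix(newx)) newx
  else matrix(newx, nrow = 1, dimnames = list(NULL, names(newx)))
}
.score_svm <- function(model, newx) {
  p <- stats::predict(model, .as_row_matrix(newx), decision.values = TRUE)
  dv <- drop(attr(p, "decision.values"))
  pos_first <- startsWith(colnames(attr(p, "decision.values"))[1], "R")
  stats::plogis(if (pos_first) dv else -dv)
}

.fit_rf <- function(x, y) {
  yf <- .as_factor_y(y)
  nmin <- min(table(yf))
  randomForest::randomForest(x, yf, ntree = 30, strata = yf,
                             sampsize = c(nmin, nmin), replace = TRUE)
}
.score_rf <- function(model, newx) {
  stats::predict(model, .as_row_matrix(newx), type = "prob")[, "R"]
}

.fit_ridge <- function(x, y) {
  yn <- ifelse(y == "R", 1, -1)
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) {
    return(list(intercept = mean(yn), coef = numeric(0),
                features = character(0)))
  }
  xs <- x[, keep, drop = FALSE]
  feats <- colnames(xs)
  colnames(xs) <- paste0("V", seq_along(feats))  # HGNC symbols can be
  df <- data.frame(..y = yn, xs)                 # non-syntactic (e.g. IGHV1-69)
  fit <- MASS::lm.ridge(..y ~ ., data = df, lambda = 1)
  cf <- stats::coef(fit)
  list(intercept = cf[1], coef = unname(cf[-1]), features = feats)
}
.score_ridge <- function(model, newx) {
  x <- .as_row_matrix(newx)
  raw <- model$intercept +
    if (length(model$features))
      drop(x[, model$features, drop = FALSE] %*% model$coef) else 0
  stats::plogis(as.numeric(raw))
}

# Bernoulli naive Bayes, binarization threshold 0, smoothing alpha = 1,
# uniform class priors (sklearn BernoulliNB(alpha=1, binarize=0,
# fit_prior=False))
.fit_bnb <- function(x, y, alpha = 1) {
  xb <- x > 0
  theta <- sapply(c("NR", "R"), function(cl) {
    idx <- y == cl
    (colSums(xb[idx, , drop = FALSE]) + alpha) / (sum(idx) + 2 * alpha)
  })
  list(theta = theta, features = colnames(x))
}
.score_bnb <- function(model, newx) {
  xb <- .as_row_matrix(newx)[, model$features, drop = FALSE] > 0
  ll <- xb %*% log(model$theta) + (1 - xb) %*% log(1 - model$theta)
  as.numeric(1 / (1 + exp(ll[, "NR"] - ll[, "R"])))
}

.fit_mlp <- function(x, y) {
  yi <- as.numeric(y == "R")
  nnet::nnet(x, yi, size = 30, decay = 0.001, entropy = TRUE,
             trace = FALSE, MaxNWts = 50000)
}
.score_mlp <- function(model, newx) {
  as.numeric(stats::predict(model, .as_row_matrix(newx)))
}

#' ROC AUC and precision-recall AUC of a score vector
#'
#' `roc_auc` is the Mann-Whitney statistic (probability that a random
#' responder outscores a random non-responder, ties 1/2). `aupr` is the area
#' under the precision-recall step curve by the interpolation-free
#' summation convention (average precision); for constant scores it equals
#' the positive-class prevalence.
#'
#' @param scores numeric scores, larger = more responder-like.
#' @param labels `"R"`/`"NR"` labels, both classes present.
#' @return a number in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  .assert(length(scores) == length(labels), "scores/labels length mismatch")
  .check_labels(labels)
  .mw_auc(scores, labels == "R")
}

#' @rdname roc_auc
#' @export
aupr <- function(scores, labels) {
  .assert(length(scores) == length(labels), "scores/labels length mismatch")
  .check_labels(labels)
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord] == "R"
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # one operating point per distinct score value (last index of each block)
  idx <- cumsum(rle(s)$lengths)
  prec <- tp[idx] / (tp[idx] + fp[idx])
  rec <- tp[idx] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Sensitivity/specificity against the balance factor B
#'
#' B is a false-positive vs false-negative cost balance: a sample is called
#' a responder when its score reaches the threshold `tau(B) = B / (1 + B)`,
#' so B = 1 recovers the neutral 0.5 threshold, small B favours sensitivity
#' and large B favours specificity.
#'
#' @param evaluation a `loo_eval` object, or a list/vector of scores (then
#'   `labels` must be given).
#' @param B_grid positive balance-factor values (default: 15 log-spaced in
#'   [0.1, 10]).
#' @param labels labels when `evaluation` is a plain score vector.
#' @return data.frame with columns `B`, `tau`, `sensitivity`, `specificity`.
#' @export
metrics_vs_balance <- function(evaluation, B_grid = default_b_grid(),
                               labels = NULL) {
  if (inherits(evaluation, "loo_eval")) {
    scores <- evaluation$scores
    labels <- evaluation$labels
  } else scores <- evaluation
  .assert(all(B_grid > 0), "B values must be positive")
  .check_labels(labels)
  pos <- labels == "R"
  out <- lapply(B_grid, function(B) {
    tau <- B / (1 + B)
    call_pos <- scores >= tau
    data.frame(B = B, tau = tau,
               sensitivity = sum(call_pos & pos) / sum(pos),
               specificity = sum(!call_pos & !pos) / sum(!pos))
  })
  do.call(rbind, out)
}

#' @rdname metrics_vs_balance
#' @export
default_b_grid <- function() exp(seq(log(0.1), log(10), length.out = 15))

#' Leave-one-out evaluation of a classifier, with or without FloWPS
#'
#' For every sample i the learner is trained on the remaining samples
#' (features z-scored with training-fold means/sds) — directly, or through
#' [flowps_predict()] when `flowps` parameters are supplied — and sample i
#' is scored out-of-fold. Features should be the core marker genes from
#' [loo_core_markers()].
#'
#' @param features samples x genes numeric matrix (rows = samples).
#' @param labels per-sample `"R"`/`"NR"` labels, >= 3 per class.
#' @param config a `base_learner` from [build_classifier()], or a method
#'   name (then built with `seed`).
#' @param flowps a [flowps_params()] object to enable FloWPS, or NULL.
#' @param B_grid balance-factor grid for the sensitivity/specificity curves.
#' @param seed seed used when `config` is a method name.
#' @param cohort optional cohort tag ("full"/"VCD") carried into the result.
#' @return object of class `loo_eval` with out-of-fold `scores`, `labels`,
#'   `roc_auc`, `aupr`, `curves` (from [metrics_vs_balance()]), `method`,
#'   `flowps` flag and `cohort`.
#' @export
loo_evaluate <- function(features, labels, config, flowps = NULL,
                         B_grid = default_b_grid(), seed = 1L,
                         cohort = NULL) {
  .assert(is.matrix(features), "features must be a samples x genes matrix")
  n <- nrow(features)
  .assert(length(labels) == n, "labels must match rows of features")
  .check_labels(labels)
  .assert(min(table(labels)) >= 3, "need >= 3 samples per class")
  learner <- if (inherits(config, "base_learner")) config
             else build_classifier(config, seed = seed)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    train <- features[-i, , drop = FALSE]
    test <- features[i, ]
    .assert(all(c("R", "NR") %in% labels[-i]), "degenerate fold at sample ", i)
    if (is.null(flowps)) {
      mu <- colMeans(train)
      sd_ <- apply(train, 2L, stats::sd)
      sd_[sd_ == 0] <- 1
      ztrain <- sweep(sweep(train, 2L, mu), 2L, sd_, "/")
      ztest <- (test - mu) / sd_
      model <- learner$fit(ztrain, labels[-i])
      scores[i] <- learner$score(model, ztest)
    } else {
      scores[i] <- as.numeric(
        flowps_predict(test, train, labels[-i], learner, params = flowps))
    }
  }
  names(scores) <- rownames(features)
  structure(list(scores = scores, labels = labels,
                 roc_auc = roc_auc(scores, labels),
                 aupr = aupr(scores, labels),
                 curves = metrics_vs_balance(scores, B_grid, labels = labels),
                 method = learner$method, flowps = !is.null(flowps),
                 B_grid = B_grid, cohort = cohort),
            class = "loo_eval")
}

#' @export
print.loo_eval <- function(x, ...) {
  cat(sprintf("Leave-one-out evaluation: %s%s%s\n", x$method,
              if (x$flowps) " + FloWPS" else "",
              if (!is.null(x$cohort)) paste0(" [", x$cohort, " cohort]") else ""))
  cat(sprintf("  n = %d (%d R / %d NR)   ROC AUC = %.3f   AUPR = %.3f\n",
              length(x$scores), sum(x$labels == "R"), sum(x$labels == "NR"),
              x$roc_auc, x$aupr))
  invisible(x)
}

#' @export
summary.loo_eval <- function(object, ...) {
  print(object)
  b1 <- object$curves[which.min(abs(object$curves$B - 1)), ]
  cat(sprintf("  at B = 1 (tau = 0.5): sensitivity %.3f, specificity %.3f\n",
              b1$sensitivity, b1$specificity))
  invisible(object$curves)
}

#' @export
plot.loo_eval <- function(x, ...) {
  cv <- x$curves
  plot(cv$B, cv$sensitivity, log = "x", type = "b", pch = 16, col = "firebrick",
       ylim = c(0, 1), xlab = "balance factor B", ylab = "Sn / Sp",
       main = sprintf("%s%s: AUC %.2f, AUPR %.2f", x$method,
                      if (x$flowps) " + FloWPS" else "", x$roc_auc, x$aupr),
       ...)
  graphics::lines(cv$B, cv$specificity, type = "b", pch = 17, col = "navy")
  graphics::legend("right", c("sensitivity", "specificity"),
                   col = c("firebrick", "navy"), pch = c(16, 17), bty = "n")
  invisible(x)
}
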