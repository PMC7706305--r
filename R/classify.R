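# L1-regularized logistic classification of genotype from the trait table.
#
# The optimizer minimizes   mean logistic loss + lambda * sum(|w_j|)
# with an unpenalized intercept, from a zero initialization, either by
# cyclic coordinate descent with a quadratic majorization of the per-
# coordinate curvature (default) or by proximal gradient (ISTA) with a
# spectral step size. Both are monotone in the objective; convergence is
# declared when the KKT residual of the subgradient conditions falls below
# `tol`, so the two routes agree at the (unique, for lambda > 0) optimum.

softThreshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

logisticObjective <- function(X, y, w, b, lambda) {
  eta <- drop(X %*% w) + b
  # numerically stable log(1 + exp(-yy * eta)) with yy in {-1, 1}
  m <- ifelse(y == 1, -eta, eta)
  mean(ifelse(m > 30, m, log1p(exp(m)))) + lambda * sum(abs(w))
}

#' KKT residuals of an L1 logistic solution
#'
#' For the objective mean-loss + lambda |w|_1 the optimum satisfies
#' |g_j| <= lambda where w_j = 0 and g_j = -lambda sign(w_j) otherwise
#' (g the gradient of the unpenalized mean loss); the intercept gradient is
#' zero. Returns the violation of these conditions per coefficient
#' (intercept last) — all near zero at a converged solution.
#'
#' @param model a [ClassifierModel-class].
#' @param X,y the training features (raw scale) and 0/1 labels.
#' @return numeric vector of nonnegative residuals.
#' @export
kktResiduals <- function(model, X, y) {
  Xs <- scale(X, center = model@center, scale = model@scale)
  n <- nrow(Xs)
  p <- stats::plogis(drop(Xs %*% model@weights) + model@intercept)
  g <- drop(crossprod(Xs, p - y)) / n
  w <- model@weights
  res <- ifelse(w == 0, pmax(abs(g) - model@lambda, 0),
                abs(g + model@lambda * sign(w)))
  c(res, intercept = abs(mean(p - y)))
}

fitCoordinateDescent <- function(Xs, y, lambda, tol, maxIter, init = NULL) {
  n <- nrow(Xs); d <- ncol(Xs)
  if (is.null(init)) { w <- numeric(d); b <- 0 }
  else { w <- init$w; b <- init$b }
  eta <- drop(Xs %*% w) + b
  hj <- colSums(Xs^2) / (4 * n)  # curvature upper bound per coordinate
  it <- 0L; converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    p <- stats::plogis(eta)
    gb <- mean(p - y)
    db <- -gb / 0.25
    b <- b + db; eta <- eta + db
    for (j in seq_len(d)) {
      if (hj[j] == 0) next
      p <- stats::plogis(eta)
      gj <- sum(Xs[, j] * (p - y)) / n
      wj <- softThreshold(hj[j] * w[j] - gj, lambda) / hj[j]
      if (wj != w[j]) {
        eta <- eta + (wj - w[j]) * Xs[, j]
        w[j] <- wj
      }
    }
    p <- stats::plogis(eta)
    g <- drop(crossprod(Xs, p - y)) / n
    kkt <- max(ifelse(w == 0, pmax(abs(g) - lambda, 0),
                      abs(g + lambda * sign(w))), abs(mean(p - y)))
    if (kkt <= tol) { converged <- TRUE; break }
  }
  list(w = w, b = b, iterations = it, converged = converged)
}

fitProximalGradient <- function(Xs, y, lambda, tol, maxIter) {
  n <- nrow(Xs); d <- ncol(Xs)
  # spectral norm of [1 X] by power iteration -> Lipschitz constant / 4
  v <- stats::rnorm(d + 1); v <- v / sqrt(sum(v^2))
  A <- cbind(1, Xs)
  for (i in 1:60) { v <- drop(crossprod(A, A %*% v)); v <- v / sqrt(sum(v^2)) }
  L <- drop(crossprod(A %*% v)) / 4 / n
  step <- 1 / L
  w <- numeric(d); b <- 0
  it <- 0L; converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    p <- stats::plogis(drop(Xs %*% w) + b)
    g <- drop(crossprod(Xs, p - y)) / n
    gb <- mean(p - y)
    w <- softThreshold(w - step * g, step * lambda)
    b <- b - step * gb
    p <- stats::plogis(drop(Xs %*% w) + b)
    g <- drop(crossprod(Xs, p - y)) / n
    kkt <- max(ifelse(w == 0, pmax(abs(g) - lambda, 0),
                      abs(g + lambda * sign(w))), abs(mean(p - y)))
    if (kkt <= tol) { converged <- TRUE; break }
  }
  list(w = w, b = b, iterations = it, converged = converged)
}

#' Fit the L1-regularized logistic genotype classifier
#'
#' @param X a [FeatureMatrix-class], or a numeric matrix (then `y` is
#'   required).
#' @param y 0/1 labels when `X` is a plain matrix.
#' @param lambda L1 penalty (>= 0) on the mean logistic loss.
#' @param tol convergence tolerance on the KKT residual.
#' @param maxIter maximum optimizer sweeps/iterations; non-convergence is
#'   reported with a warning and flagged on the returned model.
#' @param method "coordinate" (default) or "proximal".
#' @param standardize z-score the columns before fitting (the returned
#'   weights then live on the standardized scale; prediction undoes this).
#' @param init optional warm start, a list with `w` (standardized-scale
#'   weights) and `b`; the default is the zero initialization.
#' @return a [ClassifierModel-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 100, 2)
#' y <- as.integer(X[, 1] + rnorm(100, 0, 0.4) > 0)
#' fitL1Logistic(X, y, lambda = 0.05)
#' @export
fitL1Logistic <- function(X, y = NULL, lambda, tol = 1e-7, maxIter = 500L,
                          method = c("coordinate", "proximal"),
                          standardize = TRUE, init = NULL) {
  method <- match.arg(method)
  if (is(X, "FeatureMatrix")) { y <- X@y; X <- X@X }
  if (is.null(y)) stop("labels y are required")
  if (lambda < 0) stop("lambda must be >= 0")
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  names(ctr) <- names(scl) <- colnames(X)
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- switch(method,
    coordinate = fitCoordinateDescent(Xs, y, lambda, tol, maxIter, init),
    proximal = fitProximalGradient(Xs, y, lambda, tol, maxIter))
  if (!fit$converged)
    warning("L1 logistic fit did not reach tol in ", maxIter,
            " iterations; returning partial model")
  w <- stats::setNames(fit$w, colnames(X))
  new("ClassifierModel", weights = w, intercept = fit$b, lambda = lambda,
      center = ctr, scale = scl, converged = fit$converged,
      iterations = fit$iterations,
      objective = logisticObjective(Xs, y, fit$w, fit$b, lambda))
}

#' Predicted hsp101 probability for new samples
#'
#' @param object a [ClassifierModel-class].
#' @param newdata numeric matrix on the raw feature scale with the model's
#'   columns.
#' @param type "response" for probabilities, "class" for 0/1 labels.
#' @param ... unused.
#' @export
setMethod("predict", "ClassifierModel",
  function(object, newdata, type = c("response", "class"), ...) {
    type <- match.arg(type)
    Xs <- scale(newdata[, names(object@weights), drop = FALSE],
                center = object@center, scale = object@scale)
    pr <- stats::plogis(drop(Xs %*% object@weights) + object@intercept)
    if (type == "response") pr else as.integer(pr > 0.5)
  })

#' The smallest lambda that zeroes all weights
#'
#' At `lambda >= max_j |g_j(0)|` (gradient of the mean loss at the
#' intercept-only solution) the KKT conditions are met with all weights
#' zero.
#'
#' @param X standardizable feature matrix or [FeatureMatrix-class].
#' @param y 0/1 labels when `X` is a matrix.
#' @return scalar lambda_max.
#' @export
lambdaMax <- function(X, y = NULL) {
  if (is(X, "FeatureMatrix")) { y <- X@y; X <- X@X }
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, center = colMeans(X), scale = scl)
  max(abs(drop(crossprod(Xs, y - mean(y)))) / nrow(Xs))
}

#' Build the classification feature matrix for one treatment group
#'
#' One sample per plant-day (time pooled), one column per trait. Columns
#' that are constant within the group are dropped with a warning; samples
#' with missing trait values are dropped listwise. Standardization is NOT
#' applied here — it is fitted on training partitions only, inside
#' [fitL1Logistic()] and [cvAccuracy()].
#'
#' @param table a [TraitTable-class].
#' @param group treatment group ("control", "HS3h", "HS6h", "HS9h").
#' @param traits optional subset of trait names (default: every trait
#'   present).
#' @return a [FeatureMatrix-class].
#' @export
buildFeatures <- function(table, group, traits = NULL) {
  stopifnot(is(table, "TraitTable"))
  d <- traitData(table)
  d <- d[d$treatment == group, ]
  if (nrow(d) == 0L) stop("no observations in group ", group)
  if (is.null(traits)) traits <- sort(unique(d$trait))
  d <- d[d$trait %in% traits, ]
  key <- paste(d$plant_id, d$das, sep = "\r")
  rows <- !duplicated(key)
  ids <- d$plant_id[rows]; das <- d$das[rows]
  X <- matrix(NA_real_, sum(rows), length(traits),
              dimnames = list(NULL, traits))
  X[cbind(match(key, key[rows]), match(d$trait, traits))] <- d$value
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; ids <- ids[ok]; das <- das[ok]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant columns: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  geno <- d$genotype[rows][ok]
  new("FeatureMatrix", X = X, y = as.integer(geno == "hsp101"),
      plant = ids, das = as.integer(das))
}

# Stratified fold assignment at the plant level: every plant's days stay in
# one fold and each fold keeps both classes.
plantFolds <- function(plant, y, k, seed) {
  pl <- unique(data.frame(plant = plant, y = y))
  withSeed(seed, {
    fold <- integer(nrow(pl))
    for (cls in unique(pl$y)) {
      idx <- which(pl$y == cls)
      if (length(idx) < k)
        stop("class ", cls, " has fewer plants (", length(idx),
             ") than folds (", k, ")")
      fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
    }
    stats::setNames(fold, pl$plant)
  })
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation grouped by plant — every day of a
#' plant stays in one fold, preventing temporal leakage — with an inner
#' grouped cross-validation on each training partition to choose lambda
#' from a grid. Standardization is refit on each training partition. The
#' reported accuracy is the mean outer-fold accuracy.
#'
#' @param features a [FeatureMatrix-class].
#' @param lambdaGrid penalty grid; default: 8 values spanning three decades
#'   below the all-zero threshold [lambdaMax()].
#' @param k outer folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @param innerK inner folds for the lambda choice.
#' @param tol,maxIter optimizer settings per fit.
#' @return list: `accuracy` (mean outer-fold accuracy), `foldAccuracy`,
#'   `lambda` (chosen per outer fold), `folds` (named plant-to-fold map).
#' @export
cvAccuracy <- function(features, lambdaGrid = NULL, k = 5L, seed = 1L,
                       innerK = 3L, tol = 1e-5, maxIter = 200L) {
  stopifnot(is(features, "FeatureMatrix"), k >= 2)
  X <- features@X; y <- features@y; plant <- features@plant
  if (is.null(lambdaGrid)) {
    lmax <- lambdaMax(X, y)
    lambdaGrid <- lmax * 10^seq(-0.5, -3, length.out = 8)
  }
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  folds <- plantFolds(plant, y, k, seed)
  rowFold <- unname(folds[plant])
  gridAccuracy <- function(Xtr, ytr, Xva, yva) {
    # warm starts along the descending grid keep the path fits cheap
    warm <- NULL
    vapply(seq_along(lambdaGrid), function(i) {
      m <- suppressWarnings(
        fitL1Logistic(Xtr, ytr, lambda = lambdaGrid[i], tol = tol,
                      maxIter = maxIter, init = warm))
      warm <<- list(w = unname(m@weights), b = m@intercept)
      mean(predict(m, Xva, type = "class") == yva)
    }, numeric(1))
  }
  foldAcc <- numeric(k); foldLam <- numeric(k)
  for (f in seq_len(k)) {
    tr <- rowFold != f
    inFolds <- plantFolds(plant[tr], y[tr], innerK, childSeed(seed, f))
    inRow <- unname(inFolds[plant[tr]])
    acc <- rowMeans(vapply(seq_len(innerK), function(g) {
      itr <- inRow != g
      gridAccuracy(X[tr, , drop = FALSE][itr, , drop = FALSE], y[tr][itr],
                   X[tr, , drop = FALSE][!itr, , drop = FALSE], y[tr][!itr])
    }, numeric(length(lambdaGrid))))
    best <- which.max(acc)   # ties resolve to the sparser (larger) lambda
    foldLam[f] <- lambdaGrid[best]
    m <- suppressWarnings(
      fitL1Logistic(X[tr, , drop = FALSE], y[tr], lambda = foldLam[f],
                    tol = tol, maxIter = maxIter))
    foldAcc[f] <- mean(predict(m, X[!tr, , drop = FALSE], type = "class") ==
                         y[!tr])
  }
  list(accuracy = mean(foldAcc), foldAccuracy = foldAcc, lambda = foldLam,
       folds = folds)
}

#' Serialize a fitted classifier to JSON
#'
#' Writes weights, intercept, penalty and the standardization parameters so
#' a fit can be archived next to its report and reapplied elsewhere.
#'
#' @param model a [ClassifierModel-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClassifierJSON <- function(model, path) {
  stopifnot(is(model, "ClassifierModel"))
  jsonlite::write_json(list(
    weights = as.list(model@weights), intercept = model@intercept,
    lambda = model@lambda, center = as.list(model@center),
    scale = as.list(model@scale), converged = model@converged,
    iterations = model@iterations, objective = model@objective),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeClassifierJSON
#' @return `readClassifierJSON()` returns the restored
#'   [ClassifierModel-class].
#' @export
readClassifierJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ClassifierModel", weights = unlist(j$weights),
      intercept = j$intercept, lambda = j$lambda,
      center = unlist(j$center), scale = unlist(j$scale),
      converged = j$converged, iterations = as.integer(j$iterations),
      objective = j$objective)
}

#' Rank traits by classifier weight
#'
#' Traits ordered by decreasing absolute standardized weight; ties broken
#' lexicographically; zero-weight traits excluded.
#'
#' @param model a [ClassifierModel-class].
#' @param topN number of traits to return.
#' @return character vector of trait names (possibly shorter than `topN`).
#' @export
rankTraits <- function(model, topN = 10L) {
  w <- model@weights
  w <- w[w != 0]
  if (length(w) == 0L) {
    warning("all weights are zero; no traits to rank")
    return(character(0))
  }
  ord <- order(-abs(w), names(w))
  utils::head(names(w)[ord], topN)
}
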