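# L1 logistic classification: optimizer correctness (KKT, dual routes,
# glmnet cross-check), feature construction and grouped cross-validation.

toyData <- function(n = 120, d = 6, sep = 1.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, letters[1:d]))
  y <- as.integer(X[, 1] * sep + 0.5 * X[, 2] + rnorm(n, 0, 0.5) > 0)
  list(X = X, y = y)
}

test_that("lambda above the KKT threshold zeroes all weights", {
  td <- toyData()
  lmax <- lambdaMax(td$X, td$y)
  m <- fitL1Logistic(td$X, td$y, lambda = lmax * 1.001, tol = 1e-9,
                     maxIter = 2000)
  expect_true(all(m@weights == 0))
  expect_equal(m@intercept, qlogis(mean(td$y)), tolerance = 1e-6)
  # just below the threshold at least one weight activates
  m2 <- fitL1Logistic(td$X, td$y, lambda = lmax * 0.95, tol = 1e-9,
                      maxIter = 2000)
  expect_gt(sum(m2@weights != 0), 0)
})

test_that("a separable two-feature problem reaches training accuracy 1", {
  set.seed(2)
  X <- cbind(f1 = c(rnorm(30, -3), rnorm(30, 3)), f2 = rnorm(60))
  y <- rep(c(0L, 1L), each = 30)
  m <- suppressWarnings(fitL1Logistic(X, y, lambda = 1e-3))
  expect_equal(mean(predict(m, X, type = "class") == y), 1)
})

test_that("KKT residuals at convergence stay within 10x the tolerance", {
  td <- toyData(n = 150, d = 8, seed = 3)
  for (lam in c(0.005, 0.02, 0.1)) {
    m <- fitL1Logistic(td$X, td$y, lambda = lam, tol = 1e-8, maxIter = 5000)
    expect_true(m@converged)
    expect_lt(max(kktResiduals(m, td$X, td$y)), 10 * 1e-8 + 1e-7)
    # verify the optimality conditions against a finite-difference gradient
    Xs <- scale(td$X)
    ng <- numericalGradient(Xs, td$y, unname(m@weights), m@intercept)
    w <- m@weights
    for (j in seq_along(w)) {
      if (w[j] == 0) expect_lte(abs(ng$gw[j]), lam + 1e-5)
      else expect_lt(abs(ng$gw[j] + lam * sign(w[j])), 1e-5)
    }
    expect_lt(abs(ng$gb), 1e-5)
  }
})

test_that("coordinate descent and proximal gradient find the same optimum", {
  td <- toyData(n = 100, d = 5, seed = 4)
  a <- fitL1Logistic(td$X, td$y, lambda = 0.03, tol = 1e-10, maxIter = 20000,
                     method = "coordinate")
  b <- fitL1Logistic(td$X, td$y, lambda = 0.03, tol = 1e-10, maxIter = 50000,
                     method = "proximal")
  expect_equal(unname(a@weights), unname(b@weights), tolerance = 1e-6)
  expect_equal(a@intercept, b@intercept, tolerance = 1e-6)
})

test_that("the fit agrees with glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  td <- toyData(n = 200, d = 10, seed = 5)
  Xs <- scale(td$X)
  lam <- 0.04
  m <- fitL1Logistic(Xs, td$y, lambda = lam, tol = 1e-10, maxIter = 20000,
                     standardize = FALSE)
  g <- glmnet::glmnet(Xs, td$y, family = "binomial", lambda = lam,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(m@weights), as.numeric(g$beta), tolerance = 1e-4)
  expect_equal(m@intercept, as.numeric(g$a0), tolerance = 1e-4)
})

test_that("the active set shrinks monotonically along the lambda path", {
  td <- toyData(n = 150, d = 10, seed = 6)
  grid <- lambdaMax(td$X, td$y) * 10^seq(-3, 0, length.out = 12)
  nz <- vapply(grid, function(l)
    sum(fitL1Logistic(td$X, td$y, lambda = l, tol = 1e-8,
                      maxIter = 5000)@weights != 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("the objective never increases across optimizer iterations", {
  td <- toyData(n = 80, d = 4, seed = 7)
  Xs <- scale(td$X)
  # track the objective through successive single-sweep refits (warm starts)
  lam <- 0.05
  obj <- numeric(30)
  warm <- NULL
  for (i in 1:30) {
    m <- suppressWarnings(
      fitL1Logistic(Xs, td$y, lambda = lam, tol = 0, maxIter = 1,
                    standardize = FALSE, init = warm))
    obj[i] <- m@objective
    warm <- list(w = unname(m@weights), b = m@intercept)
  }
  expect_true(all(diff(obj) <= 1e-12))
})

test_that("feature matrices carry one sample per plant-day with clean labels", {
  res <- smallTraitTable()
  fm <- buildFeatures(res$table, "HS6h")
  expect_s4_class(fm, "FeatureMatrix")
  expect_equal(nrow(fm@X), length(unique(paste(fm@plant, fm@das))))
  expect_setequal(unique(fm@y), c(0L, 1L))
  # genotype labels line up with plant ids
  expect_true(all((fm@y == 1) == grepl("^hsp101", fm@plant)))
  sub <- buildFeatures(res$table, "HS6h", traits = c("area", "QYmax"))
  expect_equal(colnames(sub@X), c("area", "QYmax"))
  expect_error(buildFeatures(res$table, "HS12h"), "no observations")
  # standardization happens at fit time, on request only
  m <- fitL1Logistic(fm, lambda = 0.05)
  Xs <- scale(fm@X, m@center, m@scale)
  expect_lt(max(abs(colMeans(Xs))), 1e-10)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-10)
})

test_that("cross-validation never splits a plant across folds and is seed-stable", {
  res <- smallTraitTable()
  fm <- buildFeatures(res$table, "HS3h")
  cv1 <- cvAccuracy(fm, k = 3, seed = 42, innerK = 2)
  cv2 <- cvAccuracy(fm, k = 3, seed = 42, innerK = 2)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$accuracy, cv2$accuracy)
  # fold map is per plant, so a plant's rows can never straddle folds
  rowFold <- cv1$folds[fm@plant]
  expect_true(all(tapply(rowFold, fm@plant,
                         function(f) length(unique(f))) == 1))
  # both classes in every fold
  pl <- unique(data.frame(p = fm@plant, y = fm@y))
  expect_true(all(table(cv1$folds[pl$p], pl$y) > 0))
})

test_that("label-independent features give chance-level accuracy", {
  set.seed(9)
  n <- 40
  X <- matrix(rnorm(n * 9 * 8), n * 9, 8,
              dimnames = list(NULL, paste0("t", 1:8)))
  plant <- rep(sprintf("p%02d", 1:n), each = 9)
  y <- rep(sample(rep(0:1, n / 2)), each = 9)
  fm <- new("FeatureMatrix", X = X, y = as.integer(y), plant = plant,
            das = rep(1:9, n))
  cv <- cvAccuracy(fm, k = 5, seed = 1)
  expect_gt(cv$accuracy, 0.3)
  expect_lt(cv$accuracy, 0.7)
})

test_that("trait ranking orders by absolute weight and drops zeros", {
  m <- new("ClassifierModel",
           weights = c(a = 0.5, b = -2, c = 0),
           intercept = 0, lambda = 0.1,
           center = c(a = 0, b = 0, c = 0), scale = c(a = 1, b = 1, c = 1),
           converged = TRUE, iterations = 1L, objective = 0)
  expect_equal(rankTraits(m), c("b", "a"))
  expect_equal(rankTraits(m, 1), "b")
  # ties break lexicographically
  m@weights <- c(b = 1, a = -1, c = 0.5)
  expect_equal(rankTraits(m), c("a", "b", "c"))
  m@weights <- c(a = 0, b = 0, c = 0)
  expect_warning(out <- rankTraits(m), "all weights")
  expect_length(out, 0)
})

test_that("classifier models round-trip through JSON", {
  td <- toyData(n = 90, d = 4, seed = 10)
  m <- fitL1Logistic(td$X, td$y, lambda = 0.03)
  fp <- tempfile(fileext = ".json")
  writeClassifierJSON(m, fp)
  back <- readClassifierJSON(fp)
  expect_equal(back@weights, m@weights, tolerance = 1e-12)
  expect_equal(back@intercept, m@intercept, tolerance = 1e-12)
  expect_equal(predict(back, td$X), predict(m, td$X), tolerance = 1e-12)
})

test_that("a single discriminative feature is ranked first almost always", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 80
    y <- rep(0:1, each = n / 2)
    X <- cbind(temperature = rnorm(n, y * 1.5, 0.5),
               matrix(rnorm(n * 6), n, 6,
                      dimnames = list(NULL, paste0("noise", 1:6))))
    m <- fitL1Logistic(X, as.integer(y), lambda = 0.05)
    r <- rankTraits(m, 3)
    if (length(r) && r[1] == "temperature") hits <- hits + 1
  }
  expect_gte(hits, 18)
})
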