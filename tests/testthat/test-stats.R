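# Group statistics: t-tests, stars, interaction models, correlations.

test_that("Student's t-test matches the pooled-variance closed form", {
  got <- studentsTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(got$statistic, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-10)

  set.seed(11)
  for (i in 1:30) {
    x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1), 0.5)
    o <- oracleTTest(x, y)
    g <- studentsTTest(x, y)
    expect_equal(g$statistic, o$t, tolerance = 1e-10)
    expect_equal(g$df, o$df)
    expect_equal(g$p, o$p, tolerance = 1e-10)
  }
})

test_that("t-test degenerate cases follow the conventions", {
  g <- studentsTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$statistic, 0)
  expect_equal(g$p, 1)
  z <- studentsTTest(c(2, 2, 2), c(2, 2))
  expect_equal(z$p, 1)
  expect_error(studentsTTest(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(studentsTTest(1, c(1, 2)), "at least 2")
  # Welch differs from pooled when variances do
  w <- studentsTTest(c(1, 2, 3), c(0, 5, 10, 15), welch = TRUE)
  s <- studentsTTest(c(1, 2, 3), c(0, 5, 10, 15))
  expect_false(isTRUE(all.equal(w$df, s$df)))
})

test_that("significance stars map the four thresholds", {
  expect_equal(significanceStars(0.03), "*")
  expect_equal(significanceStars(0.5), "")
  expect_equal(significanceStars(1e-6), "****")
  expect_equal(significanceStars(c(0.05, 0.049, 0.01, 0.009, 1e-3, 1e-4, 0)),
               c("", "*", "*", "**", "**", "***", "****"))
  expect_error(significanceStars(-0.1), "\\[0, 1\\]")
  expect_error(significanceStars(1.2), "\\[0, 1\\]")
})

makeTable <- function(df) TraitTable(df)

test_that("interaction coefficient equals the 2x2 cell-mean contrast exactly", {
  cells <- expand.grid(genotype = c("WT", "hsp101"),
                       treatment = c("control", "HS6h"),
                       rep = 1:3, stringsAsFactors = FALSE)
  mu <- c("WT.control" = 10, "hsp101.control" = 10,
          "WT.HS6h" = 8, "hsp101.HS6h" = 5)
  cells$value <- mu[paste(cells$genotype, cells$treatment, sep = ".")]
  tab <- makeTable(data.frame(
    plant_id = paste0("p", seq_len(nrow(cells))),
    genotype = cells$genotype, treatment = cells$treatment,
    das = 0L, trait = "area", value = cells$value))
  fit <- fitInteractionModel(tab, "area", "HS6h")
  expect_identical(names(fit),
                   c("intercept", "genotype", "treatment", "interaction"))
  expect_equal(fit$interaction$estimate, 5 - 8 - 10 + 10)
  expect_equal(fit$intercept$estimate, 10)
  expect_equal(fit$genotype$estimate, 0)
  expect_equal(fit$treatment$estimate, -2)
})

test_that("interaction OLS equals the normal-equation solve", {
  set.seed(21)
  g <- rep(c("WT", "hsp101"), each = 6)
  tm <- rep(rep(c("control", "HS3h"), each = 3), 2)
  v <- rnorm(12, 10)
  tab <- makeTable(data.frame(plant_id = paste0("p", 1:12), genotype = g,
                              treatment = tm, das = 0L, trait = "x",
                              value = v))
  fit <- fitInteractionModel(tab, "x", "HS3h")
  X <- cbind(1, g == "hsp101", tm == "HS3h",
             (g == "hsp101") * (tm == "HS3h"))
  beta <- oracleOLS(X, v)
  expect_equal(fit$intercept$estimate, beta[1], tolerance = 1e-10)
  expect_equal(fit$genotype$estimate, beta[2], tolerance = 1e-10)
  expect_equal(fit$treatment$estimate, beta[3], tolerance = 1e-10)
  expect_equal(fit$interaction$estimate, beta[4], tolerance = 1e-10)
})

test_that("interaction p value is null-uniform when only a genotype effect exists", {
  set.seed(31)
  ps <- replicate(400, {
    g <- rep(c("WT", "hsp101"), each = 10)
    tm <- rep(rep(c("control", "HS6h"), each = 5), 2)
    v <- rnorm(20) + (g == "hsp101") * 2
    tab <- makeTable(data.frame(plant_id = paste0("p", 1:20), genotype = g,
                                treatment = tm, das = 0L, trait = "x",
                                value = v))
    fitInteractionModel(tab, "x", "HS6h")$interaction$p
  })
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.05 - 2.5 * sqrt(0.05 * 0.95 / 400))
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 400))
})

test_that("interaction model rejects missing levels and unknown treatments", {
  tab <- makeTable(data.frame(plant_id = paste0("p", 1:4), genotype = "WT",
                              treatment = rep(c("control", "HS6h"), 2),
                              das = 0L, trait = "x", value = 1:4))
  expect_error(fitInteractionModel(tab, "x", "HS6h"), "both genotypes")
  expect_error(fitInteractionModel(tab, "x", "control"), "heat-stress level")
})

test_that("pearsonMatrix matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  pm <- pearsonMatrix(cbind(a = x, b = y))
  o <- oraclePearson(x, y)
  expect_equal(pm$r["a", "b"], 0.8)
  expect_equal(pm$r["a", "b"], o$r, tolerance = 1e-10)
  expect_equal(pm$p["a", "b"], o$p, tolerance = 1e-10)
  expect_equal(pm$n["a", "b"], 4)

  expect_equal(unname(diag(pm$r)), c(1, 1))
  expect_equal(pm$r, t(pm$r))
  # perfect anticorrelation
  pm2 <- pearsonMatrix(cbind(x, -x))
  expect_equal(pm2$r[1, 2], -1)
  expect_equal(pm2$p[1, 2], 0)
})

test_that("pearsonMatrix is affine invariant with sign flip under negation", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  a <- pearsonMatrix(X)
  Y <- X
  Y[, 1] <- 3 * X[, 1] + 7
  Y[, 2] <- -0.5 * X[, 2] + 1
  b <- pearsonMatrix(Y)
  expect_equal(b$r[1, 3], a$r[1, 3], tolerance = 1e-12)
  expect_equal(b$r[2, 3], -a$r[2, 3], tolerance = 1e-12)
  expect_equal(b$r[1, 2], -a$r[1, 2], tolerance = 1e-12)
})

test_that("zero-variance columns are flagged and skipped", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(pm <- pearsonMatrix(X), "zero-variance")
  expect_true(is.na(pm$r["a", "b"]))
  expect_equal(pm$r["a", "a"], 1)
})

test_that("cross-time correlation of a trait with itself is 1 per stratum", {
  res <- smallTraitTable()
  out <- crossTimeCorrelation(res$table, "QYmax", 0, "QYmax", 0)
  expect_equal(nrow(out), 8)  # 2 genotypes x 4 treatments
  expect_true(all(abs(out$r - 1) < 1e-12))
  expect_true(all(out$n >= 3))
})

test_that("understaffed strata are omitted with a warning", {
  d <- data.frame(plant_id = c("a", "b", "a", "b"),
                  genotype = "WT", treatment = "control",
                  das = c(0, 0, 7, 7), trait = "area", value = c(1, 2, 3, 4))
  expect_warning(out <- crossTimeCorrelation(TraitTable(d), "area", 0,
                                             "area", 7),
                 "fewer than 3")
  expect_null(out)
})
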