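# Temporal group statistics: per-day two-sample comparisons, the
# genotype x treatment interaction model, Pearson correlograms and the
# cross-time trait correlation analysis.

#' Significance stars for a p value
#'
#' `""` for p >= 0.05, then `*`, `**`, `***`, `****` for p below 0.05, 0.01,
#' 0.001 and 0.0001.
#'
#' @param p p value(s) in `[0, 1]`.
#' @return character vector of star strings.
#' @export
significanceStars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  breaks <- c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf)
  stars <- c("****", "***", "**", "*", "")
  stars[findInterval(p, breaks)]  # right-open: p = 0.05 earns no star
}

#' Two-sample Student's t-test
#'
#' Classic equal-variance two-sample t-test (Welch's correction available
#' behind a flag), as used for the per-day treated-vs-control and
#' WT-vs-hsp101 comparisons. With zero pooled variance and equal means the
#' statistic is taken as 0 (p = 1); zero pooled variance with unequal means
#' is a degenerate-variance error.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param welch use Welch's unequal-variance test instead.
#' @return object of class `StatResult`: list with `estimate` (mean of x
#'   minus mean of y), `se`, `statistic`, `df`, `p`, `stars`.
#' @export
studentsTTest <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  if (!welch && stats::var(x) + stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(estimate = 0, se = 0, statistic = 0,
                            df = length(x) + length(y) - 2, p = 1,
                            stars = ""), class = "StatResult"))
    }
    stop("zero pooled variance with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  res <- list(estimate = unname(tt$estimate[1] - tt$estimate[2]),
              se = unname(tt$stderr),
              statistic = unname(tt$statistic),
              df = unname(tt$parameter),
              p = tt$p.value,
              stars = significanceStars(tt$p.value))
  structure(res, class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("estimate %.4g (se %.3g), t = %.4g, df = %.4g, p = %.3g %s\n",
              x$estimate, x$se, x$statistic, x$df, x$p, x$stars))
  invisible(x)
}

#' Genotype-by-treatment interaction model for one trait
#'
#' Ordinary least squares fit of
#' `value ~ genotype + treatment + genotype:treatment` for one heat-stress
#' level against control, with treatment-contrast coding and WT / control as
#' the reference levels — the per-stress-level interaction test of the
#' analysis. Observations are plant-day values of the trait, pooled over
#' days unless `das` restricts them.
#'
#' @param table a [TraitTable-class].
#' @param trait trait name.
#' @param treatment the heat-stress level to compare against control
#'   ("HS3h", "HS6h" or "HS9h").
#' @param das optional day (or days) to restrict to.
#' @return named list of `StatResult` objects for the coefficients
#'   `intercept`, `genotype`, `treatment` and `interaction`.
#' @export
fitInteractionModel <- function(table, trait, treatment, das = NULL) {
  stopifnot(is(table, "TraitTable"))
  if (!treatment %in% c("HS3h", "HS6h", "HS9h"))
    stop("treatment must be one heat-stress level")
  d <- traitData(table)
  d <- d[d$trait == trait & d$treatment %in% c("control", treatment), ]
  if (!is.null(das)) d <- d[d$das %in% das, ]
  if (nrow(d) == 0L) stop("no observations for this trait/treatment")
  d$genotype <- factor(d$genotype, levels = GENOTYPES)
  d$treatment <- factor(d$treatment, levels = c("control", treatment))
  if (nlevels(droplevels(d$genotype)) < 2 || nlevels(droplevels(d$treatment)) < 2)
    stop("both genotypes and both treatment levels must be present")
  fit <- stats::lm(value ~ genotype + treatment + genotype:treatment, data = d)
  # summary.lm warns on noiseless saturated fits; the coefficients are exact
  sm <- suppressWarnings(summary(fit))$coefficients
  if (nrow(sm) < 4 || any(is.na(stats::coef(fit))))
    stop("singular design: interaction model is rank deficient")
  dfres <- fit$df.residual
  out <- lapply(seq_len(4), function(i) {
    p <- sm[i, 4]  # NaN on a saturated noiseless fit (zero residual variance)
    structure(list(estimate = sm[i, 1], se = sm[i, 2], statistic = sm[i, 3],
                   df = dfres, p = p,
                   stars = if (is.finite(p)) significanceStars(p)
                           else NA_character_),
              class = "StatResult")
  })
  names(out) <- c("intercept", "genotype", "treatment", "interaction")
  out
}

#' Pearson correlation matrix with t-distribution p values
#'
#' Pairwise-complete Pearson correlations between the columns of a matrix,
#' with two-sided p values from t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees
#' of freedom. Zero-variance columns are flagged with a warning and their
#' pairs reported as NA.
#'
#' @param x numeric matrix, observations x variables.
#' @return list of class `CorrelationMatrix` with matrices `r`, `p`
#'   and `n`.
#' @export
pearsonMatrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two columns")
  nobs <- crossprod(!is.na(x))
  if (any(nobs[upper.tri(nobs)] < 3))
    warning("some pairs have fewer than 3 complete observations")
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sds) | sds == 0
  if (any(bad))
    warning("zero-variance columns skipped: ",
            paste(colnames(x)[bad], collapse = ", "))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[bad, ] <- NA; r[, bad] <- NA
  diag(r)[!bad] <- 1
  tstat <- r * sqrt(pmax(nobs - 2, 0) / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(nobs - 2, 1))
  p[abs(r) >= 1] <- 0
  diag(p)[!bad] <- 0
  structure(list(r = r, p = p, n = nobs), class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("CorrelationMatrix over", ncol(x$r), "variables\n")
  print(round(x$r, 3))
  invisible(x)
}

# Wide (plants x 1) extraction of one trait at one day.
traitAt <- function(d, trait, das) {
  sel <- d[d$trait == trait & d$das == das, c("plant_id", "value")]
  stats::setNames(sel$value, sel$plant_id)
}

#' Cross-time correlation between two traits
#'
#' Pearson correlation, per genotype x treatment stratum (or any custom
#' stratification), between trait A measured at one day and trait B measured
#' at another — e.g. photochemical quenching on the stress day against
#' rosette area a week later. Strata with fewer than 3 plants carrying both
#' observations are omitted with a warning.
#'
#' @param table a [TraitTable-class].
#' @param traitA,traitB trait names.
#' @param dasA,dasB the day each trait is taken at.
#' @param by stratification columns (subset of genotype, treatment);
#'   `character(0)` pools everything.
#' @return data.frame with one row per stratum: the stratum labels, `r`,
#'   `p`, `n`.
#' @export
crossTimeCorrelation <- function(table, traitA, dasA, traitB, dasB,
                                 by = c("genotype", "treatment")) {
  stopifnot(is(table, "TraitTable"))
  d <- traitData(table)
  meta <- unique(d[, c("plant_id", "genotype", "treatment")])
  strata <- if (length(by)) split(meta, meta[by], drop = TRUE) else list(all = meta)
  rows <- lapply(names(strata), function(sn) {
    ids <- strata[[sn]]$plant_id
    a <- traitAt(d[d$plant_id %in% ids, ], traitA, dasA)
    b <- traitAt(d[d$plant_id %in% ids, ], traitB, dasB)
    common <- intersect(names(a), names(b))
    if (length(common) < 3) {
      warning("stratum ", sn, " has fewer than 3 plants with both traits; omitted")
      return(NULL)
    }
    ct <- stats::cor.test(a[common], b[common], method = "pearson")
    cbind(strata[[sn]][1, by, drop = FALSE],
          data.frame(r = unname(ct$estimate), p = ct$p.value,
                     n = length(common), row.names = NULL))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-time correlation grid (correlogram) between two traits
#'
#' Runs [crossTimeCorrelation()] over the full DAS x DAS grid, producing the
#' long-format table behind a trait-vs-trait correlogram.
#'
#' @inheritParams crossTimeCorrelation
#' @param daysA,daysB DAS grids for each trait.
#' @return long data.frame: stratum labels, `dasA`, `dasB`, `r`, `p`, `n`.
#' @export
crossTimeGrid <- function(table, traitA, traitB, daysA, daysB,
                          by = c("genotype", "treatment")) {
  combos <- expand.grid(dasA = daysA, dasB = daysB)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    res <- crossTimeCorrelation(table, traitA, combos$dasA[i],
                                traitB, combos$dasB[i], by)
    if (is.null(res) || nrow(res) == 0L) return(NULL)
    cbind(res, dasA = combos$dasA[i], dasB = combos$dasB[i])
  })
  do.call(rbind, out)
}

#' Per-day group comparison of one trait
#'
#' Student's t-test of a target group against a reference group at every
#' imaging day — the per-day starred comparisons of the temporal analysis.
#'
#' @param table a [TraitTable-class].
#' @param trait trait name.
#' @param groupA,groupB named lists selecting the two groups, e.g.
#'   `list(genotype = "WT", treatment = "HS6h")`.
#' @param adjust optional p-value adjustment method (see
#'   [stats::p.adjust()]); default "none", matching per-day starring.
#' @return data.frame with das, estimate, se, t, df, p, stars.
#' @export
compareByDay <- function(table, trait, groupA, groupB, adjust = "none") {
  stopifnot(is(table, "TraitTable"))
  d <- traitData(table)
  d <- d[d$trait == trait, ]
  pick <- function(g) {
    sel <- rep(TRUE, nrow(d))
    for (f in names(g)) sel <- sel & d[[f]] == g[[f]]
    d[sel, ]
  }
  da <- pick(groupA); db <- pick(groupB)
  days <- sort(intersect(unique(da$das), unique(db$das)))
  rows <- lapply(days, function(day) {
    x <- da$value[da$das == day]; y <- db$value[db$das == day]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    r <- studentsTTest(x, y)
    data.frame(das = day, estimate = r$estimate, se = r$se, t = r$statistic,
               df = r$df, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = adjust)
  out$stars <- significanceStars(out$p)
  out
}
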