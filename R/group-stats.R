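#' Hemispheric asymmetry score
#'
#' `AS(X) = 100 * (X_R - X_L) / (X_R + X_L)`. Negative values indicate a
#' leftward advantage of the graph metric X, positive values a rightward
#' advantage; for nonnegative inputs the score is bounded in \[-100, 100\]
#' and is antisymmetric under swapping the hemispheres. When both inputs
#' are zero the score is undefined and returned as NA with a warning.
#'
#' @param xRight,xLeft nonnegative metric values for the right and left
#'   hemispheric networks (vectorized).
#' @return numeric vector of asymmetry scores in percent units.
#' @examples
#' asymmetryScore(3, 1)  # 50: rightward
#' @export
asymmetryScore <- function(xRight, xLeft) {
  tot <- xRight + xLeft
  bad <- !is.na(tot) & tot == 0
  if (any(bad)) warning(sum(bad), " asymmetry score(s) undefined (both hemispheres zero)")
  out <- 100 * (xRight - xLeft) / tot
  out[bad] <- NA_real_
  out
}

## --- internal helpers -----------------------------------------------------

## Covariate design matrix: centered numeric columns; sex coded 0/1.
.covariateMatrix <- function(df, covariates) {
  if (!length(covariates)) return(NULL)
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  cols <- lapply(covariates, function(cv) {
    x <- df[[cv]]
    if (is.character(x) || is.factor(x)) x <- as.numeric(factor(x)) - 1
    if (anyNA(x)) stop("missing values in covariate '", cv, "'")
    x - mean(x)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  qrm <- qr(cbind(1, m))
  if (qrm$rank < ncol(m) + 1) stop("singular covariate design")
  m
}

## Reshape a single-metric long table to one row per subject with columns
## L, R and the covariates; enforce the balanced L/R contract.
.wideMetric <- function(table, covariates) {
  need <- c("subject_id", "group", "hemisphere", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("metric table missing column(s): ", paste(miss, collapse = ", "))
  if ("metric" %in% names(table) && length(unique(table$metric)) > 1)
    stop("metric table contains multiple metrics; analyse one at a time")
  if (!all(table$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  lh <- table[table$hemisphere == "L", ]
  rh <- table[table$hemisphere == "R", ]
  if (nrow(lh) != nrow(rh) || anyDuplicated(lh$subject_id) ||
      !setequal(lh$subject_id, rh$subject_id))
    stop("each subject must contribute exactly one L and one R value")
  rh <- rh[match(lh$subject_id, rh$subject_id), ]
  wide <- data.frame(subject_id = lh$subject_id, group = lh$group,
                     L = lh$value, R = rh$value, stringsAsFactors = FALSE)
  for (cv in covariates) wide[[cv]] <- lh[[cv]]
  wide
}

## F test for the last term of an lm fit (Type III with the centered
## sum-coded designs used here): squared t of that coefficient.
.lastTermF <- function(fit, term) {
  sm <- suppressWarnings(summary(fit))$coefficients
  tv <- sm[term, "t value"]
  p <- sm[term, "Pr(>|t|)"]
  if (!is.finite(tv)) {
    ## degenerate (zero-residual) fit: no evidence against the null when
    ## the estimate itself is zero, overwhelming evidence otherwise
    if (abs(sm[term, "Estimate"]) < 1e-12) { tv <- 0; p <- 1 }
    else { tv <- Inf; p <- 0 }
  }
  list(F = tv^2, df1 = 1L, df2 = fit$df.residual, p = p)
}

## --- repeated-measures ANOVA ---------------------------------------------

#' Group-by-hemisphere repeated-measures ANOVA with covariates
#'
#' Two-level repeated-measures analysis with group (e.g. NC vs BD) as the
#' between-subject factor and hemisphere (L/R) as the within-subject
#' factor, in ANCOVA form: the between-subject group effect is tested on
#' per-subject hemisphere means adjusted for covariates; the hemisphere
#' main effect and the group-by-hemisphere interaction are tested on the
#' per-subject R - L contrasts with the same covariates. Covariates are
#' centered and the group factor is sum-to-zero coded, so with c covariates
#' and N subjects every effect is an exact F(1, N - 2 - c) test (the
#' df pattern 1, 99 for 104 subjects and 3 covariates).
#'
#' @param table long-format data.frame with columns `subject_id`, `group`,
#'   `hemisphere` (`"L"`/`"R"`), `value`, plus one column per covariate;
#'   exactly one L and one R row per subject, one metric at a time.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return data.frame with one row per effect (`group`, `hemisphere`,
#'   `interaction`) and columns `F`, `df1`, `df2`, `p`.
#' @export
mixedAnova <- function(table, covariates = character(0)) {
  wide <- .wideMetric(table, covariates)
  if (length(unique(wide$group)) != 2) stop("exactly two groups required")
  if (min(table(wide$group)) < 2) stop("each group needs at least 2 subjects")
  cm <- .covariateMatrix(wide, covariates)
  g <- ifelse(wide$group == sort(unique(wide$group))[1], 1, -1)  # sum coding
  m <- (wide$L + wide$R) / 2
  d <- wide$R - wide$L
  dfB <- if (is.null(cm)) data.frame(g = g) else data.frame(cm, g = g)
  fitB <- stats::lm(m ~ ., data = dfB)
  fitW <- stats::lm(d ~ ., data = dfB)
  resG <- .lastTermF(fitB, "g")
  resI <- .lastTermF(fitW, "g")
  resH <- .lastTermF(fitW, "(Intercept)")
  out <- data.frame(effect = c("group", "hemisphere", "interaction"),
                    F = c(resG$F, resH$F, resI$F),
                    df1 = 1L,
                    df2 = c(resG$df2, resH$df2, resI$df2),
                    p = c(resG$p, resH$p, resI$p))
  out$stars <- significanceStars(out$p)
  out
}

#' Post hoc t-tests after a significant omnibus effect
#'
#' Paired t-tests comparing hemispheres within each group (covariates are
#' subject-constant, so they cancel from the R - L differences) and
#' covariate-adjusted independent t-tests comparing groups within each
#' hemisphere (group coefficient of `lm(value ~ covariates + group)`, which
#' residualizes both the response and the group indicator on the covariates
#' with the correct degrees of freedom).
#'
#' @inheritParams mixedAnova
#' @return data.frame with columns `comparison`, `stratum`, `t`, `df`, `p`,
#'   `stars`.
#' @export
posthocTests <- function(table, covariates = character(0)) {
  wide <- .wideMetric(table, covariates)
  groups <- sort(unique(wide$group))
  rows <- list()
  for (g in groups) {
    sub <- wide[wide$group == g, ]
    if (nrow(sub) < 2) stop("group '", g, "' has fewer than 2 subjects")
    d <- sub$R - sub$L
    if (stats::sd(d) < 1e-12 * max(abs(mean(d)), 1)) {
      tv <- if (abs(mean(d)) < 1e-12) 0 else Inf
      tt <- list(statistic = tv, parameter = length(d) - 1,
                 p.value = if (tv == 0) 1 else 0)
    } else tt <- stats::t.test(sub$R, sub$L, paired = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "hemisphere_R_vs_L", stratum = g,
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  for (h in c("L", "R")) {
    sub <- wide
    sub$value <- sub[[h]]
    rows[[length(rows) + 1]] <- cbind(
      data.frame(comparison = paste0("group_", groups[2], "_vs_", groups[1]),
                 stratum = h),
      .adjustedGroupT(sub$value, sub$group, .covariateMatrix(sub, covariates)))
  }
  out <- do.call(rbind, rows)
  out$stars <- significanceStars(out$p)
  out
}

## Covariate-adjusted two-group t via lm; direction = second group (sorted)
## minus first.
.adjustedGroupT <- function(y, group, cm) {
  g <- ifelse(group == sort(unique(group))[2], 1, 0)
  df <- if (is.null(cm)) data.frame(g = g) else data.frame(cm, g = g)
  fit <- stats::lm(y ~ ., data = df)
  sm <- suppressWarnings(summary(fit))$coefficients
  tv <- sm["g", "t value"]
  p <- sm["g", "Pr(>|t|)"]
  if (!is.finite(tv)) {
    if (abs(sm["g", "Estimate"]) < 1e-12) { tv <- 0; p <- 1 }
    else { tv <- Inf; p <- 0 }
  }
  data.frame(t = tv, df = fit$df.residual, p = p)
}

#' Tests on asymmetry scores
#'
#' For each group, a one-sample t-test of the asymmetry scores against zero
#' (df = n - 1; a significant positive mean indicates rightward asymmetry),
#' plus a covariate-adjusted independent t-test for the between-group
#' difference in asymmetry. Metrics whose scores are entirely missing are
#' skipped with a message.
#'
#' @param records data.frame with columns `subject_id`, `group`,
#'   `as_value`, optionally `metric`, plus covariate columns.
#' @param covariates covariate column names for the group contrast.
#' @return data.frame with one row per (metric, test).
#' @export
asymmetryTests <- function(records, covariates = character(0)) {
  if (!"metric" %in% names(records)) records$metric <- "metric"
  out <- list()
  for (mt in unique(records$metric)) {
    sub <- records[records$metric == mt & !is.na(records$as_value), ]
    if (!nrow(sub)) {
      message("asymmetry metric '", mt, "' skipped: all values missing")
      next
    }
    groups <- sort(unique(sub$group))
    for (g in groups) {
      asv <- sub$as_value[sub$group == g]
      if (stats::sd(asv) == 0) {
        tt <- list(statistic = 0, parameter = length(asv) - 1, p.value = 1)
      } else tt <- stats::t.test(asv, mu = 0)
      out[[length(out) + 1]] <- data.frame(
        metric = mt, test = paste0("one_sample_", g),
        t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
        mean_as = mean(asv))
    }
    if (length(groups) == 2) {
      adj <- .adjustedGroupT(sub$as_value, sub$group,
                             .covariateMatrix(sub, covariates))
      out[[length(out) + 1]] <- data.frame(
        metric = mt, test = paste0("group_", groups[2], "_vs_", groups[1]),
        t = adj$t, df = adj$df, p = adj$p, mean_as = NA_real_)
    }
  }
  out <- do.call(rbind, out)
  if (!is.null(out)) out$stars <- significanceStars(out$p)
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` — the correction used for the 45 per-region
#' nodal-degree comparisons (connectivity measures are reported
#' uncorrected).
#'
#' @param pValues p-values in \[0, 1\].
#' @param m number of comparisons (defaults to `length(pValues)`).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(pValues, m = length(pValues)) {
  if (m < 1) stop("m must be at least 1")
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmin(1, m * pValues)
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Rank-transforms x and y, residualizes both rank vectors on the covariate
#' design, and correlates the residuals (Pearson). The p-value uses the
#' t approximation with df = n - 2 - c. With no (or constant) covariates
#' this reduces to the ordinary Spearman coefficient. Being rank-based, the
#' estimate is invariant to strictly monotone transforms of x or y.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of covariates (sex may be a
#'   character column).
#' @return list with `rho`, `p`, `n`, `df`; `rho` is NA for constant input
#'   or fewer than 5 complete pairs.
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  cdf <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  cc <- stats::complete.cases(x, y, if (is.null(cdf)) rep(TRUE, length(x)) else cdf)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 5) return(list(rho = NA_real_, p = NA_real_, n = n, df = NA_integer_))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; partial Spearman undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, df = NA_integer_))
  }
  cm <- NULL
  if (!is.null(cdf)) {
    cdf <- cdf[cc, , drop = FALSE]
    keep <- vapply(names(cdf), function(nm) {
      v <- cdf[[nm]]
      if (is.character(v) || is.factor(v)) length(unique(v)) > 1
      else stats::sd(v) > 0
    }, TRUE)
    if (any(keep)) cm <- .covariateMatrix(cdf, names(cdf)[keep])
  }
  rx <- rank(x); ry <- rank(y)
  if (!is.null(cm)) {
    rx <- stats::lm.fit(cbind(1, cm), rx)$residuals
    ry <- stats::lm.fit(cbind(1, cm), ry)$residuals
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  dfr <- n - 2L - if (is.null(cm)) 0L else ncol(cm)
  tv <- rho * sqrt(dfr / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tv), dfr)
  list(rho = rho, p = p, n = n, df = as.integer(dfr))
}

## --- edge-wise census ------------------------------------------------------

## Vectorized per-column two-sample t (equal variance) on matrix X
## (subjects x edges) given logical group indicator.
.colIndT <- function(X, inB) {
  n1 <- sum(!inB); n2 <- sum(inB)
  m1 <- colMeans(X[!inB, , drop = FALSE]); m2 <- colMeans(X[inB, , drop = FALSE])
  v1 <- apply(X[!inB, , drop = FALSE], 2, stats::var)
  v2 <- apply(X[inB, , drop = FALSE], 2, stats::var)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tv <- (m2 - m1) / sqrt(sp * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tv), n1 + n2 - 2)
  list(t = tv, p = p)
}

.colPairT <- function(X, Y) {
  D <- Y - X
  n <- nrow(D)
  m <- colMeans(D)
  s <- apply(D, 2, stats::var)
  tv <- m / sqrt(s / n)
  p <- 2 * stats::pt(-abs(tv), n - 1)
  list(t = tv, p = p)
}

#' Edge-wise aberrant-connection census
#'
#' For every classified edge of the hemispheric layout, tests (a) the group
#' difference in connectivity (independent t on the per-subject L/R mean of
#' the edge's FA weight, absent edges entering as true zeros), (b) the
#' hemisphere difference (paired t on the homologue-aligned left vs right
#' weights across all subjects), and (c) the group difference in the
#' edge-wise asymmetry score. Significant edges (uncorrected p < alpha, per
#' the exploratory framing of such censuses) are counted per connection
#' class, along with the proportion `100 * observed / total` per class.
#'
#' @param leftMat,rightMat numeric matrices (subjects x edges) of FA
#'   weights of the classified edges in the left and right hemispheric
#'   networks; columns follow `edgeTable(cls)` order.
#' @param groups character vector of group labels per subject (2 levels).
#' @param cls the [EdgeClassification-class] of the group-average network.
#' @param alpha per-edge significance level (default 0.05, uncorrected).
#' @return list with `edges` (per-edge t/p per test), `counts` (per class x
#'   test significant-edge counts), `proportions` (percent of each class's
#'   edges significant), `totals` (edges per class).
#' @export
edgewiseCensus <- function(leftMat, rightMat, groups, cls, alpha = 0.05) {
  ed <- edgeTable(cls)
  if (ncol(leftMat) != nrow(ed) || ncol(rightMat) != nrow(ed))
    stop("edge matrices must have one column per classified edge")
  if (nrow(leftMat) != nrow(rightMat) || nrow(leftMat) != length(groups))
    stop("subject dimensions of leftMat, rightMat and groups must agree")
  if (length(unique(groups)) != 2) stop("exactly two groups required")
  inB <- groups == sort(unique(groups))[2]
  grp <- .colIndT((leftMat + rightMat) / 2, inB)
  hem <- .colPairT(leftMat, rightMat)
  tot <- leftMat + rightMat
  AS <- 100 * (rightMat - leftMat) / tot
  AS[tot == 0] <- NA
  asg <- .naColIndT(AS, inB)
  perEdge <- data.frame(from = ed$from, to = ed$to, class = ed$class,
                        t_group = grp$t, p_group = grp$p,
                        t_hemisphere = hem$t, p_hemisphere = hem$p,
                        t_asymmetry = asg$t, p_asymmetry = asg$p)
  classes <- factor(ed$class, levels = edgeClassLevels)
  sig <- function(p) !is.na(p) & p < alpha
  counts <- rbind(group = tapply(sig(grp$p), classes, sum, default = 0L),
                  hemisphere = tapply(sig(hem$p), classes, sum, default = 0L),
                  asymmetry = tapply(sig(asg$p), classes, sum, default = 0L))
  totals <- table(classes)
  prop <- sweep(counts, 2, pmax(as.numeric(totals), 1), "/") * 100
  list(edges = perEdge, counts = counts, proportions = prop,
       totals = as.numeric(totals), alpha = alpha)
}

## Two-sample t per column with NA-tolerant group means (edges where a
## subject has no connection in either hemisphere have undefined AS).
.naColIndT <- function(X, inB) {
  tcol <- function(col) {
    a <- col[!inB]; b <- col[inB]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2 || n2 < 2) return(c(NA_real_, NA_real_))
    sp <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    if (!is.finite(se) || se < 1e-10 * max(abs(mean(a)), abs(mean(b)), 1))
      return(c(NA_real_, NA_real_))
    tv <- (mean(b) - mean(a)) / se
    c(tv, 2 * stats::pt(-abs(tv), n1 + n2 - 2))
  }
  res <- apply(X, 2, tcol)
  list(t = res[1, ], p = res[2, ])
}
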