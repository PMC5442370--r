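# Recognition-memory scoring and the reprocessing-behaviour statistics:
# d-prime with a log-linear extreme-rate correction, overnight
# consolidation (post - pre d'), Spearman and partial rank correlations,
# standardized OLS with a squared-semipartial variance decomposition, the
# stage x strength slope-interaction test with cluster-robust errors, and
# the leverage-based sensitivity filter.

#' Recognition sensitivity d'
#'
#' \code{d' = qnorm(hitRate) - qnorm(faRate)}, with rates corrected by
#' the log-linear rule \code{(count + 0.5) / (n + 1)} so perfect scores
#' stay finite.
#'
#' @param hits,falseAlarms counts of hits (of \code{nOld} old items) and
#'   false alarms (of \code{nNew} new items); vectors are accepted
#' @param nOld,nNew item counts, both > 0
#' @return numeric d' (standard-normal units)
#' @examples
#' dprime(50, 100, 25, 50)   # equal rates -> 0
#' @export
dprime <- function(hits, nOld, falseAlarms, nNew) {
  if (any(nOld <= 0) || any(nNew <= 0)) stop("nOld and nNew must be > 0")
  if (any(hits < 0 | hits > nOld) || any(falseAlarms < 0 | falseAlarms > nNew))
    stop("counts out of range")
  hr <- (hits + 0.5) / (nOld + 1)
  far <- (falseAlarms + 0.5) / (nNew + 1)
  qnorm(hr) - qnorm(far)
}

#' Score a behaviour table into per-night d' and consolidation
#'
#' @param behaviour long-format data.frame(subjectId, night, session,
#'   nOld, nNew, hits, falseAlarms) with sessions "pre" and "post"
#' @return data.frame(subjectId, night, nightId, dPre, dPost,
#'   consolidation = dPost - dPre)
#' @export
scoreBehaviour <- function(behaviour) {
  key <- paste(behaviour$subjectId, behaviour$night)
  out <- NULL
  for (k in unique(key)) {
    b <- behaviour[key == k, ]
    pre <- b[b$session == "pre", ]
    post <- b[b$session == "post", ]
    if (nrow(pre) != 1L || nrow(post) != 1L)
      stop("need exactly one pre and one post session per night: ", k)
    dPre <- dprime(pre$hits, pre$nOld, pre$falseAlarms, pre$nNew)
    dPost <- dprime(post$hits, post$nOld, post$falseAlarms, post$nNew)
    out <- rbind(out, data.frame(
      subjectId = pre$subjectId, night = pre$night,
      nightId = paste0(pre$subjectId, "_n", pre$night),
      dPre = dPre, dPost = dPost, consolidation = dPost - dPre))
  }
  rownames(out) <- NULL
  out
}

#' Reprocessing strength from a decoding result
#'
#' The strength of memory reprocessing for a night is the calibrated
#' probability the classifier assigns to the night's true condition,
#' averaged over all cross-validation repetitions.  With
#' \code{bySubject = TRUE} the two nights of each subject are averaged.
#'
#' @param result a \linkS4class{DecodingResult}
#' @param bySubject average the two nights per subject (default FALSE:
#'   one value per night)
#' @return named numeric in [0, 1]; nights absent from the analysed cell
#'   are simply absent (exclude pairwise downstream)
#' @export
reprocessingStrength <- function(result, bySubject = FALSE) {
  p <- probEstimates(result)
  if (!bySubject) return(p)
  subj <- sub("_n[12]$", "", names(p))
  tapply(p, subj, mean)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks are used for ties; the p-value comes from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param x,y paired observations (>= 5 complete pairs)
#' @return list(rho, p, n)
#' @export
spearmanRho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("rank correlation undefined for a constant vector")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) .Machine$double.xmin else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three variables, then computes the partial Pearson
#' correlation of x and y controlling for z.
#'
#' @param x,y,z paired observations
#' @return list(rho, p, n) with the t-approximation on n - 3 df
#' @export
partialSpearman <- function(x, y, z) {
  ok <- complete.cases(x, y, z)
  x <- rank(x[ok]); y <- rank(y[ok]); z <- rank(z[ok])
  n <- length(x)
  if (n < 5) stop("need at least 5 complete triples")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0)
    stop("rank correlation undefined for a constant vector")
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (1 - rxz^2 < 1e-12 || 1 - ryz^2 < 1e-12)
    stop("a variable is rank-collinear with the control; ",
         "the partial correlation is undefined")
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  p <- if (abs(rho) >= 1) .Machine$double.xmin else {
    tstat <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 3)
  }
  list(rho = rho, p = p, n = n)
}

#' Multi-stage reprocessing regression with variance decomposition
#'
#' Ordinary least squares of consolidation on the standardized
#' reprocessing strengths of several sleep stages (listwise deletion).
#' Per-predictor variance explained is the squared semipartial
#' correlation \code{t^2 (1 - R^2) / (n - p - 1)}.
#'
#' @param strengths data.frame of per-observation strengths, one column
#'   per stage (e.g. S2, SWS, REM)
#' @param consolidation overnight d' change, same length
#' @return list(coefficients = data.frame(predictor, beta, sr2, p),
#'   r2, n)
#' @export
reprocessingRegression <- function(strengths, consolidation) {
  df <- cbind(strengths, .y = consolidation)
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 10) stop("need at least 10 complete cases")
  X <- scale(as.matrix(df[, setdiff(names(df), ".y"), drop = FALSE]))
  if (kappa(crossprod(X)) > 1e6)
    stop("predictors are (near-)collinear; condition number > 1e6")
  y <- as.numeric(scale(df$.y))
  fit <- lm(y ~ X)
  sm <- summary(fit)
  cf <- sm$coefficients[-1, , drop = FALSE]
  p <- nrow(cf)
  # squared semipartial correlation of each predictor: the drop in R^2
  # when it is removed from the full model
  sr2 <- vapply(seq_len(p), function(j) {
    r2red <- if (p == 1) 0 else
      summary(lm(y ~ X[, -j, drop = FALSE]))$r.squared
    sm$r.squared - r2red
  }, 0)
  list(coefficients = data.frame(
         predictor = colnames(X), beta = unname(cf[, "Estimate"]),
         sr2 = unname(sr2), p = unname(cf[, "Pr(>|t|)"])),
       r2 = sm$r.squared, n = n)
}

#' Stage x strength slope-interaction test
#'
#' Tests whether the slope of consolidation on reprocessing strength
#' differs between two sleep stages.  Observations are stacked (two rows
#' per unit: one per stage) and consolidation is regressed on strength,
#' a stage indicator and their interaction; because the two stage
#' strengths of a unit are paired, the interaction coefficient's standard
#' error is cluster-robust by unit.
#'
#' @param strengthA,strengthB per-unit strengths of the two stages
#' @param consolidation per-unit overnight d' change
#' @param cluster cluster identifier per unit (e.g. subject); defaults to
#'   the observation index
#' @param labels stage names, used in the output
#' @return list(pInteraction, estimate = slope difference B - A, model)
#' @export
slopeInteractionTest <- function(strengthA, strengthB, consolidation,
                                 cluster = NULL,
                                 labels = c("A", "B")) {
  ok <- complete.cases(strengthA, strengthB, consolidation)
  sA <- strengthA[ok]; sB <- strengthB[ok]; y <- consolidation[ok]
  n <- length(y)
  if (n < 4) stop("need at least 4 complete units")
  cl <- if (is.null(cluster)) seq_len(n) else cluster[ok]
  dat <- data.frame(y = c(y, y), strength = c(sA, sB),
                    stage = rep(c(0, 1), each = n),
                    cluster = c(cl, cl))
  fit <- lm(y ~ strength * stage, data = dat)
  V <- sandwich::vcovCL(fit, cluster = dat$cluster)
  est <- coef(fit)[["strength:stage"]]
  seI <- sqrt(V["strength:stage", "strength:stage"])
  tstat <- est / seI
  dfres <- length(unique(cl)) - 1
  p <- 2 * pt(-abs(tstat), df = dfres)
  list(pInteraction = p, estimate = est, tstat = tstat,
       labels = labels, model = fit)
}

#' Leverage-based sensitivity filter
#'
#' Computes the hat-matrix diagonals of the simple regression of y on x
#' and drops the k most influential observations.
#'
#' @param x,y paired observations
#' @param k number of high-leverage points to remove (default 3)
#' @return integer indices of the retained observations
#' @export
leverageFilter <- function(x, y, k = 3) {
  n <- length(x)
  if (k < 0 || k >= n) stop("k must satisfy 0 <= k < n")
  if (k == 0) return(seq_len(n))
  h <- hatvalues(lm(y ~ x))
  sort(order(h, decreasing = TRUE)[-seq_len(k)])
}
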