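# Statistical battery for cohort analyses: Kruskal-Wallis, the
# Scheirer-Ray-Hare two-factor rank test, allometric (log-log) scaling fits
# with covariates, logistic occupancy regression, and coefficient of
# variation.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference (k-1 df). All-identical data
#' return H = 0, p = 1 by convention.
#'
#' @param values Numeric observations.
#' @param groups Grouping vector (coerced to factor, >= 2 non-empty levels).
#' @return A `rank_test` data frame (`effect`, `H`, `df`, `p`) with a
#'   `tie_correction` attribute.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (length(values) != length(groups)) stop("values and groups lengths differ")
  df <- nlevels(groups) - 1L
  if (length(unique(values)) == 1) {
    out <- data.frame(effect = "group", H = 0, df = df, p = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
    out <- data.frame(effect = "group", H = unname(kt$statistic),
                      df = unname(kt$parameter), p = kt$p.value)
  }
  attr(out, "tie_correction") <- anyDuplicated(values) > 0
  class(out) <- c("rank_test", "data.frame")
  out
}

.rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Scheirer-Ray-Hare two-factor rank test
#'
#' Extension of Kruskal-Wallis to a two-factor layout: all N observations are
#' ranked jointly (mid-ranks for ties), two-way ANOVA sums of squares are
#' computed on the ranks (type II in unbalanced designs), and each effect's
#' statistic is H = SS_effect / MS_total with MS_total = SS_total / (N - 1).
#' Computing MS_total from the mid-ranks applies the standard tie correction
#' exactly (for tie-free data MS_total = N(N+1)/12). Each H is referred to a
#' chi-square distribution with the effect's degrees of freedom. On a
#' one-factor layout (the other factor constant) the factor's H reduces to
#' the Kruskal-Wallis H.
#'
#' @param values Numeric observations.
#' @param factorA,factorB Factors (coerced), one observation per row.
#' @return A `rank_test` data frame with rows for `factorA`, `factorB` and
#'   the interaction (`NA` rows for effects undefined by a single-level
#'   factor).
#' @export
scheirer_ray_hare <- function(values, factorA, factorB) {
  A <- droplevels(factor(factorA))
  B <- droplevels(factor(factorB))
  N <- length(values)
  if (length(A) != N || length(B) != N) stop("factor lengths differ from values")
  if (N < 3) stop("need at least 3 observations")
  r <- rank(values)
  ss_total <- sum((r - mean(r))^2)
  dfA <- nlevels(A) - 1L
  dfB <- nlevels(B) - 1L
  dfAB <- dfA * dfB
  H <- c(NA_real_, NA_real_, NA_real_)
  if (ss_total > 0) {
    ms_total <- ss_total / (N - 1)
    one <- matrix(1, N, 1)
    Xa <- if (dfA > 0) stats::model.matrix(~A) else one
    Xb <- if (dfB > 0) stats::model.matrix(~B) else one
    Xab <- if (dfA > 0 && dfB > 0) stats::model.matrix(~A + B) else if (dfA > 0) Xa else Xb
    if (dfA > 0) H[1] <- (.rss(Xb, r) - .rss(Xab, r)) / ms_total
    if (dfB > 0) H[2] <- (.rss(Xa, r) - .rss(Xab, r)) / ms_total
    if (dfAB > 0) {
      Xfull <- stats::model.matrix(~A * B)
      H[3] <- (.rss(Xab, r) - .rss(Xfull, r)) / ms_total
    }
  } else {
    # degenerate all-tied data
    H <- c(if (dfA > 0) 0 else NA_real_,
           if (dfB > 0) 0 else NA_real_,
           if (dfAB > 0) 0 else NA_real_)
  }
  H <- pmax(H, 0)
  dfs <- c(dfA, dfB, dfAB)
  dfs[dfs == 0] <- NA_integer_
  p <- ifelse(is.na(H) | is.na(dfs), NA_real_,
              stats::pchisq(H, dfs, lower.tail = FALSE))
  out <- data.frame(effect = c("factorA", "factorB", "interaction"),
                    H = H, df = dfs, p = p)
  attr(out, "tie_correction") <- anyDuplicated(values) > 0
  class(out) <- c("rank_test", "data.frame")
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat("rank test (chi-square reference)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Allometric scaling fit
#'
#' Ordinary least squares of log10(response) on log10(body mass), optionally
#' with additional covariates (an ANCOVA when a covariate is a factor such as
#' resource level). The slope is the allometric scaling exponent.
#'
#' @param response Positive response values (e.g. cumulative space used, m²).
#' @param body_mass Positive body masses (mg dry weight).
#' @param covariates Optional data frame of covariates.
#' @param conf_level Confidence level for the exponent CI (default 0.95).
#' @return A `scaling_fit` list: `exponent`, `intercept`, `exponent_ci`,
#'   `r_squared`, `anova` (F tests), and the underlying `lm` fit.
#' @export
fit_scaling <- function(response, body_mass, covariates = NULL,
                        conf_level = 0.95) {
  n <- length(response)
  if (n < 3) stop("need at least 3 observations")
  if (length(body_mass) != n) stop("response and body_mass lengths differ")
  bad <- which(!is.finite(response) | !is.finite(body_mass) |
                 response <= 0 | body_mass <= 0)
  if (length(bad)) {
    stop("log-log fit requires positive response and mass; offending rows: ",
         paste(bad, collapse = ", "))
  }
  d <- data.frame(.logy = log10(response), .logm = log10(body_mass))
  form <- .logy ~ .logm
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    d <- cbind(d, covariates)
    form <- stats::reformulate(c(".logm", names(covariates)), response = ".logy")
  }
  fit <- stats::lm(form, data = d)
  ci <- stats::confint(fit, ".logm", level = conf_level)
  out <- list(exponent = unname(stats::coef(fit)[".logm"]),
              intercept = unname(stats::coef(fit)[1]),
              exponent_ci = as.numeric(ci),
              r_squared = summary(fit)$r.squared,
              anova = stats::anova(fit),
              conf_level = conf_level,
              fit = fit)
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("allometric scaling fit: exponent %.3f [%.3f, %.3f] (%.0f%% CI), R^2 = %.3f\n",
              x$exponent, x$exponent_ci[1], x$exponent_ci[2],
              100 * x$conf_level, x$r_squared))
  invisible(x)
}

# Firth-type penalized logistic fit (Jeffreys prior): used when ordinary ML
# meets complete separation. Newton iterations on the modified score
# U* = X'(y - p + h (1/2 - p)) with h the hat diagonal.
.firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  # drop aliased columns (rank-deficient designs, e.g. a constant covariate)
  qx <- qr(X)
  keep <- qx$pivot[seq_len(qx$rank)]
  dropped <- setdiff(seq_len(ncol(X)), keep)
  Xf <- X[, keep, drop = FALSE]
  res <- .firth_core(Xf, y, maxit, tol)
  beta <- rep(NA_real_, ncol(X))
  beta[keep] <- res$coefficients
  V <- matrix(NA_real_, ncol(X), ncol(X))
  V[keep, keep] <- res$vcov
  list(coefficients = beta, vcov = V, fitted = res$fitted, dropped = dropped)
}

.firth_core <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    XW <- X * w
    info <- crossprod(X, XW)
    infoinv <- solve(info)
    h <- rowSums((X %*% infoinv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- infoinv %*% U
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(coefficients = beta, vcov = infoinv, fitted = 1 / (1 + exp(-as.numeric(X %*% beta))))
}

#' Logistic occupancy model
#'
#' Models a binary per-bin indicator (animal in a resource patch or not)
#' as a function of elapsed time, a resource flag, and their interaction.
#' Coefficients are reported as odds ratios with Wald confidence intervals.
#' Under complete separation the maximum-likelihood fit is flagged and a
#' Firth-type penalized fit is used instead.
#'
#' @param data Data frame with columns `occupied` (0/1), `time` and
#'   `resource` (0/1 or logical).
#' @param conf_level Confidence level (default 0.95).
#' @return An `occupancy_fit` list: `odds_ratios` (point estimate + CI per
#'   term), `n`, `pseudo_r2` (McFadden), `separation` flag.
#' @export
fit_occupancy <- function(data, conf_level = 0.95) {
  need <- c("occupied", "time", "resource")
  if (!all(need %in% names(data))) {
    stop("data must have columns ", paste(need, collapse = ", "))
  }
  n <- nrow(data)
  if (n < 20) stop("need at least 20 observations")
  y <- as.numeric(data$occupied)
  if (!all(y %in% c(0, 1))) stop("occupied must be binary")
  d <- data.frame(time = as.numeric(data$time),
                  resource = as.numeric(data$resource))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ time * resource, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged || sep || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    sep <- TRUE
    X <- stats::model.matrix(~time * resource, data = d)
    ff <- .firth_logistic(X, y)
    co <- as.numeric(ff$coefficients)
    se <- sqrt(diag(ff$vcov))
    names(co) <- colnames(X)
    p_fit <- ff$fitted
  } else {
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    p_fit <- stats::fitted(fit)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  or <- data.frame(term = names(co),
                   odds_ratio = exp(co),
                   ci_lower = exp(co - z * se),
                   ci_upper = exp(co + z * se))
  eps <- 1e-12
  ll <- sum(y * log(pmax(p_fit, eps)) + (1 - y) * log(pmax(1 - p_fit, eps)))
  p0 <- mean(y)
  ll0 <- sum(y * log(max(p0, eps)) + (1 - y) * log(max(1 - p0, eps)))
  out <- list(odds_ratios = or, n = n,
              pseudo_r2 = if (ll0 < 0) 1 - ll / ll0 else NA_real_,
              separation = sep, conf_level = conf_level)
  class(out) <- "occupancy_fit"
  out
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("logistic occupancy model (n = %d%s)\n", x$n,
              if (x$separation) ", penalized: separation detected" else ""))
  print.data.frame(x$odds_ratios, row.names = FALSE, digits = 4)
  cat(sprintf("  McFadden pseudo-R^2: %.3f\n", x$pseudo_r2))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample SD (n−1 denominator) over the mean, in percent.
#'
#' @param values Numeric vector with non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || abs(m) < .Machine$double.eps) {
    stop("coefficient of variation undefined for zero mean")
  }
  100 * stats::sd(values) / m
}
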