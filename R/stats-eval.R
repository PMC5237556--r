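# Statistical screening: pooled two-sample t, Mann-Whitney U, and
# age-adjusted multiple logistic regression with Wald statistics and odds
# ratios.  The pooled (equal-variance) t is the default because it
# reproduces published summary-statistic tables computed that way; a Welch
# variant is available by flag.

#' Group summary (mean, sd, n)
#' @param x numeric vector, or pass `mean`, `sd`, `n` directly.
#' @param mean,sd,n summary statistics when `x` is missing.
#' @return An object of class `ld_group_summary`.
#' @export
group_summary <- function(x = NULL, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(x)) {
    mean <- base::mean(x); sd <- stats::sd(x); n <- length(x)
  }
  stopifnot(n >= 2, sd >= 0)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "ld_group_summary")
}

#' Two-sample t-test from group summaries
#'
#' Equal-variance (pooled) Student's t by default:
#' `sp2 = ((na-1)sa^2 + (nb-1)sb^2) / (na+nb-2)`,
#' `t = (ma-mb) / sqrt(sp2 (1/na + 1/nb))`, `df = na+nb-2`.  The CI of the
#' mean difference uses the t quantile at `df`.
#'
#' @param a,b `ld_group_summary` objects (or numeric vectors, converted).
#' @param conf confidence level for the CI of the difference.
#' @param welch if `TRUE`, use the Welch unequal-variance form with
#'   Satterthwaite df.
#' @return Object of class `ld_ttest`: `t`, `df`, `p` (two-tailed),
#'   `ci_lo`, `ci_hi`, `diff`.
#' @export
pooled_t_test <- function(a, b, conf = 0.95, welch = FALSE) {
  if (is.numeric(a)) a <- group_summary(a)
  if (is.numeric(b)) b <- group_summary(b)
  stopifnot(inherits(a, "ld_group_summary"), inherits(b, "ld_group_summary"))
  d <- a$mean - b$mean
  if (welch) {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  if (se == 0) {
    if (d == 0) {
      tstat <- 0
    } else {
      stop("degenerate zero pooled variance with unequal means")
    }
  } else {
    tstat <- d / se
  }
  tc <- stats::qt(1 - (1 - conf) / 2, df)
  structure(list(t = tstat, df = df,
                 p = 2 * stats::pt(-abs(tstat), df),
                 ci_lo = d - tc * se, ci_hi = d + tc * se, diff = d),
            class = "ld_ttest")
}

#' @export
print.ld_ttest <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.1f, p = %.4g, 95%% CI of diff (%.3f, %.3f)\n",
              x$t, x$df, x$p, x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Midranks are used for ties.  For small samples (`min(n) <= 8`, no ties)
#' the p-value is exact (full enumeration of the null distribution of U);
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x,y numeric samples.
#' @return List with `U` (statistic for `x`), `p` (two-tailed), `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(n1, n2) <= 8 && !ties) {
    # exact enumeration via the standard counting recursion
    p <- mw_exact_dp(U, n1, n2)
    return(list(U = U, p = p, method = "exact"))
  }
  N <- n1 + n2
  tt <- table(r)
  tie_term <- sum(tt^3 - tt) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  mu <- n1 * n2 / 2
  if (sigma2 == 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

# distribution of U for samples of size n1, n2 without ties; returns
# two-tailed P(|U - mu| >= |u - mu|).
mw_exact_dp <- function(u, n1, n2) {
  # count partitions: c(u; n1, n2) = c(u - n2; n1 - 1, n2) + c(u; n1, n2 - 1)
  memo <- new.env(parent = emptyenv())
  cnt <- function(u, a, b) {
    if (u < 0) return(0)
    if (a == 0) return(as.numeric(u == 0))
    if (b == 0) return(as.numeric(u == 0))
    key <- paste(u, a, b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- cnt(u - b, a - 1, b) + cnt(u, a, b - 1)
    memo[[key]] <- v
    v
  }
  maxU <- n1 * n2
  tot <- choose(n1 + n2, n1)
  probs <- vapply(0:maxU, function(k) cnt(k, n1, n2), 0) / tot
  mu <- maxU / 2
  p <- sum(probs[abs((0:maxU) - mu) >= abs(u - mu) - 1e-9])
  min(p, 1)
}

#' Odds ratios from logistic coefficients
#'
#' `OR = exp(beta)`, CI `exp(beta +/- 1.96 se)` (the fixed 1.96 normal
#' quantile, matching common clinical-table arithmetic, not profile
#' likelihood).
#'
#' @param beta,se coefficient and standard error vectors.
#' @return Data frame `or`, `or_lo`, `or_hi`.
#' @export
odds_ratios <- function(beta, se) {
  data.frame(or = exp(beta), or_lo = exp(beta - 1.96 * se),
             or_hi = exp(beta + 1.96 * se))
}

#' Multiple logistic regression via IRLS
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares);
#' standard errors from the inverse observed information; Wald chi-square
#' `(beta/se)^2` with 1 df.  Rows mirror clinical MLR tables: beta, SE,
#' Wald X2, p, OR and the 1.96-quantile OR CI.
#'
#' @param X design matrix or data frame of predictors (no intercept column;
#'   one is added, reported as `(Intercept)`).
#' @param y binary outcome: logical, 0/1, or a 2-level factor (second level
#'   = positive).
#' @param max_iter,tol IRLS iteration cap and deviance-change tolerance.
#' @return Object of class `ld_mlr`: `coefficients` data frame (`term`,
#'   `beta`, `se`, `wald_x2`, `p`, `or`, `or_lo`, `or_hi`), `converged`,
#'   `iterations`, `separation` (terms with diverging coefficients),
#'   `deviance`.
#' @export
fit_mlr <- function(X, y, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (ncol(X) > 0) {
    const <- apply(X, 2, function(c) stats::sd(c) == 0)
    if (any(const))
      stop("constant predictor column(s): ",
           paste(colnames(X)[const], collapse = ", "))
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    beta_new <- tryCatch(solve(XtW %*% Xd, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                    (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev - dev_old) < tol) { converged <- TRUE; break }
    dev_old <- dev
  }
  eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(Xd * w) %*% Xd
  cov <- tryCatch(solve(info), error = function(e) matrix(NA, p, p))
  se <- sqrt(pmax(diag(cov), 0))
  dev_final <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                        (1 - y) * log(pmax(1 - mu, 1e-12)))
  # diverging coefficients, or a saturated (zero-deviance) fit, indicate
  # quasi-complete separation
  separation <- abs(beta) > 15 |
    (dev_final < 1e-6 & abs(beta) > 1 & seq_len(p) > 1)
  if (any(separation[-1]))
    warning("possible quasi-complete separation: ",
            paste(colnames(Xd)[separation], collapse = ", "))
  wald <- (beta / se)^2
  tab <- cbind(data.frame(term = colnames(Xd), beta = beta, se = se,
                          wald_x2 = wald,
                          p = 1 - stats::pchisq(wald, df = 1),
                          stringsAsFactors = FALSE),
               odds_ratios(beta, se))
  rownames(tab) <- NULL
  structure(list(coefficients = tab, converged = converged, iterations = it,
                 separation = colnames(Xd)[separation],
                 deviance = -2 * sum(y * log(pmax(mu, 1e-12)) +
                                     (1 - y) * log(pmax(1 - mu, 1e-12)))),
            class = "ld_mlr")
}

#' @export
print.ld_mlr <- function(x, ...) {
  cat(sprintf("<ld_mlr> %s after %d IRLS iterations\n",
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Screen a feature table group-wise (summary-table style)
#'
#' For every feature column: per-group mean(sd), pooled t, df, two-tailed
#' p, 95% CI of the difference, and the Mann-Whitney U p.
#'
#' @param ft feature table from [build_feature_table()] (needs a `group`
#'   column with values `PrADG`/`HEG`).
#' @param features columns to screen; default all 23 canonical features
#'   present.
#' @return Data frame, one row per feature.
#' @export
screen_features <- function(ft, features = NULL) {
  if (is.null(features)) features <- intersect(feature_names_23(), names(ft))
  ga <- ft$group == "PrADG"; gb <- ft$group == "HEG"
  stopifnot(sum(ga) >= 2, sum(gb) >= 2)
  rows <- lapply(features, function(f) {
    xa <- ft[[f]][ga]; xb <- ft[[f]][gb]
    tt <- pooled_t_test(xa, xb)
    mw <- mann_whitney_u(xa, xb)
    data.frame(feature = f, mean_pradg = mean(xa), sd_pradg = stats::sd(xa),
               mean_heg = mean(xb), sd_heg = stats::sd(xb),
               t = tt$t, df = tt$df, p = tt$p,
               ci_lo = tt$ci_lo, ci_hi = tt$ci_hi,
               u = mw$U, p_u = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-adjusted MLR on screening-significant features
#'
#' @param ft feature table with `group` and `age`.
#' @param features predictor columns (age is always added first).
#' @return An `ld_mlr` fit with outcome 1 = PrADG.
#' @export
mlr_adjusted <- function(ft, features) {
  keep <- ft$group %in% c("PrADG", "HEG") & !is.na(ft$age)
  ft <- ft[keep, , drop = FALSE]
  X <- as.matrix(cbind(age = ft$age, ft[, features, drop = FALSE]))
  fit_mlr(X, as.numeric(ft$group == "PrADG"))
}
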