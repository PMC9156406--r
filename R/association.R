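# Association statistics: median split, baseline group comparisons,
# covariate-adjusted linear regression, Bonferroni adjustment, and the
# regression power analysis (Cohen's f^2).

#' Median split of a genetic score
#'
#' Dichotomizes scores at the sample median (standard midpoint definition).
#' Scores strictly above the median are labelled `"high"`; scores strictly
#' below, and ties at the median, are labelled `"low"` (a deterministic,
#' documented tie rule; with tied score values the two groups need not have
#' equal sizes).
#'
#' @param scores Numeric vector (>= 2 values), optionally named by
#'   individual id.
#' @return Data frame `individual_id`, `score`, `group` with attributes
#'   `median` and `sizes` (named low/high counts).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores", call. = FALSE)
  if (diff(range(scores)) == 0) {
    stop("all scores identical: median split is degenerate", call. = FALSE)
  }
  med <- median(scores)
  group <- ifelse(scores > med, "high", "low")
  ids <- names(scores) %||% as.character(seq_along(scores))
  out <- data.frame(individual_id = ids, score = as.numeric(scores),
                    group = group, stringsAsFactors = FALSE)
  structure(out, median = med,
            sizes = c(low = sum(group == "low"), high = sum(group == "high")))
}

#' Two-sample t-test from printed summary statistics
#'
#' Computes Student's or Welch's t-test directly from group means, standard
#' deviations and sizes, as needed to reproduce baseline-characteristics
#' tables that print only summaries. With `variant = "auto"` the pooled
#' test is used unless an F-ratio pretest rejects variance equality at
#' level `pretest_alpha`, in which case Welch's test (Welch-Satterthwaite
#' degrees of freedom) is used.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`sd1 > 0`, `n1 >= 2`).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variant `"welch"`, `"student"`, or `"auto"`.
#' @param pretest_alpha Level of the variance-equality F pretest used by
#'   `"auto"` (default 0.05).
#' @return List with `t`, `df`, `p` (two-sided) and the `variant` used.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("welch", "student", "auto"),
                                pretest_alpha = 0.05) {
  variant <- match.arg(variant)
  for (v in list(c(sd1, 1e-300), c(sd2, 1e-300))) {
    if (v[1] <= 0) stop("standard deviations must be > 0", call. = FALSE)
  }
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (variant == "auto") {
    f <- (sd1^2) / (sd2^2)
    p_f <- 2 * min(pf(f, n1 - 1, n2 - 1), 1 - pf(f, n1 - 1, n2 - 1))
    variant <- if (p_f < pretest_alpha) "welch" else "student"
  }
  if (variant == "welch") {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), variant = variant)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' @param a,b First row of the table (e.g. group 1 counts of the two
#'   categories).
#' @param c,d Second row.
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return List with `chi2`, `df` (= 1) and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  tab <- matrix(cells, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Covariate-adjusted linear association of a score with an outcome
#'
#' Ordinary least squares of the outcome on the genetic score, adjusting
#' for sex and population-stratification principal components. The
#' reported coefficient, standard error and two-sided p-value are those of
#' the score term.
#'
#' @param outcome Numeric outcome vector.
#' @param score Numeric genetic score vector.
#' @param sex Optional numeric/factor covariate.
#' @param pcs Optional matrix/data frame of principal components.
#' @param outcome_name Label stored in the result.
#' @return An object of class `"coex_assoc"`: list with `outcome`, `beta`,
#'   `se`, `t`, `p`, `n`, `covariates`, and the full `fit`.
#' @export
fit_linear_association <- function(outcome, score, sex = NULL, pcs = NULL,
                                   outcome_name = "outcome") {
  df <- data.frame(.outcome = outcome, score = score)
  covars <- character()
  if (!is.null(sex)) {
    df$sex <- sex
    covars <- c(covars, "sex")
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    pc_names <- colnames(pcs) %||% paste0("PC", seq_len(ncol(pcs)))
    colnames(pcs) <- pc_names
    df <- cbind(df, as.data.frame(pcs))
    covars <- c(covars, pc_names)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < ncol(df) + 2) {
    stop("too few complete cases for the model", call. = FALSE)
  }
  fit <- lm(.outcome ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients["score", ]
  structure(list(outcome = outcome_name, beta = unname(sm["Estimate"]),
                 se = unname(sm["Std. Error"]), t = unname(sm["t value"]),
                 p = unname(sm["Pr(>|t|)"]), n = nrow(df),
                 covariates = covars, fit = fit),
            class = "coex_assoc")
}

#' @export
print.coex_assoc <- function(x, ...) {
  cat(sprintf("%s ~ score + %s: beta = %.4g (se %.3g), p = %.4g, n = %d\n",
              x$outcome,
              if (length(x$covariates)) paste(x$covariates, collapse = " + ")
              else "1",
              x$beta, x$se, x$p, x$n))
  invisible(x)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p)`, applied independently for each behavioural
#' construct/cohort family.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size (>= number of p-values; defaults to their count).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  .assert_scalar_number(m, "m", 1)
  if (m < length(p)) {
    stop("family size `m` must be >= the number of p-values", call. = FALSE)
  }
  p.adjust(p, method = "bonferroni", n = m)
}

#' Power of the score term in a multiple linear regression
#'
#' Analytic power for detecting a predictor of effect size Cohen's
#' `f2` in a linear regression at sample size `n`, via the noncentrality
#' parameter `lambda = f2 * n`. Two conventions are provided:
#' the noncentral-t form (`test = "noncentral-t"`, default), where a
#' one-tailed test has power `P(T_df(ncp = sqrt(lambda)) > t_crit(alpha))`
#' with `df = n - n_terms`; and the noncentral-F form
#' (`test = "noncentral-F"`), `P(F(u, n - u - 1, ncp = lambda) > F_crit)`,
#' which corresponds to the two-sided F test of the added predictor. The
#' two conventions differ materially at small `lambda` (e.g. ~0.64 vs
#' ~0.52 at `f2 = 0.02`, `n = 202`, one-tailed alpha 0.05); choose
#' deliberately.
#'
#' @param f2 Cohen's f-squared effect size (>= 0).
#' @param n Sample size.
#' @param alpha Test level (default 0.05).
#' @param tails `"one"` or `"two"` (noncentral-t only; the F test is
#'   inherently two-sided).
#' @param test `"noncentral-t"` (default) or `"noncentral-F"`.
#' @param n_terms Model terms counted against the t degrees of freedom
#'   (default 2: intercept + score, giving `df = n - 2`).
#' @param u Numerator degrees of freedom of the F test (default 1, the
#'   single score term).
#' @return Power in \[0, 1\]. With `f2 = 0` the power equals `alpha`.
#' @export
power_analysis <- function(f2, n, alpha = 0.05, tails = c("one", "two"),
                           test = c("noncentral-t", "noncentral-F"),
                           n_terms = 2, u = 1) {
  tails <- match.arg(tails)
  test <- match.arg(test)
  .assert_scalar_number(f2, "f2", 0)
  .assert_scalar_number(n, "n", n_terms + 1)
  .assert_scalar_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  lambda <- f2 * n
  if (test == "noncentral-F") {
    df2 <- n - u - 1
    return(1 - pf(qf(1 - alpha, u, df2), u, df2, ncp = lambda))
  }
  df <- n - n_terms
  ncp <- sqrt(lambda)
  if (tails == "one") {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha / 2, df)
    (1 - pt(crit, df, ncp = ncp)) + pt(-crit, df, ncp = ncp)
  }
}

#' Monte-Carlo power of the score term by simulation
#'
#' Estimates the same power as [power_analysis()] by simulating simple
#' linear regressions: a standard-normal predictor with planted slope
#' `sqrt(f2)` against unit-variance Gaussian noise (so the population
#' f-squared equals `f2`), testing the slope at level `alpha`.
#'
#' @inheritParams power_analysis
#' @param n_reps Number of simulated regressions (default 10000).
#' @param seed Integer RNG seed.
#' @param chunk Replicates simulated per block (memory control).
#' @return Rejection proportion across replicates.
#' @export
monte_carlo_power <- function(f2, n, alpha = 0.05, tails = c("one", "two"),
                              n_reps = 10000, seed = 1L, chunk = 500) {
  tails <- match.arg(tails)
  .assert_scalar_number(f2, "f2", 0)
  b <- sqrt(f2)
  crit <- if (tails == "one") qt(1 - alpha, n - 2) else qt(1 - alpha / 2, n - 2)
  .with_seed(seed, {
    rejected <- 0L
    done <- 0L
    while (done < n_reps) {
      k <- min(chunk, n_reps - done)
      x <- matrix(rnorm(n * k), n, k)
      y <- b * x + matrix(rnorm(n * k), n, k)
      xc <- sweep(x, 2, colMeans(x))
      yc <- sweep(y, 2, colMeans(y))
      r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
      t <- r * sqrt((n - 2) / (1 - r^2))
      rejected <- rejected +
        if (tails == "one") sum(t > crit) else sum(abs(t) > crit)
      done <- done + k
    }
  })
  rejected / n_reps
}
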