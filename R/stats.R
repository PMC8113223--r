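# Inferential battery: within-subject ANOVA with Greenhouse-Geisser
# correction, paired contrasts, Bonferroni adjustment, default JZS Bayes
# factors, random-intercept logistic regression, Pearson correlations.

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical fully-within-subject decomposition for one or two within
#' factors, computed via the multivariate approach (`car::Anova` on an
#' intercept-only multivariate linear model). For every effect involving a
#' factor with more than two levels, the Greenhouse-Geisser epsilon and the
#' epsilon-corrected (fractional) degrees of freedom and p value are reported
#' alongside the uncorrected ones; two-level effects have epsilon 1 by
#' construction.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric response column (one value per subject x
#'   cell; aggregate trials to subject means first).
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Name of the subject identifier column.
#' @return Tibble of class `br_anova` with one row per effect: `effect`,
#'   `ss`, `df_num`, `df_den`, `ss_error`, `F`, `p`, `gg_epsilon`,
#'   `df_num_gg`, `df_den_gg`, `p_gg`, plus attributes `n_subjects` and
#'   `cell_means`.
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  stopifnot(length(within) %in% 1:2)
  data <- as.data.frame(data)
  for (w in within) {
    if (!is.factor(data[[w]])) data[[w]] <- factor(data[[w]])
  }
  levs <- lapply(within, function(w) levels(data[[w]]))
  names(levs) <- within
  idata <- expand.grid(levs, stringsAsFactors = TRUE)  # within[1] fastest
  want <- do.call(paste, c(lapply(idata, as.character), sep = ":"))
  cell_id <- do.call(paste, c(lapply(within, function(w) as.character(data[[w]])),
                              sep = ":"))
  subj <- factor(data[[subject]])
  cell <- factor(cell_id, levels = want)
  counts <- table(subj, cell)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    msg <- paste(sprintf("subject %s, cell %s (%d values)",
                         rownames(counts)[bad[, 1]],
                         colnames(counts)[bad[, 2]],
                         counts[bad]), collapse = "; ")
    stop("rm_anova requires exactly one value per subject x cell; offending: ",
         msg, call. = FALSE)
  }
  Y <- tapply(data[[dv]], list(subj, cell), mean)
  if (anyNA(Y)) stop("rm_anova: missing cells after reshaping", call. = FALSE)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = "III")
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  adj <- s$pval.adjustments
  effects <- setdiff(rownames(uni), "(Intercept)")
  res <- tibble::tibble(
    effect = effects,
    ss = unname(uni[effects, "Sum Sq"]),
    df_num = unname(uni[effects, "num Df"]),
    df_den = unname(uni[effects, "den Df"]),
    ss_error = unname(uni[effects, "Error SS"]),
    F = unname(uni[effects, "F value"]),
    p = unname(uni[effects, "Pr(>F)"]),
    gg_epsilon = 1, df_num_gg = unname(uni[effects, "num Df"]),
    df_den_gg = unname(uni[effects, "den Df"]),
    p_gg = unname(uni[effects, "Pr(>F)"]))
  if (!is.null(adj) && nrow(adj) > 0) {
    for (e in intersect(rownames(adj), effects)) {
      i <- match(e, res$effect)
      eps <- adj[e, "GG eps"]
      res$gg_epsilon[i] <- eps
      res$df_num_gg[i] <- res$df_num[i] * eps
      res$df_den_gg[i] <- res$df_den[i] * eps
      res$p_gg[i] <- adj[e, "Pr(>F[GG])"]
    }
  }
  attr(res, "n_subjects") <- nrow(Y)
  attr(res, "cell_means") <- colMeans(Y)
  class(res) <- c("br_anova", class(res))
  res
}

#' Greenhouse-Geisser epsilon from a cell covariance matrix
#'
#' Epsilon of the double-centered covariance of the k within-subject cell
#' scores: `tr(D)^2 / ((k-1) * tr(D^2))` with `D = C S C`, `C = I - J/k`.
#' Clamped to its theoretical range `[1/(k-1), 1]`; equals 1 under compound
#' symmetry (sphericity).
#'
#' @param S k x k sample covariance matrix of the cell scores.
#' @return Scalar epsilon.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 2 || ncol(S) != k) stop("gg_epsilon needs a k x k matrix, k >= 2",
                                  call. = FALSE)
  C <- diag(k) - 1 / k
  D <- C %*% S %*% C
  eps <- sum(diag(D))^2 / ((k - 1) * sum(D * D))
  min(1, max(1 / (k - 1), eps))
}

#' Paired t test with standardized effect size
#'
#' Classical paired t with Cohen's d_z (mean difference over the SD of the
#' differences). When all differences are exactly zero the statistic is
#' defined by continuity as t = 0, p = 1; a nonzero mean with zero variance
#' is an error.
#'
#' @param x,y Equal-length paired numeric vectors (difference taken as
#'   `x - y`).
#' @param sided `"two"` or `"one"` (one-sided tests the direction of the
#'   observed mean difference).
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `d_z`, `n`, `sided`.
#' @export
paired_t <- function(x, y, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, df = n - 1, p = 1, mean_diff = 0, d_z = 0,
                            n = n, sided = sided))
    }
    stop("paired_t: differences have zero variance but nonzero mean",
         call. = FALSE)
  }
  t <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1
  p <- if (sided == "two") 2 * stats::pt(-abs(t), df) else stats::pt(-abs(t), df)
  tibble::tibble(t = t, df = df, p = p, mean_diff = mean(d),
                 d_z = mean(d) / sd_d, n = n, sided = sided)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)`. The family size is explicit (and may exceed the number of
#' p values supplied) so that contrast families are declared, never implied
#' by vector length.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param m Family size, at least `length(pvals)`.
#' @return Adjusted p values, order-preserving.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1), m >= length(pvals))
  pmin(1, pvals * m)
}

#' Default JZS Bayes factor for a paired/one-sample t design
#'
#' BF10 for H1: effect size delta ~ Cauchy(0, `rscale`) against H0: delta = 0,
#' computed as the ratio of the marginal likelihood of the observed t
#' statistic (noncentral t with ncp = delta * sqrt(n), integrated over the
#' Cauchy prior by adaptive quadrature) to its central-t density under the
#' null.
#'
#' @param t Observed paired t statistic.
#' @param n Number of pairs.
#' @param rscale Cauchy prior scale on the standardized effect (default
#'   `sqrt(2)/2`, the conventional "medium" prior).
#' @return One-row tibble: `bf10`, `bf01`, `rscale`, `rel_error` (bound on
#'   the relative numerical-integration error).
#' @export
jzs_bf10_paired <- function(t, n, rscale = sqrt(2) / 2) {
  stopifnot(n >= 2, rscale > 0)
  df <- n - 1
  # substitute delta = rscale * tan(theta): the Cauchy prior becomes uniform
  # on (-pi/2, pi/2), giving a smooth integrand on a finite domain
  g <- function(theta) {
    suppressWarnings(
      stats::dt(t, df, ncp = rscale * tan(theta) * sqrt(n))) / pi
  }
  q <- stats::integrate(g, -pi / 2, pi / 2, rel.tol = 1e-9, abs.tol = 0,
                        subdivisions = 1000L)
  if (q$message != "OK") {
    stop("jzs_bf10_paired: numerical integration failed (", q$message, ")",
         call. = FALSE)
  }
  m1 <- q$value
  m0 <- stats::dt(t, df)
  bf10 <- m1 / m0
  rel_err <- q$abs.error / m1
  tibble::tibble(bf10 = bf10, bf01 = 1 / bf10, rscale = rscale,
                 rel_error = rel_err)
}

#' Random-intercept logistic regression for initial percepts
#'
#' Models the probability that a trial's initial percept is happy as a
#' function of the mimicry condition, with a per-subject random intercept
#' fitted by adaptive Gauss-Hermite quadrature (default 20 nodes; 1 node is
#' the Laplace approximation). The slope is the log odds ratio of a happy
#' initial percept in the blocked relative to the free condition. With
#' `random_intercept = FALSE` the model degenerates to ordinary (pooled)
#' logistic regression, whose slope is the closed-form 2x2 log odds ratio.
#'
#' @param ip_records Data frame with columns `subject`, `mimicry`
#'   (`free`/`blocked`), `ip` (`happy`/`neutral`; other values are dropped).
#' @param random_intercept Fit the subject random intercept (default) or
#'   constrain its variance to zero.
#' @param nagq Number of adaptive Gauss-Hermite quadrature nodes.
#' @return One-row tibble: `beta`, `se`, `z`, `p`, `odds_ratio`,
#'   `intercept`, `ranef_sd`, `n_subjects`, `n_trials`.
#' @export
fit_ip_logistic <- function(ip_records, random_intercept = TRUE, nagq = 20) {
  d <- as.data.frame(ip_records)
  d <- d[d$ip %in% c("happy", "neutral"), , drop = FALSE]
  d$happy <- as.integer(d$ip == "happy")
  d$mimicry <- factor(d$mimicry, levels = MIMICRY_LEVELS)
  d$subject <- factor(d$subject)
  if (nlevels(d$subject) < 2 && random_intercept) {
    stop("fit_ip_logistic: at least two subjects are required for a random intercept",
         call. = FALSE)
  }
  if (random_intercept) {
    fit <- lme4::glmer(happy ~ mimicry + (1 | subject), data = d,
                       family = stats::binomial(), nAGQ = nagq)
    co <- summary(fit)$coefficients
    ranef_sd <- sqrt(unname(lme4::VarCorr(fit)$subject[1, 1]))
  } else {
    fit <- stats::glm(happy ~ mimicry, data = d, family = stats::binomial())
    co <- summary(fit)$coefficients
    ranef_sd <- 0
  }
  beta <- co["mimicryblocked", 1]
  se <- co["mimicryblocked", 2]
  if (abs(beta) > 10 || se > 100) {
    stop("fit_ip_logistic: estimates diverged; the data are (quasi-)separated",
         call. = FALSE)
  }
  tibble::tibble(beta = beta, se = se, z = beta / se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 odds_ratio = exp(beta),
                 intercept = co["(Intercept)", 1], ranef_sd = ranef_sd,
                 n_subjects = nlevels(droplevels(d$subject)),
                 n_trials = nrow(d))
}

#' Pearson correlation with the n-2 df reporting convention
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with nonzero
#'   variance. Pairs with missing values are dropped.
#' @return One-row tibble: `r`, `df`, `p` (two-sided, from the t transform),
#'   `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_cor: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_cor: zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = n)
}
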