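# Independent oracles used by both the unit and the acceptance tests. Each
# one recomputes a quantity by a different route than the implementation:
# explicit design-matrix projections for the within-subject ANOVA, Simpson
# quadrature for the JZS Bayes factor, and a chi-square-mixture integral for
# noncentral-t power.

# classical fully-within ANOVA by explicit least squares: every effect's SS
# is the squared norm of the projection of the response onto that term's
# sum-to-zero design columns; F uses the matching effect-by-subject
# interaction as the error term
anova_projection_oracle <- function(data, dv, within, subject = "subject") {
  d <- as.data.frame(data)
  d$..S <- factor(d[[subject]])
  for (w in within) d[[w]] <- factor(d[[w]])
  rhs <- paste(c("..S", within), collapse = "*")
  ctr <- stats::setNames(rep(list("contr.sum"), length(within) + 1),
                         c("..S", within))
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d,
                            contrasts.arg = ctr)
  asg <- attr(mm, "assign")
  labs <- attr(stats::terms(stats::as.formula(paste("~", rhs))), "term.labels")
  y <- d[[dv]]
  ss_of <- function(term) {
    cols <- which(asg == match(term, labs))
    X <- mm[, cols, drop = FALSE]
    proj <- X %*% solve(crossprod(X), crossprod(X, y))
    sum(proj^2)
  }
  df_of <- function(term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    prod(vapply(parts, function(p) nlevels(d[[p]]) - 1, double(1)))
  }
  effs <- labs[!grepl("..S", labs, fixed = TRUE)]
  out <- lapply(effs, function(e) {
    err_term <- paste0("..S:", e)
    ss <- ss_of(e); ss_e <- ss_of(err_term)
    df1 <- df_of(e); df2 <- df_of(err_term)
    data.frame(effect = e, ss = ss, df_num = df1, df_den = df2,
               ss_error = ss_e, F = (ss / df1) / (ss_e / df2))
  })
  do.call(rbind, out)
}

rand_within_table <- function(n_subj, levels_list, seed) {
  set.seed(seed)
  grid <- expand.grid(c(list(subject = paste0("s", seq_len(n_subj))),
                        levels_list), stringsAsFactors = FALSE)
  grid$y <- rnorm(nrow(grid))
  grid
}

# high-resolution brute-force quadrature for the JZS Bayes factor: Simpson's
# rule on the Cauchy-substituted axis delta = r * tan(theta), >= 1e5 nodes
jzs_bf_oracle <- function(t, n, rscale = sqrt(2) / 2, nodes = 2e5 + 1) {
  df <- n - 1
  theta <- seq(-pi / 2 + 1e-9, pi / 2 - 1e-9, length.out = nodes)
  delta <- rscale * tan(theta)
  f <- suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n))) / pi
  h <- theta[2] - theta[1]
  w <- rep(c(4, 2), length.out = nodes); w[1] <- 1; w[nodes] <- 1
  m1 <- sum(w * f) * h / 3
  m1 / stats::dt(t, df)
}

# noncentral-t CDF as a chi-square mixture of normal CDFs
pnct_oracle <- function(t, df, ncp) {
  f <- function(v) stats::pnorm(t * sqrt(v / df) - ncp) * stats::dchisq(v, df)
  stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 1000L)$value
}

power_oracle <- function(n, d, alpha, sided) {
  df <- n - 1; ncp <- d * sqrt(n)
  if (sided == "one") {
    tc <- stats::qt(1 - alpha, df)
    1 - pnct_oracle(tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    (1 - pnct_oracle(tc, df, ncp)) + pnct_oracle(-tc, df, ncp)
  }
}
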