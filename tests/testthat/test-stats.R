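test_that("rm_anova matches the projection oracle on small tables", {
  cases <- list(
    list(n = 6, levs = list(content = c("a", "b", "c")), seed = 1),
    list(n = 8, levs = list(mimicry = c("free", "blocked"),
                            content = c("happy", "neutral", "mixed")), seed = 2),
    list(n = 5, levs = list(mimicry = c("free", "blocked"),
                            ip = c("happy", "neutral")), seed = 3))
  for (cs in cases) {
    tab <- rand_within_table(cs$n, cs$levs, cs$seed)
    got <- rm_anova(tab, "y", within = names(cs$levs))
    want <- anova_projection_oracle(tab, "y", within = names(cs$levs))
    for (i in seq_len(nrow(want))) {
      j <- match(want$effect[i], got$effect)
      expect_false(is.na(j))
      expect_equal(got$ss[j], want$ss[i], tolerance = 1e-8)
      expect_equal(got$ss_error[j], want$ss_error[i], tolerance = 1e-8)
      expect_equal(got$F[j], want$F[i], tolerance = 1e-8)
      expect_equal(got$df_num[j], want$df_num[i])
      expect_equal(got$df_den[j], want$df_den[i])
    }
  }
})

test_that("a two-level within factor reproduces the squared paired t", {
  tab <- rand_within_table(10, list(mimicry = c("free", "blocked")), seed = 9)
  av <- rm_anova(tab, "y", within = "mimicry")
  w <- tidyr::pivot_wider(tab, names_from = "mimicry", values_from = "y")
  tt <- paired_t(w$free, w$blocked)
  expect_lt(abs(av$F[av$effect == "mimicry"] - tt$t^2), 1e-8)
  expect_equal(av$p[av$effect == "mimicry"], tt$p, tolerance = 1e-10)
})

test_that("rm_anova reports fractional GG-corrected dfs for 3-level factors", {
  tab <- rand_within_table(28, list(mimicry = c("free", "blocked"),
                                    content = c("happy", "neutral", "mixed")),
                           seed = 4)
  av <- rm_anova(tab, "y", within = c("mimicry", "content"))
  ia <- av[av$effect == "mimicry:content", ]
  expect_true(ia$gg_epsilon > 0.5 && ia$gg_epsilon <= 1)
  expect_equal(ia$df_num_gg, 2 * ia$gg_epsilon)
  expect_equal(ia$df_den_gg, 54 * ia$gg_epsilon)
  # corrected p comes from the F distribution with the fractional dfs
  expect_equal(ia$p_gg, pf(ia$F, ia$df_num_gg, ia$df_den_gg, lower.tail = FALSE),
               tolerance = 1e-12)
  # two-level effect: epsilon pinned at 1
  expect_equal(av$gg_epsilon[av$effect == "mimicry"], 1)
})

test_that("rm_anova rejects unbalanced tables and names the offender", {
  tab <- rand_within_table(4, list(content = c("a", "b")), seed = 5)
  expect_error(rm_anova(tab[-1, ], "y", within = "content"), "s1")
})

test_that("gg_epsilon matches the closed-form Box formula and its bounds", {
  box_eps <- function(S) {
    k <- nrow(S)
    sbar_d <- mean(diag(S)); sbar <- mean(S); rowm <- rowMeans(S)
    (k * (sbar_d - sbar))^2 /
      ((k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * sbar^2))
  }
  # hand-derived value for diag(1, 1, 10): 64 / 100
  S <- diag(c(1, 1, 10))
  expect_equal(gg_epsilon(S), 0.64)
  expect_equal(gg_epsilon(S), box_eps(S))
  # compound symmetry -> sphericity -> epsilon 1
  cs <- matrix(0.3, 4, 4); diag(cs) <- 1
  expect_equal(gg_epsilon(cs), 1)
  # random covariances: agreement with the formula, and the k = 3 lower bound
  set.seed(8)
  for (i in 1:20) {
    X <- matrix(rnorm(30), 10, 3)
    S <- cov(X)
    expect_equal(gg_epsilon(S), min(1, max(0.5, box_eps(S))), tolerance = 1e-12)
    expect_gte(gg_epsilon(S), 0.5)
  }
})

test_that("gg_epsilon agrees with the epsilon rm_anova extracts", {
  tab <- rand_within_table(12, list(content = c("a", "b", "c")), seed = 10)
  av <- rm_anova(tab, "y", within = "content")
  w <- tapply(tab$y, list(tab$subject, tab$content), mean)
  expect_equal(av$gg_epsilon[av$effect == "content"], gg_epsilon(cov(w)),
               tolerance = 1e-10)
})

test_that("paired_t matches hand arithmetic and its symmetries", {
  # diffs 1,2,3,4: t = 2.5 / (sd/2) = 3.872983..., df 3
  x <- c(1, 2, 3, 4); y <- c(0, 0, 0, 0)
  tt <- paired_t(x, y)
  expect_equal(tt$t, 2.5 / (sd(x) / 2), tolerance = 1e-12)
  expect_equal(tt$t, 3.872983, tolerance = 1e-6)
  expect_equal(tt$df, 3)
  expect_equal(tt$d_z, 2.5 / sd(x), tolerance = 1e-12)
  # x = y: defined by continuity
  tt0 <- paired_t(y, y)
  expect_equal(tt0$t, 0); expect_equal(tt0$p, 1)
  # sign flip negates t, two-sided p unchanged
  flip <- paired_t(y, x)
  expect_equal(flip$t, -tt$t)
  expect_equal(flip$p, tt$p)
  # nonzero constant difference: zero variance error
  expect_error(paired_t(x + 1, x), "zero variance")
})

test_that("bonferroni adjustment clamps, scales, and preserves order", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04), m = 2), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.9, m = 3), 1)
  set.seed(3)
  p <- runif(10, 0, 1 / 15)  # below the clamp for m = 12
  expect_equal(rank(bonferroni_adjust(p, m = 12)), rank(p))
  # with clamping the map is still weakly order-preserving
  p2 <- runif(10)
  adj <- bonferroni_adjust(p2, m = 12)
  expect_true(all(diff(adj[order(p2)]) >= 0))
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "m >= length")
})

test_that("the JZS Bayes factor matches a high-resolution quadrature oracle", {
  for (case in list(c(2.5, 28), c(0.5, 10), c(4, 100), c(1.5, 28))) {
    got <- jzs_bf10_paired(case[1], case[2])
    want <- jzs_bf_oracle(case[1], case[2])
    expect_lt(abs(got$bf10 - want) / want, 1e-6)
    expect_lt(got$rel_error, 1e-6)
    expect_equal(got$bf10 * got$bf01, 1)
  }
})

test_that("the JZS Bayes factor favours the null at t = 0 and is monotone in |t|", {
  expect_lt(jzs_bf10_paired(0, 30)$bf10, 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(t) jzs_bf10_paired(t, 28)$bf10, double(1))
  expect_true(all(diff(bfs) > 0))
  # symmetric in the sign of t
  expect_equal(jzs_bf10_paired(-2.5, 28)$bf10, jzs_bf10_paired(2.5, 28)$bf10,
               tolerance = 1e-9)
})

test_that("the pooled logistic slope equals the closed-form 2x2 log odds ratio", {
  counts <- list(blocked = c(happy = 304, neutral = 128),
                 free = c(happy = 317, neutral = 113))
  rec <- do.call(rbind, lapply(names(counts), function(mim) {
    data.frame(subject = "pool", mimicry = mim,
               ip = rep(names(counts[[mim]]), counts[[mim]]))
  }))
  fit <- fit_ip_logistic(rec, random_intercept = FALSE)
  beta_closed <- log((304 / 128) / (317 / 113))
  expect_equal(fit$beta, beta_closed, tolerance = 1e-6)
  expect_equal(round(fit$beta, 4), -0.1665)  # odds ratio about 0.85
  expect_equal(fit$odds_ratio, exp(beta_closed), tolerance = 1e-6)
})

test_that("perfectly balanced counts give a zero slope and unit odds ratio", {
  rec <- expand.grid(subject = paste0("s", 1:6),
                     mimicry = c("free", "blocked"),
                     ip = rep(c("happy", "neutral"), 4),
                     stringsAsFactors = FALSE)
  pooled <- fit_ip_logistic(rec, random_intercept = FALSE)
  expect_equal(pooled$beta, 0, tolerance = 1e-10)
  expect_equal(pooled$odds_ratio, 1, tolerance = 1e-10)
  mixed <- fit_ip_logistic(rec)
  expect_equal(mixed$beta, 0, tolerance = 1e-6)
})

test_that("the mixed fit reduces to the pooled fit when subjects are homogeneous", {
  set.seed(42)
  d <- expand.grid(subject = paste0("s", 1:20), trial = 1:20,
                   mimicry = c("free", "blocked"), stringsAsFactors = FALSE)
  eta <- 0.9 - 0.2 * (d$mimicry == "blocked")
  d$ip <- ifelse(runif(nrow(d)) < plogis(eta), "happy", "neutral")
  mixed <- fit_ip_logistic(d)
  pooled <- fit_ip_logistic(d, random_intercept = FALSE)
  expect_lt(mixed$ranef_sd, 0.25)
  expect_equal(mixed$beta, pooled$beta, tolerance = 0.02)
})

test_that("separated data raise an informative error", {
  rec <- data.frame(subject = rep(c("s1", "s2"), each = 8),
                    mimicry = rep(c("free", "blocked"), 8),
                    ip = ifelse(rep(c("free", "blocked"), 8) == "free",
                                "happy", "neutral"))
  expect_error(fit_ip_logistic(rec, random_intercept = FALSE), "separat")
})

test_that("pearson_cor follows the n-2 df convention and rejects degenerate input", {
  x <- rnorm(28)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_equal(pearson_cor(x, rnorm(28))$df, 26)
  expect_error(pearson_cor(x, rep(1, 28)), "zero variance")
  # agreement with cor.test p value
  set.seed(2); y <- rnorm(28)
  expect_equal(pearson_cor(x, y)$p, cor.test(x, y)$p.value)
})
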