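# ANOVA, Tukey letters, correlations and the CAR~RSLR model.

anova_oracle <- function(values, group) {
  # brute-force sum-of-squares decomposition
  g <- split(values, group)
  grand <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the sum-of-squares oracle and its invariances", {
  expect_equal(oneway_anova(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3))$F, 0)
  set.seed(71)
  for (case in 1:5) {
    k <- sample(2:4, 1)
    n <- sample(5:12, k, replace = TRUE)
    values <- unlist(lapply(n, function(m) rnorm(m, runif(1, 0, 5))))
    group <- rep(letters[seq_len(k)], times = n)
    got <- oneway_anova(values, group)
    want <- anova_oracle(values, group)
    expect_equal(got$F, want$F)
    expect_equal(got$p, want$p)
    shifted <- oneway_anova(values + 100, group)
    expect_equal(shifted$F, got$F)
  }
  expect_error(oneway_anova(rep(1, 6), rep(c("a", "b"), 3)), "degenerate")
})

test_that("Tukey letters share a letter iff groups are not significantly different", {
  set.seed(72)
  same <- rnorm(30)
  r <- tukey_hsd(rep(same[1:10], 3), rep(c("a", "b", "c"), each = 10))
  expect_true(all(r$letters == r$letters[1]))
  far <- c(rnorm(10, 0, 1), rnorm(10, 100, 1))
  r2 <- tukey_hsd(far, rep(c("lo", "hi"), each = 10))
  expect_false(r2$letters[["lo"]] == r2$letters[["hi"]])
  # middle group overlapping both extremes gets both letters
  vals <- c(rnorm(15, 0, 2), rnorm(15, 3.6, 2), rnorm(15, 7, 2))
  grp <- rep(c("a", "m", "b"), each = 15)
  r3 <- tukey_hsd(vals, grp)
  pw <- r3$pairwise
  for (i in seq_len(nrow(pw))) {
    l1 <- r3$letters[[pw$group1[i]]]
    l2 <- r3$letters[[pw$group2[i]]]
    share <- length(intersect(strsplit(l1, "")[[1]],
                              strsplit(l2, "")[[1]])) > 0
    expect_equal(share, pw$p_adj[i] >= 0.05)
  }
})

test_that("Tukey pairwise p-values agree with a max-T permutation oracle", {
  set.seed(73)
  n <- 20
  vals <- c(rnorm(n, 0), rnorm(n, 0.6), rnorm(n, 1.1))
  grp <- rep(c("a", "b", "c"), each = n)
  got <- tukey_hsd(vals, grp)$pairwise
  # permutation distribution of the studentized range (max-T over pairs)
  B <- 20000
  k <- 3
  stat_range <- function(v, g) {
    m <- tapply(v, g, mean)
    s2 <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (3 * n - k)
    (max(m) - min(m)) / sqrt(s2 / n)
  }
  qobs <- vapply(seq_len(nrow(got)), function(i) {
    a <- got$group1[i]; b <- got$group2[i]
    m <- tapply(vals, grp, mean)
    s2 <- sum(tapply(vals, grp, function(x) sum((x - mean(x))^2))) / (3 * n - k)
    abs(m[[a]] - m[[b]]) / sqrt(s2 / n)
  }, numeric(1))
  perm <- vapply(seq_len(B), function(b) stat_range(vals, sample(grp)),
                 numeric(1))
  p_perm <- vapply(qobs, function(q) mean(perm >= q), numeric(1))
  expect_true(all(abs(p_perm - got$p_adj) < 0.05))
})

test_that("Pearson and partial correlations behave and match oracles", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  set.seed(74)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50); z0 <- rnorm(50)
  # control exactly orthogonal to both -> partial equals plain Pearson
  z_orth <- residuals(lm(z0 ~ x + y))
  expect_equal(partial_r(x, y, z_orth)$r, pearson_r(x, y)$r,
               tolerance = 1e-12)
  # residual-on-residual regression oracle on random triples
  for (case in 1:5) {
    a <- rnorm(40); b <- rnorm(40) + 0.4 * a; c <- rnorm(40) + 0.3 * a
    got <- partial_r(a, b, c)
    want <- cor(residuals(lm(a ~ c)), residuals(lm(b ~ c)))
    expect_equal(got$r, want, tolerance = 1e-10)
    # symmetry in x and y
    expect_equal(partial_r(b, a, c)$r, got$r)
    expect_true(abs(got$r) <= 1)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("the CAR~RSLR model recovers an exact linear law in every fit mode", {
  d <- tibble::tibble(rslr_mm_yr = rep(seq(1, 10, length.out = 10), 3),
                      source_id = rep(c("s1", "s2", "s3"), each = 10))
  d$car_gC_m2_yr <- 30 * d$rslr_mm_yr
  for (mode in c("ols", "cluster_robust", "random_intercept")) {
    m <- suppressMessages(suppressWarnings(fit_car_rslr(d, mode)))
    expect_equal(m$slope, 30, tolerance = 1e-6)
    expect_equal(m$intercept, 0, tolerance = 1e-6)
    expect_equal(m$fit_mode, mode)
  }
})

test_that("the OLS slope equals cov/var and is invariant to duplicating the data", {
  set.seed(75)
  d <- tibble::tibble(rslr_mm_yr = runif(40, 1, 9), source_id = "s1")
  d$car_gC_m2_yr <- 100 + 20 * d$rslr_mm_yr + rnorm(40, 0, 30)
  m <- fit_car_rslr(d, "ols")
  expect_equal(m$slope, cov(d$car_gC_m2_yr, d$rslr_mm_yr) /
                 var(d$rslr_mm_yr))
  dup <- rbind(d, d)
  expect_equal(fit_car_rslr(dup, "ols")$slope, m$slope)
  flat <- d
  flat$rslr_mm_yr <- 5
  expect_error(fit_car_rslr(flat), "unidentifiable")
})

test_that("cluster-robust SEs differ from OLS SEs under source-level intercepts", {
  set.seed(76)
  src <- rep(sprintf("s%02d", 1:20), each = 6)
  eff <- rep(rnorm(20, 0, 50), each = 6)
  d <- tibble::tibble(rslr_mm_yr = runif(120, 1, 9), source_id = src)
  d$car_gC_m2_yr <- 80 + 25 * d$rslr_mm_yr + eff + rnorm(120, 0, 20)
  m_ols <- fit_car_rslr(d, "ols")
  m_cl <- fit_car_rslr(d, "cluster_robust")
  expect_equal(m_cl$slope, m_ols$slope) # same point estimate
  expect_false(isTRUE(all.equal(m_cl$slope_se, m_ols$slope_se)))
})

test_that("the correlation table reports the CAR/SAR/C-density triangle as partials", {
  sites <- generate_sites(small_config(seed = 19))
  ct <- correlation_table(sites)
  expect_true(all(c("pearson", "partial") %in% ct$type))
  row <- ct[ct$var1 == "car" & ct$var2 == "sar", ]
  expect_equal(row$type, "partial")
  want <- partial_r(sites$car_gC_m2_yr, sites$sar_mm_yr,
                    sites$c_density_gC_cm3)
  expect_equal(row$r, want$r)
  prow <- ct[ct$var1 == "car" & ct$var2 == "rslr", ]
  expect_equal(prow$type, "pearson")
  expect_equal(prow$r, pearson_r(sites$car_gC_m2_yr, sites$rslr_mm_yr)$r)
})
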