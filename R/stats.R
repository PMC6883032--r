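# Statistical surface: one-way ANOVA, Tukey HSD with compact letter display,
# Pearson / first-order partial correlation, and the CAR~RSLR model with
# OLS, cluster-robust, or random-intercept fits.

check_grouped <- function(values, group) {
  stopifnot(length(values) == length(group))
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- factor(group[ok])
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  list(values = values, group = group)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()], as used for
#' the vegetation / region / state group comparisons of CAR, SAR and carbon
#' density.
#'
#' @param values Numeric response vector.
#' @param group Grouping factor (>= 2 groups, each with n >= 2).
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' oneway_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$F # 0
oneway_anova <- function(values, group) {
  g <- check_grouped(values, group)
  if (sd(g$values) == 0) {
    stop("all values identical; ANOVA is degenerate", call. = FALSE)
  }
  fit <- aov(g$values ~ g$group)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p = tab[1, "Pr(>F)"])
}

# Compact letter display by insert-and-absorb on a logical "significantly
# different" matrix; groups ordered by decreasing mean get letters first.
cld_from_signif <- function(signif, means) {
  k <- nrow(signif)
  ord <- order(-means)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!signif[i, j]) next
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        sets <- c(sets, list(setdiff(sets[[s]], i)),
                  list(setdiff(sets[[s]], j)))
        sets[[s]] <- NULL
        # absorb: drop sets contained in another
        keep <- rep(TRUE, length(sets))
        for (a in seq_along(sets)) for (b in seq_along(sets)) {
          if (a != b && keep[a] && all(sets[[a]] %in% sets[[b]])) keep[a] <- FALSE
        }
        sets <- sets[keep]
        break
      }
    }
  }
  # order sets by the best-ranked (largest-mean) group they contain
  rank_of <- match(seq_len(k), ord)
  sets <- sets[order(vapply(sets, function(s) min(rank_of[s]), numeric(1)))]
  letters_out <- rep("", k)
  for (s in seq_along(sets)) {
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  }
  letters_out
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' Studentized-range pairwise comparisons via [stats::TukeyHSD()] (which
#' applies the Tukey-Kramer harmonic adjustment under unequal group sizes),
#' plus the letter display used in the summary tables: two groups share a
#' letter iff they are not significantly different at `alpha`.
#'
#' @inheritParams oneway_anova
#' @param alpha Family-wise significance level (default 0.05).
#' @return A list with `pairwise` (tibble: `group1`, `group2`, `diff`,
#'   `lwr`, `upr`, `p_adj`) and `letters` (named character vector).
#' @export
tukey_hsd <- function(values, group, alpha = 0.05) {
  g <- check_grouped(values, group)
  fit <- aov(g$values ~ g$group)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)[[1]]
  # rows follow combn(levels, 2) as "second-first"; group labels may
  # themselves contain '-', so never parse rownames
  cmb <- utils::combn(levels(g$group), 2)
  pairwise <- tibble::tibble(
    group1 = cmb[2, ], group2 = cmb[1, ],
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"]))
  lev <- levels(g$group)
  sig <- matrix(FALSE, length(lev), length(lev),
                dimnames = list(lev, lev))
  for (r in seq_len(nrow(pairwise))) {
    a <- pairwise$group1[r]; b <- pairwise$group2[r]
    sig[a, b] <- sig[b, a] <- pairwise$p_adj[r] < alpha
  }
  means <- tapply(g$values, g$group, mean)
  letters_out <- cld_from_signif(sig, means)
  list(pairwise = pairwise, letters = setNames(letters_out, lev))
}

#' Pearson correlation with p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A list with `r`, `p`, `n`.
#' @export
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)$r # 1
pearson_r <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in a variable", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' First-order partial correlation
#'
#' Correlation of `x` and `y` with one control variable partialled out:
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with the p-value from the t transform on n - 3 degrees of freedom. This
#' is the convention used for the CAR / SAR / C-density triangle, where each
#' pairwise association is reported with the third variable as control.
#'
#' @param x,y Numeric vectors.
#' @param control Numeric control vector.
#' @return A list with `r`, `p`, `n`.
#' @export
partial_r <- function(x, y, control) {
  ok <- complete.cases(x, y, control)
  x <- x[ok]; y <- y[ok]; z <- control[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 for a first-order partial", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    stop("zero variance in a variable", call. = FALSE)
  }
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 3)
  list(r = r, p = p, n = n)
}

#' Fit the CAR ~ RSLR linear model
#'
#' The final parsimonious model relating carbon accumulation rate to relative
#' sea-level rise. Three fit modes handle the grouping of sites by source of
#' reference: `"ols"` is plain least squares; `"cluster_robust"` (default)
#' keeps the OLS coefficients but computes source-clustered sandwich
#' standard errors; `"random_intercept"` fits a per-source random intercept
#' by REML via \pkg{lme4}.
#'
#' @param records Data frame with columns `car_gC_m2_yr`, `rslr_mm_yr` and
#'   (for the clustered/random modes) `source_id`.
#' @param fit_mode One of `"cluster_robust"`, `"ols"`, `"random_intercept"`.
#' @return An object of class `car_rslr_model`: `slope` (g C m^-2 yr^-1 per
#'   mm yr^-1), `intercept`, `slope_se`, `intercept_se`, `fit_mode`, `n`.
#' @export
fit_car_rslr <- function(records,
                         fit_mode = c("cluster_robust", "ols",
                                      "random_intercept")) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(is.data.frame(records))
  ok <- complete.cases(records$car_gC_m2_yr, records$rslr_mm_yr)
  d <- records[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 records with CAR and RSLR", call. = FALSE)
  if (sd(d$rslr_mm_yr) == 0) {
    stop("all RSLR values identical; slope unidentifiable", call. = FALSE)
  }
  if (fit_mode != "ols" && is.null(d$source_id)) {
    stop("fit_mode '", fit_mode, "' requires a source_id column",
         call. = FALSE)
  }
  if (fit_mode == "random_intercept") {
    fit <- suppressMessages(
      lme4::lmer(car_gC_m2_yr ~ rslr_mm_yr + (1 | source_id), data = d))
    fe <- lme4::fixef(fit)
    # a degenerate REML fit (zero residual variance) returns an NA
    # covariance; fall back to the OLS covariance, which is then exact
    se <- tryCatch({
      s <- suppressWarnings(sqrt(diag(as.matrix(vcov(fit)))))
      if (anyNA(s)) stop("NA vcov")
      s
    }, error = function(e) {
      sqrt(diag(vcov(lm(car_gC_m2_yr ~ rslr_mm_yr, data = d))))
    })
  } else {
    fit <- lm(car_gC_m2_yr ~ rslr_mm_yr, data = d)
    fe <- coef(fit)
    V <- if (fit_mode == "cluster_robust") {
      sandwich::vcovCL(fit, cluster = d$source_id)
    } else {
      vcov(fit)
    }
    se <- sqrt(diag(V))
  }
  structure(list(slope = unname(fe[2]), intercept = unname(fe[1]),
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 fit_mode = fit_mode, n = nrow(d)),
            class = "car_rslr_model")
}

#' @export
print.car_rslr_model <- function(x, ...) {
  cat(sprintf(
    "CAR ~ RSLR (%s, n = %d)\n  slope     %8.3f +/- %.3f g C m-2 yr-1 per mm yr-1\n  intercept %8.3f +/- %.3f g C m-2 yr-1\n",
    x$fit_mode, x$n, x$slope, x$slope_se, x$intercept, x$intercept_se))
  invisible(x)
}

#' Correlation table of CAR and SAR against regional drivers
#'
#' Reproduces the layout of the driver-correlation summary: plain Pearson
#' correlations of CAR and SAR with RSLR, salinity, air temperature,
#' precipitation and coordinates, except that within the CAR / SAR /
#' C-density triangle each pair is a first-order partial correlation with
#' the third variable as control.
#'
#' @param sites Sites data frame with the harmonized column names.
#' @return A tibble with `var1`, `var2`, `r`, `p`, `n`, `type`.
#' @export
correlation_table <- function(sites) {
  vars <- c(sar = "sar_mm_yr", c_density = "c_density_gC_cm3",
            rslr = "rslr_mm_yr", salinity = "salinity_ppt", tair = "tair_c",
            prcp = "prcp_mm_yr", latitude = "lat", longitude = "lon")
  triangle <- list(
    c("car_gC_m2_yr", "sar_mm_yr", "c_density_gC_cm3"),
    c("car_gC_m2_yr", "c_density_gC_cm3", "sar_mm_yr"),
    c("sar_mm_yr", "c_density_gC_cm3", "car_gC_m2_yr"))
  rows <- list()
  for (v in names(vars)) {
    col <- vars[[v]]
    if (!col %in% names(sites)) next
    if (col %in% c("sar_mm_yr", "c_density_gC_cm3")) next
    ct <- pearson_r(sites$car_gC_m2_yr, sites[[col]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      var1 = "car", var2 = v, r = ct$r, p = ct$p, n = ct$n, type = "pearson")
  }
  for (tr in triangle) {
    if (!all(tr %in% names(sites))) next
    ct <- partial_r(sites[[tr[1]]], sites[[tr[2]]], sites[[tr[3]]])
    nm <- function(col) names(vars)[match(col, vars)]
    rows[[length(rows) + 1]] <- tibble::tibble(
      var1 = if (tr[1] == "car_gC_m2_yr") "car" else nm(tr[1]),
      var2 = nm(tr[2]), r = ct$r, p = ct$p, n = ct$n, type = "partial")
  }
  dplyr::bind_rows(rows)
}
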