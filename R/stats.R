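#' Shapiro-Wilk normality test
#'
#' Gatekeeper used throughout the battery: parametric branches (Pearson
#' correlation, Welch/paired t) are taken only when this test does not
#' reject at the chosen alpha.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p_value`.
#' @export
normality_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("normality_test requires 3 <= n <= 5000", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("normality_test: sample is constant (zero variance)",
         call. = FALSE)
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Normality-gated correlation
#'
#' Pearson's r (with its t-based p-value) when both variables pass the
#' Shapiro-Wilk gate at `alpha`; Spearman's rho otherwise. With ties the
#' Spearman p-value uses the tie-corrected large-sample approximation.
#'
#' @param x,y Paired numeric samples, n >= 4.
#' @param alpha Gate level for the normality test (default 0.05).
#' @return An object of class `correlation_result`: list with `method`
#'   ("pearson" or "spearman"), `coefficient`, `p_value`, `n`, and
#'   `gate_report` (the two normality p-values).
#' @examples
#' correlation_auto(1:10, 2 * (1:10) + 1)
#' @export
correlation_auto <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("correlation_auto requires n >= 4", call. = FALSE)
  gate <- c(x = normality_test(x)$p_value, y = normality_test(y)$p_value)
  method <- if (all(gate >= alpha)) "pearson" else "spearman"
  if (method == "pearson") {
    ct <- cor.test(x, y, method = "pearson")
  } else {
    tie <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = !tie))
  }
  structure(
    list(method = method, coefficient = unname(ct$estimate),
         p_value = ct$p.value, n = n, gate_report = gate),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s %s = %.3f, p = %.4g, n = %d\n",
              x$method, if (x$method == "pearson") "r" else "rho",
              x$coefficient, x$p_value, x$n))
  invisible(x)
}

# one-way random-effects, single-measure ICC from two sessions
icc_point <- function(day1, day2) {
  n <- length(day1)
  m_i <- (day1 + day2) / 2
  gm <- mean(m_i)
  msb <- 2 * sum((m_i - gm)^2) / (n - 1)
  msw <- sum((day1 - m_i)^2 + (day2 - m_i)^2) / n
  (msb - msw) / (msb + msw)
}

#' Repeatability: one-way bootstrap ICC
#'
#' One-way random-effects, single-measure intraclass correlation of two
#' sessions per subject, with a percentile confidence interval from
#' resampling subjects with replacement. The point estimate may be
#' negative when between-subject variance is degenerate; it is reported
#' as computed (not truncated) and flagged.
#'
#' @param day1,day2 Paired measurements (one pair per subject), n >= 5.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap, or NULL.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `icc_result`: list with `estimate`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_subjects`, `degenerate` flag.
#' @examples
#' set.seed(1)
#' s <- rnorm(30, sd = sqrt(3)); icc_oneway(s + rnorm(30), s + rnorm(30))
#' @export
icc_oneway <- function(day1, day2, n_boot = 1000, seed = NULL,
                       conf = 0.95) {
  ok <- complete.cases(day1, day2)
  day1 <- day1[ok]; day2 <- day2[ok]
  n <- length(day1)
  if (n < 5) stop("icc_oneway requires >= 5 pairs", call. = FALSE)
  est <- icc_point(day1, day2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      icc_point(day1[idx], day2[idx])
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 names = FALSE)
  structure(
    list(estimate = est, ci_low = qs[1], ci_high = qs[2],
         n_boot = n_boot, n_subjects = n,
         degenerate = !is.finite(est) || est <= 0),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc> %.3f, %d%% CI (%.3f, %.3f), n = %d, boot = %d%s\n",
              x$estimate, 95, x$ci_low, x$ci_high, x$n_subjects,
              x$n_boot, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Type II residual sums of squares machinery for a 2x2 design: Q factors
# of the four nested design matrices; RSS via ||y||^2 - ||Q'y||^2
typeII_qr <- function(a, b) {
  lapply(list(A = model.matrix(~a), B = model.matrix(~b),
              AB = model.matrix(~a + b), full = model.matrix(~a * b)),
         function(X) qr.Q(qr(X)))
}

typeII_ss <- function(Y, Qs) {
  Y <- as.matrix(Y)
  tot <- colSums(Y^2)
  rss <- lapply(Qs, function(Q) tot - colSums(crossprod(Q, Y)^2))
  list(A = rss$B - rss$AB, B = rss$A - rss$AB,
       AB = rss$AB - rss$full, error = rss$full)
}

#' Two-factor permutation ANOVA with eta-squared
#'
#' Fixed-effects 2x2 ANOVA with interaction. Observed F statistics use
#' Type II sums of squares (so main effects are adjusted for each other
#' in unbalanced designs; identical to Type I when balanced). The null
#' distribution comes from permuting the raw response vector wholesale
#' `n_perm` times — exact under the global null of complete
#' exchangeability — and p-values carry the add-one smoothing
#' `p = (1 + #\{F* >= F_obs\}) / (1 + n_perm)`, so they lie in (0, 1\].
#' Effect sizes are `eta_squared = SS_term / SS_total` from the observed
#' decomposition.
#'
#' @param y Numeric response.
#' @param a,b Factor labels, two levels each, >= 2 observations per cell.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed, or NULL.
#' @return An object of class `perm_anova_result`: a list with `terms`
#'   (data frame: term, F, p_value, eta_squared), `n_perm`, `seed`, `n`.
#' @export
perm_anova_2x2 <- function(y, a, b, n_perm = 10000, seed = NULL) {
  a <- factor(a); b <- factor(b)
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop("both factors must have exactly two levels", call. = FALSE)
  tab <- table(a, b)
  if (any(tab == 0)) stop("empty design cell", call. = FALSE)
  if (any(tab < 2))
    stop("each design cell needs >= 2 observations", call. = FALSE)
  n <- length(y)
  stopifnot(length(a) == n, length(b) == n, all(is.finite(y)))

  Qs <- typeII_qr(a, b)
  yc <- y - mean(y)
  ss_total <- sum(yc^2)
  obs <- typeII_ss(y, Qs)
  df_e <- n - 4L
  F_obs <- unlist(obs[c("A", "B", "AB")]) / (obs$error / df_e)

  if (ss_total == 0) {
    terms <- data.frame(term = c("A", "B", "A:B"), F = 0,
                        p_value = 1, eta_squared = 0)
  } else {
    perm_idx <- with_seed(seed,
      replicate(n_perm, sample.int(n)))
    Y <- matrix(y[perm_idx], nrow = n, ncol = n_perm)
    ssp <- typeII_ss(Y, Qs)
    Fp <- rbind(A = ssp$A, B = ssp$B, AB = ssp$AB) /
      matrix(ssp$error / df_e, nrow = 3, ncol = n_perm, byrow = TRUE)
    p <- (1 + rowSums(Fp >= F_obs)) / (1 + n_perm)
    terms <- data.frame(
      term = c("A", "B", "A:B"), F = unname(F_obs),
      p_value = unname(p),
      eta_squared = unname(unlist(obs[c("A", "B", "AB")]) / ss_total)
    )
  }
  structure(list(terms = terms, n_perm = n_perm, seed = seed, n = n),
            class = "perm_anova_result")
}

#' @export
print.perm_anova_result <- function(x, ...) {
  cat(sprintf("<perm_anova> n = %d, %d permutations\n", x$n, x$n_perm))
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

# classical pooled-SD Cohen's d (alternative: Welch-averaged SD)
cohens_d <- function(y1, y2, method = c("pooled", "welch")) {
  method <- match.arg(method)
  n1 <- length(y1); n2 <- length(y2)
  s <- if (method == "pooled")
    sqrt(((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2))
  else sqrt((var(y1) + var(y2)) / 2)
  (mean(y1) - mean(y2)) / s
}

#' Normality-gated two-group test
#'
#' Unpaired: Welch's t-test when both samples pass the Shapiro-Wilk gate,
#' the Mann-Whitney U test otherwise (exact p below 26 per group with no
#' ties; tie/continuity-corrected normal approximation above). Paired:
#' the differences are gated; paired t-test or the Wilcoxon signed-rank
#' test. Cohen's d (pooled-SD form by default) is attached for unpaired
#' comparisons.
#'
#' @param y1,y2 Numeric samples. Unpaired: each n >= 3. Paired: equal
#'   lengths, n >= 5 pairs.
#' @param paired Logical pairing flag.
#' @param alpha Gate level for the normality test.
#' @param d_method `"pooled"` (classical) or `"welch"` (Welch-averaged
#'   SD) denominator for Cohen's d.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param dispatch `"auto"` (normality-gated, the default),
#'   `"parametric"` or `"nonparametric"` to force a branch.
#' @return An object of class `two_group_result`: list with `method`
#'   ("welch_t", "mann_whitney", "paired_t" or "wilcoxon_signed_rank"),
#'   `statistic`, `p_value`, `cohen_d` (NA for paired designs), `n`
#'   (per-group counts), `gate_report`.
#' @examples
#' two_group_test(c(1, 2, 3), c(4, 5, 6))
#' @export
two_group_test <- function(y1, y2, paired = FALSE, alpha = 0.05,
                           d_method = c("pooled", "welch"),
                           alternative = c("two.sided", "less",
                                           "greater"),
                           dispatch = c("auto", "parametric",
                                        "nonparametric")) {
  d_method <- match.arg(d_method)
  alternative <- match.arg(alternative)
  dispatch <- match.arg(dispatch)
  y1 <- y1[!is.na(y1)]; y2 <- y2[!is.na(y2)]
  n1 <- length(y1); n2 <- length(y2)
  if (paired) {
    if (n1 != n2) stop("paired samples must have equal length",
                       call. = FALSE)
    if (n1 < 5) stop("paired test requires >= 5 pairs", call. = FALSE)
    d <- y1 - y2
    if (all(d == 0))
      stop("all paired differences are zero; no test possible",
           call. = FALSE)
    gate <- c(diff = normality_test(d)$p_value)
    parametric <- switch(dispatch, auto = gate >= alpha,
                         parametric = TRUE, nonparametric = FALSE)
    if (parametric) {
      ht <- t.test(y1, y2, paired = TRUE, alternative = alternative)
      method <- "paired_t"
    } else {
      exact <- n1 < 26 && !any(d == 0) && !anyDuplicated(abs(d))
      ht <- suppressWarnings(
        wilcox.test(y1, y2, paired = TRUE, exact = exact,
                    alternative = alternative))
      method <- "wilcoxon_signed_rank"
    }
    dval <- NA_real_
  } else {
    if (n1 < 3 || n2 < 3)
      stop("unpaired test requires >= 3 per group", call. = FALSE)
    gate <- c(y1 = normality_test(y1)$p_value,
              y2 = normality_test(y2)$p_value)
    parametric <- switch(dispatch, auto = all(gate >= alpha),
                         parametric = TRUE, nonparametric = FALSE)
    if (parametric) {
      ht <- t.test(y1, y2, var.equal = FALSE, alternative = alternative)
      method <- "welch_t"
    } else {
      exact <- n1 < 26 && n2 < 26 && !anyDuplicated(c(y1, y2))
      ht <- suppressWarnings(
        wilcox.test(y1, y2, exact = exact, alternative = alternative))
      method <- "mann_whitney"
    }
    dval <- cohens_d(y1, y2, d_method)
  }
  structure(
    list(method = method, statistic = unname(ht$statistic),
         p_value = ht$p.value, cohen_d = dval,
         n = c(n1 = n1, n2 = n2), gate_report = gate),
    class = "two_group_result"
  )
}

#' @export
print.two_group_result <- function(x, ...) {
  cat(sprintf("<two_group> %s: stat = %.3f, p = %.4g, d = %s\n",
              x$method, x$statistic, x$p_value,
              if (is.na(x$cohen_d)) "NA" else sprintf("%.2f", x$cohen_d)))
  invisible(x)
}

#' Effect-size classification
#'
#' Conventional interpretation bands: eta-squared — small
#' (0.01, 0.06), medium \[0.06, 0.14), large >= 0.14; Cohen's d (absolute
#' value) — small (0.2, 0.5), medium \[0.5, 0.8), large >= 0.8. Values at
#' or below the small lower bound are "negligible". Boundary values obey
#' these inequalities exactly: eta-squared = 0.06 is medium, d = 0.2 is
#' negligible.
#'
#' @param measure `"eta_squared"` or `"cohen_d"`.
#' @param value Effect size; eta-squared must lie in \[0, 1\]; d is taken
#'   in absolute value.
#' @return List with `measure`, `value`, `label`.
#' @examples
#' classify_effect("eta_squared", 0.04)$label  # "small"
#' classify_effect("cohen_d", 0.83)$label      # "large"
#' @export
classify_effect <- function(measure = c("eta_squared", "cohen_d"), value) {
  measure <- match.arg(measure)
  check_finite_scalar(value, "value")
  if (measure == "eta_squared") {
    if (value < 0 || value > 1)
      stop("eta_squared must lie in [0, 1]", call. = FALSE)
    v <- value
    label <- if (v >= 0.14) "large" else if (v >= 0.06) "medium"
    else if (v > 0.01) "small" else "negligible"
  } else {
    v <- abs(value)
    label <- if (v >= 0.8) "large" else if (v >= 0.5) "medium"
    else if (v > 0.2) "small" else "negligible"
  }
  list(measure = measure, value = value, label = label)
}

#' Optional Benjamini-Hochberg column for a report table
#'
#' The analysis reports raw p-values by default (matching the
#' correlation-screen convention of reporting every per-cell test
#' uncorrected); this helper appends an FDR-adjusted column for readers
#' who want one.
#'
#' @param report Data frame with a `p_value` column.
#' @return The data frame with an added `p_bh` column.
#' @export
add_bh_column <- function(report) {
  stopifnot("p_value" %in% names(report))
  report$p_bh <- p.adjust(report$p_value, method = "BH")
  report
}
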