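#' Statistical test result
#'
#' Lightweight container for one group comparison: the statistic name and
#' value, its degrees of freedom, the raw p value and (optionally) a
#' multiplicity-adjusted p value.
#'
#' @param statistic name of the statistic ("F", "D", "r", "t").
#' @param value statistic value.
#' @param df degrees of freedom (scalar or pair), may be `NA`.
#' @param p_raw raw p value.
#' @param p_adjusted adjusted p value (default `NA`).
#' @param extra named list of method-specific extras.
#' @return object of class `stat_result`.
#' @export
stat_result <- function(statistic, value, df, p_raw, p_adjusted = NA_real_,
                        extra = list()) {
  if (!is.na(p_raw) && (p_raw < 0 || p_raw > 1)) stop("p value outside [0, 1]")
  structure(list(statistic = statistic, value = value, df = df,
                 p_raw = p_raw, p_adjusted = p_adjusted, extra = extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s(%s) = %.4g, p = %.4g%s\n", x$statistic, dfs, x$value,
              x$p_raw,
              if (!is.na(x$p_adjusted)) sprintf(" (adj. %.4g)", x$p_adjusted) else ""))
  invisible(x)
}

#' Average repeated measurements into one replicate per unit
#'
#' Repeated measurements from the same animal (multiple sections, imaging
#' planes or vessel profiles) are averaged into a single replicate before any
#' group testing, so that animals -- not sections -- are the experimental
#' units.
#'
#' @param data a data.frame.
#' @param by character vector of key columns identifying the unit (e.g.
#'   animal id, or animal id + region).
#' @param values character vector of measurement columns to average; defaults
#'   to every numeric column not in `by`.
#' @return data.frame with one row per unique `by` combination; each value
#'   column holds the unweighted mean over that unit's rows.
#' @export
average_replicates <- function(data, by, values = NULL) {
  stopifnot(is.data.frame(data), all(by %in% names(data)))
  if (is.null(values)) {
    values <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], by)
  }
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  idx <- !duplicated(key)
  out <- data[idx, by, drop = FALSE]
  rownames(out) <- NULL
  ord <- key[idx]
  for (v in values) {
    m <- tapply(data[[v]], key, mean)
    out[[v]] <- as.numeric(m[as.character(ord)])
  }
  out
}

#' One-way analysis of variance from raw values
#'
#' Classical fixed-effect one-way ANOVA: the between/within sum-of-squares
#' decomposition with `F = MS_between / MS_within` on `(k - 1, N - k)`
#' degrees of freedom.
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor), same length as `values`.
#' @return `stat_result` with the F statistic.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  n <- tabulate(groups)
  if (any(n < 2)) stop("every group needs n >= 2")
  m <- tapply(values, groups, mean)
  gm <- mean(values)
  ss_b <- sum(n * (m - gm)^2)
  ss_w <- sum((values - m[as.integer(groups)])^2)
  .anova_f(ss_b, ss_w, k, sum(n))
}

#' One-way ANOVA from printed group summaries
#'
#' Reconstructs the one-way F statistic from per-group `(n, mean, sd)` alone,
#' using `SS_between = sum n_i (m_i - m_bar)^2` (grand mean weighted by n)
#' and `SS_within = sum (n_i - 1) sd_i^2`. Algebraically identical to
#' [anova_oneway()] on the raw data; it exists so published summary
#' statistics (means +/- SD with group sizes) can be re-tested without the
#' raw measurements.
#'
#' @param summaries data.frame with columns `n`, `mean`, `sd` (one row per
#'   group; sd is the sample standard deviation, n-1 denominator).
#' @return `stat_result` with the F statistic.
#' @export
anova_oneway_summary <- function(summaries) {
  stopifnot(is.data.frame(summaries), all(c("n", "mean", "sd") %in% names(summaries)))
  if (nrow(summaries) < 2) stop("need at least two groups")
  if (any(summaries$n < 2)) stop("every group needs n >= 2")
  if (any(summaries$sd < 0)) stop("sd must be non-negative")
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  N <- sum(n)
  gm <- sum(n * m) / N
  ss_b <- sum(n * (m - gm)^2)
  ss_w <- sum((n - 1) * s^2)
  .anova_f(ss_b, ss_w, nrow(summaries), N)
}

.anova_f <- function(ss_b, ss_w, k, N) {
  df1 <- as.integer(k - 1)
  df2 <- as.integer(round(N - k))
  ms_w <- ss_w / df2
  f <- if (ms_w == 0) {
    if (ss_b == 0) 0 else Inf
  } else (ss_b / df1) / ms_w
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  stat_result("F", f, c(df1, df2), p,
              extra = list(ss_between = ss_b, ss_within = ss_w))
}

#' Two-way ANOVA with sequential (Type I) sums of squares
#'
#' Fixed-effect two-factor ANOVA with terms entered in the order
#' `B`, `A`, `A:B` (matching reporting order such as position, genotype,
#' interaction). Sums of squares are sequential: each term's SS is the drop
#' in residual sum of squares when the term is added, computed by QR
#' projections; with unbalanced cells the order is therefore material and is
#' fixed here.
#'
#' @param data data.frame.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns (`factor_b` is
#'   entered first).
#' @return named list of `stat_result` (`B`, `A`, `A:B`), each with the
#'   term's F on `(df_term, df_residual)`.
#' @export
anova_twoway <- function(data, response, factor_a, factor_b) {
  y <- data[[response]]
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  if (anyNA(y) || anyNA(a) || anyNA(b)) stop("missing values in design")
  if (any(table(a, b) == 0)) stop("empty cells in the two-way design")
  X0 <- matrix(1, length(y), 1)
  Xb <- stats::model.matrix(~b)
  Xab <- stats::model.matrix(~ b + a)
  Xfull <- stats::model.matrix(~ b * a)
  rss <- function(X) {
    q <- qr(X)
    sum(qr.resid(q, y)^2)
  }
  r0 <- rss(X0); rb <- rss(Xb); rba <- rss(Xab); rf <- rss(Xfull)
  df_b <- nlevels(b) - 1L
  df_a <- nlevels(a) - 1L
  df_ab <- df_a * df_b
  df_res <- length(y) - qr(Xfull)$rank
  if (df_res <= 0) stop("no residual degrees of freedom")
  mse <- rf / df_res
  term <- function(ss, df) {
    f <- (ss / df) / mse
    stat_result("F", f, c(df, df_res),
                stats::pf(f, df, df_res, lower.tail = FALSE),
                extra = list(ss = ss))
  }
  out <- list(term(r0 - rb, df_b), term(rb - rba, df_a), term(rba - rf, df_ab))
  names(out) <- c(factor_b, factor_a, paste0(factor_a, ":", factor_b))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Controls the false-discovery rate: p values are sorted ascending and the
#' i-th adjusted value is `min over j >= i of p_(j) * m / j`, capped at 1,
#' then returned in the original order.
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values outside [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  # step-up: running minimum from the largest p downward
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p value
#' uses the asymptotic Kolmogorov distribution
#' `Q(lambda) = 2 * sum_j (-1)^(j-1) exp(-2 j^2 lambda^2)` evaluated at
#' `lambda = sqrt(n_e) * D`, with effective size
#' `n_e = n_a n_b / (n_a + n_b)`.
#'
#' @param a,b numeric samples.
#' @return `stat_result` with statistic `D`.
#' @export
ks_two_sample <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("empty sample")
  all_v <- sort(unique(c(a, b)))
  fa <- vapply(all_v, function(v) mean(a <= v), numeric(1))
  fb <- vapply(all_v, function(v) mean(b <= v), numeric(1))
  d <- max(abs(fa - fb))
  ne <- na * nb / (na + nb)
  lambda <- sqrt(ne) * d
  p <- .kolmogorov_q(lambda)
  stat_result("D", d, NA_real_, p, extra = list(n_effective = ne))
}

.kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  j <- seq_len(101)
  q <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(q, 0), 1)
}

#' Pearson correlation with t-based p value
#'
#' Sample correlation coefficient `r` with the two-sided p value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return `stat_result` with statistic `r`; `extra$t` holds the t value.
#' @export
pearson <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 3) stop("need n >= 3")
  xm <- x - mean(x); ym <- y - mean(y)
  denom <- sqrt(sum(xm^2) * sum(ym^2))
  if (denom == 0) stop("zero variance")
  r <- sum(xm * ym) / denom
  if (abs(r) >= 1) {
    p <- 0
    t <- sign(r) * Inf
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  stat_result("r", r, n - 2, p, extra = list(t = t))
}
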