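#' Balanced three-way factorial ANOVA from first principles
#'
#' Fixed-effects variance decomposition for a fully crossed, balanced
#' season x site x tissue design with replication, computed directly from
#' cell and marginal means rather than via a regression fit:
#'
#' * main effects: `SS_A = b c r * sum((mean_a - grand)^2)` and analogously
#'   for the other two factors;
#' * two-way interactions from two-factor cell means minus the main effects;
#' * the three-way interaction from full cell means minus all lower-order
#'   terms;
#' * error from within-cell deviations.
#'
#' In a balanced design this decomposition is exact and identical to Type
#' I/II/III regression sums of squares.  Unbalanced data are rejected with an
#' error naming the first deficient cell — no approximate fallback is
#' attempted.  `F = MS_effect / MS_error` and p-values are the upper tail of
#' the F distribution (the regularized incomplete beta ratio).  A constant
#' response yields all-zero sums of squares and is reported with `F = 0`,
#' `p = 1`.
#'
#' @param data Long tibble with columns `season`, `site`, `tissue`,
#'   `replicate` and the response.
#' @param response Name of the response column (default `"count"`, the
#'   isolate count per replicate sample).
#' @param transform Optional response transform applied before fitting:
#'   `"none"` (default), `"sqrt"` or `"log1p"`.
#' @return An object of class `mycodiv_anova`; see [tidy.mycodiv_anova()] and
#'   [glance.mycodiv_anova()].
#' @examples
#' set.seed(1)
#' d <- expand.grid(season = 1:3, site = 1:6, tissue = 1:3, replicate = 1:3)
#' d$count <- rpois(nrow(d), 20)
#' anova_three_way(d)
#' @export
anova_three_way <- function(data, response = "count",
                            transform = c("none", "sqrt", "log1p")) {
  transform <- match.arg(transform)
  need <- c("season", "site", "tissue", response)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  A <- factor(data$season)
  B <- factor(data$site)
  C <- factor(data$tissue)
  y <- as.numeric(data[[response]])
  if (any(is.na(y))) stop("response contains missing values", call. = FALSE)
  y <- switch(transform, none = y, sqrt = sqrt(y), log1p = log1p(y))

  counts <- table(A, B, C)
  r <- unique(as.vector(counts))
  if (length(r) != 1) {
    idx <- which(counts != max(counts), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unbalanced design: cell (season=%s, site=%s, tissue=%s) has %d of %d replicates",
      dimnames(counts)[[1]][idx[1]], dimnames(counts)[[2]][idx[2]],
      dimnames(counts)[[3]][idx[3]],
      counts[idx[1], idx[2], idx[3]], max(counts)), call. = FALSE)
  }
  if (r < 2) {
    stop("need at least 2 replicates per cell for a within-cell error term",
         call. = FALSE)
  }
  a <- nlevels(A); b <- nlevels(B); cc <- nlevels(C)
  N <- length(y)

  gm <- mean(y)
  m_a <- tapply(y, A, mean)
  m_b <- tapply(y, B, mean)
  m_c <- tapply(y, C, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_ac <- tapply(y, list(A, C), mean)
  m_bc <- tapply(y, list(B, C), mean)
  m_abc <- tapply(y, list(A, B, C), mean)

  ss_a <- b * cc * r * sum((m_a - gm)^2)
  ss_b <- a * cc * r * sum((m_b - gm)^2)
  ss_c <- a * b * r * sum((m_c - gm)^2)
  dev_ab <- sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm
  dev_ac <- sweep(sweep(m_ac, 1, m_a), 2, m_c) + gm
  dev_bc <- sweep(sweep(m_bc, 1, m_b), 2, m_c) + gm
  ss_ab <- cc * r * sum(dev_ab^2)
  ss_ac <- b * r * sum(dev_ac^2)
  ss_bc <- a * r * sum(dev_bc^2)
  dev_abc <- m_abc
  dev_abc <- sweep(dev_abc, c(1, 2), m_ab)
  dev_abc <- sweep(dev_abc, c(1, 3), m_ac)
  dev_abc <- sweep(dev_abc, c(2, 3), m_bc)
  dev_abc <- sweep(dev_abc, 1, m_a, "+")
  dev_abc <- sweep(dev_abc, 2, m_b, "+")
  dev_abc <- sweep(dev_abc, 3, m_c, "+")
  dev_abc <- dev_abc - gm
  ss_abc <- r * sum(dev_abc^2)
  cellmean <- m_abc[cbind(as.integer(A), as.integer(B), as.integer(C))]
  ss_e <- sum((y - cellmean)^2)
  ss_t <- sum((y - gm)^2)

  terms <- c("season", "site", "tissue", "season:site", "season:tissue",
             "site:tissue", "season:site:tissue", "Residuals")
  ss <- c(ss_a, ss_b, ss_c, ss_ab, ss_ac, ss_bc, ss_abc, ss_e)
  df <- c(a - 1, b - 1, cc - 1, (a - 1) * (b - 1), (a - 1) * (cc - 1),
          (b - 1) * (cc - 1), (a - 1) * (b - 1) * (cc - 1),
          a * b * cc * (r - 1))
  ms <- ss / df
  ms_e <- ms[length(ms)]
  # degenerate case: constant response within measurement precision
  tol <- 1e-12 * max(1, mean(y)^2) * N
  fstat <- vapply(seq_len(7), function(i) {
    if (ss[i] <= tol && ss_e <= tol) 0
    else if (ms_e <= 0) Inf
    else ms[i] / ms_e
  }, numeric(1))
  pval <- ifelse(is.infinite(fstat), 0,
                 ifelse(fstat == 0 & ss_e <= tol, 1,
                        pf(fstat, df[1:7], df[8], lower.tail = FALSE)))

  tab <- tibble(
    term = terms,
    df = as.integer(df),
    sumsq = ss,
    meansq = ms,
    statistic = c(fstat, NA_real_),
    p.value = c(pval, NA_real_)
  )
  structure(
    list(table = tab, total_ss = ss_t, total_df = N - 1L,
         design = list(levels = c(season = a, site = b, tissue = cc),
                       replicates = r, N = N),
         response = response, transform = transform),
    class = "mycodiv_anova"
  )
}

#' F statistic from mean squares
#'
#' @param ms_effect,ms_error Effect and error mean squares (`ms_error > 0`).
#' @return `ms_effect / ms_error` (vectorized over `ms_effect`).
#' @examples
#' f_statistic(8.614, 2.599)
#' @export
f_statistic <- function(ms_effect, ms_error) {
  if (any(ms_error <= 0)) stop("ms_error must be positive", call. = FALSE)
  ms_effect / ms_error
}

#' Upper-tail p-value of the F distribution
#'
#' Thin, argument-checked wrapper around the regularized-incomplete-beta
#' upper tail implemented by [stats::pf()].
#'
#' @param f Observed F ratio (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @examples
#' p_value(1.046, 5, 108)
#' @export
p_value <- function(f, df1, df2) {
  if (any(f < 0)) stop("F must be nonnegative", call. = FALSE)
  if (any(df1 < 1) || any(df2 < 1)) {
    stop("degrees of freedom must be >= 1", call. = FALSE)
  }
  pf(f, df1, df2, lower.tail = FALSE)
}

#' Significance stars used in the survey tables
#'
#' `***` for p < 0.001, `**` for p < 0.015, `ns` otherwise.
#' @param p Numeric p-values.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.015 ~ "**", TRUE ~ "ns")
}

#' @export
print.mycodiv_anova <- function(x, ...) {
  d <- x$design
  cat(sprintf("Balanced three-way ANOVA: %d x %d x %d cells, r = %d (N = %d)\n",
              d$levels[1], d$levels[2], d$levels[3], d$replicates, d$N))
  tab <- x$table
  tab$sig <- c(significance_label(tab$p.value[1:7]), "")
  print(as.data.frame(tab), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a three-way ANOVA fit
#'
#' @param x A `mycodiv_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per source (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`); the residual row carries `NA` for F and p.
#' @method tidy mycodiv_anova
#' @export
tidy.mycodiv_anova <- function(x, ...) {
  x$table
}

#' One-row summary of a three-way ANOVA fit
#'
#' @param x A `mycodiv_anova` object.
#' @param ... Unused.
#' @return A tibble with the design size, replicate count, total and error
#'   sums of squares, and the fraction of variance explained by the model.
#' @method glance mycodiv_anova
#' @export
glance.mycodiv_anova <- function(x, ...) {
  ss_e <- x$table$sumsq[x$table$term == "Residuals"]
  tibble(
    N = x$design$N,
    replicates = x$design$replicates,
    total_ss = x$total_ss,
    error_ms = x$table$meansq[x$table$term == "Residuals"],
    r.squared = if (x$total_ss > 0) 1 - ss_e / x$total_ss else 0
  )
}
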