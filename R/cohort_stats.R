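# Demographic matching statistics: one-way ANOVA reconstructed exactly from
# printed group summaries (mean, sample SD, n) or computed from raw data,
# and the Pearson chi-squared test of independence for categorical rows.

#' One-way ANOVA from per-group summaries
#'
#' Reconstructs the between- and within-group sums of squares exactly from
#' group means, sample standard deviations (n - 1 divisor) and sizes:
#' `SSB = sum n_g (m_g - m)^2`, `SSW = sum (n_g - 1) s_g^2`,
#' `F = (SSB / (k - 1)) / (SSW / (N - k))`.
#'
#' @param means per-group means.
#' @param sds per-group sample SDs.
#' @param ns per-group sizes (each >= 2).
#' @return list with `F`, `p`, `df` (c(k - 1, N - k)), and the sums of
#'   squares.
#' @export
#' @examples
#' # a matched three-group age row: F rounds to 0.6
#' anova_from_summary(c(58.6, 57.2, 58.4), c(7.2, 3.8, 6.8), c(44, 36, 37))$F
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(sds) != k || length(ns) != k)
    stop("means, sds, ns must have equal length", call. = FALSE)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  if (anyNA(sds)) stop("missing SD for a group with n > 1", call. = FALSE)
  if (any(sds < 0)) stop("negative SD", call. = FALSE)
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  df <- as.integer(c(k - 1L, N - k))
  if (ssw == 0) {
    return(list(F = Inf, p = 0, df = df, ssb = ssb, ssw = 0,
                degenerate = TRUE))
  }
  Fv <- (ssb / df[1]) / (ssw / df[2])
  list(F = Fv, p = pf(Fv, df[1], df[2], lower.tail = FALSE), df = df,
       ssb = ssb, ssw = ssw, degenerate = FALSE)
}

#' One-way ANOVA from raw per-group values
#'
#' Delegates to [anova_from_summary()] applied to the exact per-group
#' moments, so the two entry points agree to machine precision.
#'
#' @param values list of numeric vectors, one per group (each length >= 2).
#' @return As [anova_from_summary()].
#' @export
anova_from_raw <- function(values) {
  if (length(values) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(values) < 2L))
    stop("every group needs >= 2 values", call. = FALSE)
  anova_from_summary(vapply(values, mean, numeric(1)),
                     vapply(values, sd, numeric(1)),
                     lengths(values))
}

#' Pearson chi-squared test of independence
#'
#' Without continuity correction; `df = (rows - 1)(cols - 1)`.
#'
#' @param table groups x categories matrix of non-negative counts.
#' @return list with `chisq`, `p`, `df`.
#' @export
#' @examples
#' chi_square_independence(rbind(c(15, 29), c(11, 25), c(9, 28)))$chisq
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal: test undefined", call. = FALSE)
  E <- outer(rs, cs) / n
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(chisq = stat, p = pchisq(stat, df, lower.tail = FALSE), df = df)
}

#' Demographic matching table for a covariate data.frame
#'
#' Per-group mean (SD) for each continuous variable with the one-way ANOVA
#' F and p, and the sex chi-squared row, in the style of a cohort
#' characteristics table.
#'
#' @param demo data.frame from [make_demographics()] (columns `group`,
#'   `sex`, and continuous covariates).
#' @param continuous columns to summarize with ANOVA.
#' @return data.frame, one row per variable.
#' @export
demographics_table <- function(demo,
                               continuous = c("age", "education", "mmse",
                                              "avlt_ltm")) {
  groups <- unique(demo$group)
  rows <- lapply(continuous, function(v) {
    vals <- split(demo[[v]], factor(demo$group, levels = groups))
    a <- anova_from_raw(vals)
    cells <- vapply(vals, function(x)
      sprintf("%.2f (%.2f)", mean(x), sd(x)), character(1))
    data.frame(variable = v, t(cells), statistic = sprintf("F = %.2f", a$F),
               p = signif(a$p, 3), check.names = FALSE)
  })
  sex_tab <- table(factor(demo$group, levels = groups), demo$sex)
  cs <- chi_square_independence(unclass(sex_tab))
  sex_cells <- apply(sex_tab, 1, function(r) paste(r, collapse = "/"))
  rows[[length(rows) + 1L]] <-
    data.frame(variable = "sex", t(sex_cells),
               statistic = sprintf("chisq = %.2f", cs$chisq),
               p = signif(cs$p, 3), check.names = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
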