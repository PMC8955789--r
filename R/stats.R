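# Between-group comparisons: Kruskal-Wallis + Dunn post-hoc on counts,
# one-way ANOVA + Tukey HSD on ratios.

# Coerce to a validated named list of numeric group values.
as_groups <- function(g) {
  if (is.data.frame(g) && all(c("value", "group") %in% names(g))) {
    g <- split(g$value, g$group)
  }
  if (!is.list(g) || length(g) < 2) stop_config("need at least 2 groups")
  if (is.null(names(g)) || any(names(g) == "")) {
    names(g) <- paste0("group", seq_along(g))
  }
  g <- lapply(g, as.numeric)
  if (any(lengths(g) == 0)) stop_config("every group must be nonempty")
  if (any(vapply(g, anyNA, logical(1)))) stop_config("group values must not be NA")
  g
}

new_group_test <- function(method, statistic, df, p_value, pairwise = NULL) {
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = p_value, pairwise = pairwise),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic = %s, df = %s, p = %s\n",
              x$method, format(x$statistic, digits = 5),
              paste(x$df, collapse = ", "), format(x$p_value, digits = 4)))
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Kruskal--Wallis rank test across groups
#'
#' Tie-corrected H statistic with `df = #groups - 1` and a chi-square
#' p-value.  When all values are identical the statistic is 0 with p = 1
#' (full tie correction).
#'
#' @param g A named list of numeric vectors (one per group), or a data frame
#'   with `value` and `group` columns.
#' @return A `group_test` object.
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))  # H = 7.2, df = 2
#' @export
kruskal_wallis <- function(g) {
  g <- as_groups(g)
  values <- unlist(g, use.names = FALSE)
  if (length(values) < 3) stop_config("need at least 3 observations in total")
  k <- length(g)
  if (length(unique(values)) == 1) {
    return(new_group_test("Kruskal-Wallis", 0, k - 1L, 1))
  }
  groups <- factor(rep(names(g), lengths(g)), levels = names(g))
  kt <- kruskal.test(values, groups)
  new_group_test("Kruskal-Wallis", unname(kt$statistic),
                 as.integer(unname(kt$parameter)), unname(kt$p.value))
}

#' Dunn's post-hoc test on mean ranks
#'
#' Pairwise z statistics on group mean ranks with tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j))`,
#' two-sided p-values adjusted by the chosen method (Benjamini--Hochberg by
#' default).
#'
#' @inheritParams kruskal_wallis
#' @param adjustment One of `"BH"`, `"bonferroni"`, `"holm"`, `"none"`.
#' @return A `group_test` object whose `pairwise` data frame has columns
#'   `group1`, `group2`, `estimate` (mean-rank difference), `z`, `p_value`,
#'   `p_adj`.
#' @export
dunn_posthoc <- function(g, adjustment = c("BH", "bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  g <- as_groups(g)
  values <- unlist(g, use.names = FALSE)
  groups <- rep(names(g), lengths(g))
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))

  pairs <- utils::combn(names(g), 2)
  est <- mean_ranks[pairs[1, ]] - mean_ranks[pairs[2, ]]
  se <- sqrt(sigma2 * (1 / sizes[pairs[1, ]] + 1 / sizes[pairs[2, ]]))
  z <- ifelse(se > 0, est / se, 0)
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- p.adjust(p_raw, method = adjustment)
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    estimate = as.numeric(est), z = as.numeric(z),
    p_value = as.numeric(p_raw), p_adj = as.numeric(p_adj),
    row.names = NULL, stringsAsFactors = FALSE
  )
  new_group_test(paste0("Dunn (", adjustment, ")"), NA_real_, NA_integer_,
                 NA_real_, pw)
}

#' One-way analysis of variance across groups
#'
#' Classical between/within decomposition with `df = (k - 1, N - k)`.
#' Degenerate inputs follow the documented contract: all values identical
#' gives an undefined statistic (`NA`) with p = 1; zero within-group variance
#' with nonzero between-group variance gives `F = Inf` with p = 0.
#'
#' @inheritParams kruskal_wallis
#' @return A `group_test` object.
#' @examples
#' anova_oneway(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))  # F = 16
#' @export
anova_oneway <- function(g) {
  g <- as_groups(g)
  if (any(lengths(g) < 2)) stop_config("each group needs >= 2 values for a finite F")
  values <- unlist(g, use.names = FALSE)
  groups <- factor(rep(names(g), lengths(g)), levels = names(g))
  df1 <- length(g) - 1L
  df2 <- length(values) - length(g)
  # degenerate contracts: exactly-zero within-group variance
  within_const <- all(vapply(g, function(v) diff(range(v)) == 0, logical(1)))
  if (within_const) {
    means <- vapply(g, mean, numeric(1))
    if (diff(range(means)) == 0) {
      return(new_group_test("one-way ANOVA", NA_real_, c(df1, df2), 1))
    }
    return(new_group_test("one-way ANOVA", Inf, c(df1, df2), 0))
  }
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) {
    f <- NA_real_
    p <- 1
  }
  new_group_test("one-way ANOVA", f, c(df1, df2), p)
}

#' Tukey honest-significant-difference post-hoc test
#'
#' All pairwise group mean differences with studentized-range adjusted
#' p-values, computed from the one-way ANOVA fit.  With zero within-group
#' variance, equal means get p = 1 and unequal means p = 0.
#'
#' @inheritParams kruskal_wallis
#' @return A `group_test` object whose `pairwise` data frame has columns
#'   `group1`, `group2`, `estimate` (mean difference `group2 - group1`) and
#'   `p_adj`.
#' @export
tukey_hsd <- function(g) {
  g <- as_groups(g)
  if (any(lengths(g) < 2)) stop_config("each group needs >= 2 values")
  values <- unlist(g, use.names = FALSE)
  groups <- factor(rep(names(g), lengths(g)), levels = names(g))
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(
    group1 = vapply(nm, `[`, character(1), 2),
    group2 = vapply(nm, `[`, character(1), 1),
    estimate = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (any(!is.finite(pw$p_adj))) {
    zero_diff <- abs(pw$estimate) <= .Machine$double.eps * max(abs(values), 1)
    pw$p_adj[!is.finite(pw$p_adj) & zero_diff] <- 1
    pw$p_adj[!is.finite(pw$p_adj) & !zero_diff] <- 0
    pw$estimate[zero_diff] <- 0
  }
  new_group_test("Tukey HSD", NA_real_, NA_integer_, NA_real_, pw)
}
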