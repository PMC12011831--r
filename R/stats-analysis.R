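# Nonparametric group comparisons and OCT x OCTA correlation matrices.
# Standard tests are delegated to base R; the exact-enumeration Mann-Whitney
# path is implemented here because wilcox.test has no exact p with ties.

stat_result <- function(test_name, statistic, df = NA_real_, p_value,
                        n_per_group, extra = list()) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   n_per_group = n_per_group), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n = %s)\n", x$test_name,
              x$statistic,
              if (!is.na(x$df)) sprintf(", df = %.4g", x$df) else "",
              x$p_value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

# Exact two-sided Mann-Whitney p by enumerating all choose(n, n_a)
# assignments of the pooled mid-ranks (valid with ties).
mw_exact_p <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  sets <- utils::combn(n, n_a)
  u_all <- colSums(matrix(r[sets], nrow = n_a)) - n_a * (n_a + 1) / 2
  mu <- n_a * (n - n_a) / 2
  # two-sided: as extreme or more extreme in either direction
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = min(p, 1))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by enumeration when the total sample size is at most 12 (ties
#' allowed); otherwise the tie-corrected normal approximation without
#' continuity correction, as computed by `wilcox.test(correct = FALSE)`.
#'
#' @param a,b numeric samples.
#' @param exact_max total n at or below which the exact enumeration is used.
#' @return a `stat_result` with the U statistic of sample `a`.
#' @export
mann_whitney <- function(a, b, exact_max = 12) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n <- length(a) + length(b)
  if (n <= exact_max) {
    e <- mw_exact_p(a, b)
    return(stat_result("Mann-Whitney U (exact)", e$U, p_value = e$p,
                       n_per_group = c(length(a), length(b))))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  stat_result("Mann-Whitney U (normal approx.)", wt$statistic,
              p_value = wt$p.value, n_per_group = c(length(a), length(b)))
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H with a chi-square reference on k-1 degrees of freedom
#' (delegated to `kruskal.test`).
#'
#' @param groups list of numeric samples (the paper's use has >= 3 groups;
#'   2 are accepted).
#' @return a `stat_result`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("every group must be nonempty")
  kt <- stats::kruskal.test(groups)
  stat_result("Kruskal-Wallis H", kt$statistic, df = kt$parameter,
              p_value = kt$p.value, n_per_group = lengths(groups))
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; df = (r-1)(c-1).
#'
#' @param table matrix of counts.
#' @return a `stat_result`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  stat_result("Pearson chi-square", ct$statistic, df = ct$parameter,
              p_value = ct$p.value, n_per_group = rowSums(table))
}

#' Welch's t test from summary statistics
#'
#' Welch statistic and Welch-Satterthwaite degrees of freedom computed from
#' group means, standard deviations and sizes; two-sided p from the t
#' reference.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @return a `stat_result`.
#' @export
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  if (sd_a <= 0 || sd_b <= 0) stop("standard deviations must be positive")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  stat_result("Welch's t", t, df = df,
              p_value = 2 * stats::pt(-abs(t), df),
              n_per_group = c(n_a, n_b))
}

#' Spearman rank correlation
#'
#' Pearson correlation on mid-ranks (so ties are handled), with a two-sided
#' p from the t approximation on n-2 degrees of freedom. A constant input
#' vector gives an undefined rho, flagged rather than an error.
#'
#' @param x,y paired numeric samples, n >= 3 after pairwise deletion of
#'   missing values.
#' @return a `stat_result` with `statistic` = rho and field `undefined`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(stat_result("Spearman rho", NA_real_, df = n - 2,
                       p_value = NA_real_, n_per_group = n,
                       extra = list(undefined = TRUE)))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  stat_result("Spearman rho", rho, df = n - 2, p_value = p,
              n_per_group = n, extra = list(undefined = FALSE))
}

#' Label correlation strength
#'
#' By absolute value: \[0, 0.3) weak, \[0.3, 0.7) moderate, \[0.7, 1\] high
#' (boundary values go to the upper category).
#'
#' @param rho correlation coefficient in \[-1, 1\].
#' @return `"weak"`, `"moderate"` or `"high"`.
#' @export
strength_label <- function(rho) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("|rho| must not exceed 1")
  cut(pmin(abs(rho), 1), breaks = c(-Inf, 0.3, 0.7, Inf), right = FALSE,
      labels = c("weak", "moderate", "high")) |> as.character()
}

#' OCT x OCTA Spearman correlation matrix with Bonferroni correction
#'
#' One cell per (OCT variable, OCTA variable) pair over aligned eye-level
#' rows, pairwise-complete. The Bonferroni family is by default all cells of
#' the matrix (disc and macula panels corrected separately when called per
#' panel); `family = "global"` lets the caller supply a larger family size.
#'
#' @param oct_table data.frame of OCT thickness variables (columns).
#' @param octa_table data.frame of OCTA metric variables, same rows.
#' @param family `"per_matrix"` (m = number of testable cells) or
#'   `"global"` with `family_size` given.
#' @param family_size family size for `family = "global"`.
#' @param alpha significance level after correction (default 0.05).
#' @return data.frame with one row per cell: `oct_var, octa_var, n, rho, p,
#'   p_adj, significant, strength, missing`.
#' @export
correlation_matrix <- function(oct_table, octa_table,
                               family = c("per_matrix", "global"),
                               family_size = NULL, alpha = 0.05) {
  family <- match.arg(family)
  stopifnot(nrow(oct_table) == nrow(octa_table))
  cells <- expand.grid(oct_var = colnames(oct_table),
                       octa_var = colnames(octa_table),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    x <- oct_table[[cells$oct_var[i]]]
    y <- octa_table[[cells$octa_var[i]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3)
      return(data.frame(n = sum(ok), rho = NA_real_, p = NA_real_,
                        missing = TRUE))
    s <- spearman(x, y)
    data.frame(n = s$n_per_group, rho = s$statistic, p = s$p_value,
               missing = isTRUE(s$undefined))
  })
  out <- cbind(cells, do.call(rbind, res))
  m <- if (family == "global") {
    if (is.null(family_size)) stop("family = 'global' needs family_size")
    family_size
  } else {
    sum(!out$missing)
  }
  out$p_adj <- pmin(1, out$p * m)
  out$significant <- !out$missing & !is.na(out$p_adj) & out$p_adj < alpha
  out$strength <- ifelse(out$missing, NA_character_,
                         strength_label(ifelse(is.na(out$rho), 0, out$rho)))
  out$strength[is.na(out$rho)] <- NA_character_
  out <- out[c("oct_var", "octa_var", "n", "rho", "p", "p_adj",
               "significant", "strength", "missing")]
  attr(out, "family_size") <- m
  out
}
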