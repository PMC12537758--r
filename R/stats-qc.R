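# Outlier screening and one-way ANOVA utilities for leaf-temperature data.

#' Three-sigma outlier removal
#'
#' Flags values outside `mean +- 3 * sigma`, where sigma is the sample
#' (n-1) standard deviation of the *full* input. The rule is applied in a
#' single pass: the band is never re-estimated after removal, which keeps
#' the screen deterministic and idempotent.
#'
#' @param values Numeric vector (length >= 2).
#' @param n_sigma Band half-width in standard deviations.
#' @return An `outlier_report`: list with `retained`, `removed`,
#'   `removed_idx`, `mean`, `sigma`, `band`, and `degenerate` (TRUE when
#'   sigma is zero and nothing can be flagged).
#' @export
remove_outliers_3sigma <- function(values, n_sigma = 3) {
  check_finite(values, "values")
  if (length(values) < 2L) stop_invalid("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  degenerate <- s == 0
  band <- c(m - n_sigma * s, m + n_sigma * s)
  out <- values < band[1] | values > band[2]
  structure(list(retained = values[!out], removed = values[out],
                 removed_idx = which(out), mean = m, sigma = s,
                 band = band, degenerate = degenerate),
            class = "outlier_report")
}

#' One-way analysis of variance
#'
#' Classical one-way decomposition comparing group means; the F statistic
#' is referred to an F distribution with (k-1, N-k) degrees of freedom.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return List with `f`, `p`, and `table` (Source, SS, df, MS rows for
#'   treatment, error and total).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_invalid("need a list of at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop_invalid("every group needs at least 2 values (sizes: ",
                 paste(sizes, collapse = ", "), ")")
  }
  for (g in groups) check_finite(g, "group values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), sizes))
  aov_tab <- stats::anova(stats::lm(value ~ grp))
  ss_t <- aov_tab[["Sum Sq"]][1]; ss_e <- aov_tab[["Sum Sq"]][2]
  df_t <- aov_tab[["Df"]][1]; df_e <- aov_tab[["Df"]][2]
  list(
    f = aov_tab[["F value"]][1],
    p = aov_tab[["Pr(>F)"]][1],
    table = data.frame(
      source = c("treatment", "error", "total"),
      ss = c(ss_t, ss_e, ss_t + ss_e),
      df = c(df_t, df_e, df_t + df_e),
      ms = c(ss_t / df_t, ss_e / df_e, NA_real_)
    )
  )
}
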