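#' Group summary for a continuous variable
#'
#' @param n Group size (>= 2).
#' @param mean Group mean, in the variable's units.
#' @param sd Group standard deviation (>= 0).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (!is.numeric(n) || n < 2 || n != round(n))
    stop("n must be an integer >= 2")
  if (!is.numeric(sd) || sd < 0) stop("sd must be nonnegative")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Two-group t-test from summary statistics
#'
#' Two-sided t-test of equal means computed from per-group n, mean and SD.
#' The pooled-variance variant uses the pooled SD with
#' `df = n_a + n_b - 2`; the Welch variant uses unpooled variances with
#' Satterthwaite degrees of freedom. Summary-based computation is exact:
#' it equals the test on any raw dataset with those moments.
#'
#' @param summary_a,summary_b [group_summary()] objects (or lists with
#'   `n`, `mean`, `sd`).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' two_group_t(group_summary(300, 66.9, 9.74),
#'             group_summary(770, 66.6, 10.04))  # p ~ 0.66
#' @export
two_group_t <- function(summary_a, summary_b,
                        variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- summary_a; b <- summary_b
  for (s in list(a, b))
    if (!all(c("n", "mean", "sd") %in% names(s)))
      stop("summaries must carry n, mean and sd")
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean)
    stop("degenerate input: both groups constant at the same value")
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test on a k x 2 category table
#'
#' Uncorrected (no continuity correction) Pearson chi-square of homogeneity
#' between two groups across k categories, `df = k - 1`, upper-tail
#' p-value. Categories present in only one group are retained; a category
#' with zero total across both groups has expected count 0 and is an error
#' (drop it first).
#'
#' @param counts k x 2 matrix (or data.frame) of nonnegative integer
#'   counts, categories on rows, the two groups on columns.
#' @return List with `chi2`, `df`, `p` and the `expected` count matrix.
#' @examples
#' chi_square(cbind(tested = c(53, 34, 213),
#'                  not_tested = c(101, 95, 574)))  # region, p ~ 0.16
#' @export
chi_square <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2 || nrow(m) < 2)
    stop("counts must be a k x 2 table with k >= 2")
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("expected count of zero: drop categories absent from both groups")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = expected)
}

#' Representativeness testing of tested vs not-tested patients
#'
#' Compares the tested and not-tested cohorts variable by variable:
#' two-group t-tests for continuous baseline variables, uncorrected
#' chi-square for categorical ones, flagging differences at the given
#' significance level. With raw patient-level data, summaries and tables
#' are built from the `tested` flag; pre-computed summaries can be passed
#' through [two_group_t()] and [chi_square()] directly.
#'
#' @param demographics data.frame with a logical `tested` column plus the
#'   baseline variables.
#' @param continuous Character vector of continuous variable names
#'   (default `c("age", "tumor_area", "viable_cells")`).
#' @param categorical Character vector of categorical variable names
#'   (default `c("sex", "race", "ethnicity", "region", "site")`).
#' @param alpha Significance level, default 0.05.
#' @param t_variant Passed to [two_group_t()].
#' @return data.frame with one row per variable: `variable`, `type`,
#'   `statistic`, `df`, `p`, `flag` (`p < alpha`).
#' @export
representativeness_report <- function(demographics,
                                      continuous = c("age", "tumor_area",
                                                     "viable_cells"),
                                      categorical = c("sex", "race",
                                                      "ethnicity", "region",
                                                      "site"),
                                      alpha = 0.05, t_variant = "pooled") {
  if (!"tested" %in% names(demographics))
    stop("demographics must carry a logical 'tested' column")
  tested <- as.logical(demographics$tested)
  vars <- c(continuous, categorical)
  miss <- setdiff(vars, names(demographics))
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "))
  rows <- lapply(vars, function(v) {
    x <- demographics[[v]]
    if (v %in% continuous) {
      if (!is.numeric(x)) stop("variable ", v, " typed continuous but not numeric")
      sa <- group_summary(sum(tested), mean(x[tested]), stats::sd(x[tested]))
      sb <- group_summary(sum(!tested), mean(x[!tested]), stats::sd(x[!tested]))
      r <- two_group_t(sa, sb, variant = t_variant)
      data.frame(variable = v, type = "continuous", statistic = r$t,
                 df = r$df, p = r$p, stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(x), factor(tested, levels = c(TRUE, FALSE)))
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      r <- chi_square(unclass(tab))
      data.frame(variable = v, type = "categorical", statistic = r$chi2,
                 df = r$df, p = r$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$flag <- out$p < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Read a cohort demographics table
#'
#' @param path CSV with columns `patient_id,tested,age,sex,race,ethnicity,
#'   region,tumor_area,viable_cells,site`.
#' @return data.frame with `tested` coerced to logical.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tested", "age", "sex", "race", "ethnicity",
            "region", "tumor_area", "viable_cells", "site")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df$tested <- as.logical(df$tested)
  df
}
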