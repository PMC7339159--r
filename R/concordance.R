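#' Oriented 2x2 agreement table from paired binary calls
#'
#' Cross-tabulates an index test against a reference test with a fixed
#' orientation (reference on columns): `a` = index+/ref+, `b` = index+/ref-,
#' `c` = index-/ref+, `d` = index-/ref-. Pairs with any status other than
#' the two binary labels (invalid, insufficient, missing) must be excluded
#' before tabulation; an offending pair is an error, not a silent drop.
#'
#' @param index_call,ref_call Character vectors of equal length with the
#'   index-test and reference-test calls.
#' @param positive_label,negative_label The two admissible call labels.
#' @param sample_id Optional identifiers used in error messages.
#' @param index_name,ref_name Labels for the two assays.
#' @return Object of class `agreement_table`: list with counts `a`, `b`,
#'   `c`, `d`, `n`, and the assay labels.
#' @examples
#' build_2x2(rep(c("positive", "negative"), c(3, 2)),
#'           rep(c("positive", "negative"), c(2, 3)))
#' @export
build_2x2 <- function(index_call, ref_call,
                      positive_label = "positive",
                      negative_label = "negative",
                      sample_id = NULL,
                      index_name = "index", ref_name = "reference") {
  if (length(index_call) != length(ref_call))
    stop("index_call and ref_call must have the same length")
  if (!length(index_call)) stop("no paired calls supplied")
  ok <- c(positive_label, negative_label)
  bad <- !(index_call %in% ok) | !(ref_call %in% ok)
  if (any(bad)) {
    who <- if (is.null(sample_id)) paste("row", which(bad)[1]) else
      sample_id[which(bad)[1]]
    stop("non-binary call for ", who, ": index='", index_call[which(bad)[1]],
         "', reference='", ref_call[which(bad)[1]],
         "'; exclude invalid/insufficient pairs upstream")
  }
  ip <- index_call == positive_label
  rp <- ref_call == positive_label
  structure(list(a = sum(ip & rp), b = sum(ip & !rp),
                 c = sum(!ip & rp), d = sum(!ip & !rp),
                 n = length(index_call),
                 index_name = index_name, ref_name = ref_name),
            class = "agreement_table")
}

#' Construct an agreement table directly from its four counts
#'
#' @param a,b,c,d Cell counts: `a` index+/ref+, `b` index+/ref-,
#'   `c` index-/ref+, `d` index-/ref-.
#' @inheritParams build_2x2
#' @return Object of class `agreement_table`.
#' @examples
#' agreement_table(82, 6, 12, 192, index_name = "CDx", ref_name = "CTA")
#' @export
agreement_table <- function(a, b, c, d,
                            index_name = "index", ref_name = "reference") {
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("cell counts must be nonnegative integers")
  if (sum(cnt) == 0) stop("agreement table is empty")
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), n = as.integer(sum(cnt)),
                 index_name = index_name, ref_name = ref_name),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$a + x$c, x$b, x$d, x$b + x$d,
                x$a + x$b, x$c + x$d, x$n), nrow = 3,
              dimnames = list(
                c(paste0(x$index_name, "+"), paste0(x$index_name, "-"),
                  "Total"),
                c(paste0(x$ref_name, "+"), paste0(x$ref_name, "-"), "Total")))
  print(m)
  invisible(x)
}

#' PPA, NPA and OPA with confidence intervals
#'
#' Positive percent agreement is the share of reference-positive pairs the
#' index test also calls positive, `a / (a + c)`; negative percent
#' agreement is `d / (b + d)`; overall percent agreement is
#' `(a + d) / N`. Each is returned with the requested binomial CI.
#'
#' @param table An `agreement_table`.
#' @param method CI method, `"wilson"` (default) or `"clopper_pearson"`.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return List of class `agreement_estimates` with elements `ppa`, `npa`,
#'   `opa` (each a [proportion_estimate()]).
#' @examples
#' percent_agreement(agreement_table(82, 6, 12, 192))
#' @export
percent_agreement <- function(table, method = c("wilson", "clopper_pearson"),
                              conf_level = 0.95) {
  stopifnot(inherits(table, "agreement_table"))
  method <- match.arg(method)
  if (table$a + table$c == 0)
    stop("PPA undefined: no reference-positive pairs")
  if (table$b + table$d == 0)
    stop("NPA undefined: no reference-negative pairs")
  structure(list(
    ppa = proportion_estimate(table$a, table$a + table$c, method,
                              conf_level, label = "ppa"),
    npa = proportion_estimate(table$d, table$b + table$d, method,
                              conf_level, label = "npa"),
    opa = proportion_estimate(table$a + table$d, table$n, method,
                              conf_level, label = "opa")),
    class = "agreement_estimates")
}

#' @export
print.agreement_estimates <- function(x, digits = 1, ...) {
  for (e in x) print(e, digits = digits)
  invisible(x)
}

#' @export
as.data.frame.agreement_estimates <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' Accuracy-study acceptance rule on CI lower limits
#'
#' The accuracy criteria are met when the lower limit of the two-sided
#' exact CI for PPA is at or above `ppa_floor` and the lower limit for NPA
#' is at or above `npa_floor` (both inclusive).
#'
#' @param ppa,npa [proportion_estimate()] objects carrying CI bounds.
#' @param ppa_floor,npa_floor Acceptance floors in percent (defaults 85
#'   and 90).
#' @return List with `decision` (`"pass"`/`"fail"`) and `detail`, a
#'   data.frame with one row per criterion.
#' @export
accuracy_decision <- function(ppa, npa, ppa_floor = 85, npa_floor = 90) {
  stopifnot(inherits(ppa, "prop_estimate"), inherits(npa, "prop_estimate"))
  detail <- data.frame(
    criterion = c("ppa_lower", "npa_lower"),
    ci_low = c(ppa$ci_low, npa$ci_low),
    floor = c(ppa_floor, npa_floor),
    met = c(ppa$ci_low >= ppa_floor, npa$ci_low >= npa_floor),
    stringsAsFactors = FALSE)
  list(decision = if (all(detail$met)) "pass" else "fail", detail = detail)
}

#' Read a paired-call table
#'
#' @param path CSV file with columns `sample_id,index_call,ref_call` and
#'   optionally `ddpcr_call`.
#' @return data.frame.
#' @export
read_paired_calls <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "index_call", "ref_call")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df
}
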