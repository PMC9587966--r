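#' Two-sided Wilcoxon rank-sum test
#'
#' Group-comparison workhorse used throughout the package. The reported
#' statistic `W` is the rank sum of the smaller group (group `a` on
#' equal sizes). The p-value is computed by the exact rank-sum null when
#' the pooled size is at most 12 and there are no ties, and by the
#' normal approximation with tie-corrected variance and continuity
#' correction otherwise (the exact path refuses ties).
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return List with `statistic` (W), `p_value`, `exact` (logical),
#'   `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    stopf("Wilcoxon rank-sum test needs non-empty groups")
  pooled <- c(a, b)
  r <- rank(pooled)
  swap <- length(b) < length(a)
  ns <- if (swap) length(b) else length(a)
  nl <- if (swap) length(a) else length(b)
  ranks_small <- if (swap) r[(length(a) + 1):length(pooled)] else r[seq_along(a)]
  w <- sum(ranks_small)
  ties <- anyDuplicated(pooled) > 0
  n <- ns + nl
  if (!ties && n <= 12) {
    u <- w - ns * (ns + 1) / 2
    p_lo <- stats::pwilcox(u, ns, nl)
    p_hi <- 1 - stats::pwilcox(u - 1, ns, nl)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- ns * (n + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- ns * nl / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1, exact = FALSE,
                                 n_a = length(a), n_b = length(b)))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    exact <- FALSE
  }
  list(statistic = w, p_value = p, exact = exact,
       n_a = length(a), n_b = length(b))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1; invariant
#' to the input order. Inputs must be valid p-values in `(0, 1]`.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare metric values across comparison categories
#'
#' Runs the two-sided Wilcoxon rank-sum test for every pair of
#' categories with at least `min_n` values each, then applies
#' Benjamini-Hochberg correction across that family of contrasts.
#' Sparse categories are skipped, with reasons recorded in the
#' `skipped` attribute.
#'
#' Pairwise heterogeneity values within a patient share samples and are
#' not independent; pooled testing of pairs mirrors common practice but
#' is anti-conservative. `aggregate = "patient_median"` collapses to one
#' median per patient per category first, as a sensitivity analysis.
#'
#' @param df Data frame with columns `category`, `value` and (for the
#'   aggregated mode) `patient_id`.
#' @param metric Optional metric label copied into the output.
#' @param min_n Minimum values per category (default 2).
#' @param aggregate `"pooled"` (default) or `"patient_median"`.
#' @return Data frame of contrasts: `category_a`, `category_b`, `n_a`,
#'   `n_b`, `statistic`, `p_value`, `p_adjusted`, `significance`; skipped
#'   categories in `attr(, "skipped")`.
#' @export
compare_categories <- function(df, metric = NULL, min_n = 2,
                               aggregate = c("pooled", "patient_median")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "patient_median") {
    key <- paste(df$patient_id, df$category, sep = "\r")
    agg <- tapply(df$value, key, stats::median)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    df <- data.frame(patient_id = vapply(parts, `[`, "", 1),
                     category = vapply(parts, `[`, "", 2),
                     value = as.numeric(agg), stringsAsFactors = FALSE)
  }
  values <- split(df$value, df$category)
  sizes <- lengths(values)
  ok <- names(values)[sizes >= min_n]
  n_skip <- sum(sizes < min_n)
  skipped <- data.frame(category = names(values)[sizes < min_n],
                        n = unname(sizes[sizes < min_n]),
                        reason = rep(sprintf("fewer than %d values", min_n),
                                     n_skip),
                        stringsAsFactors = FALSE)
  if (length(ok) < 2) {
    out <- data.frame(category_a = character(), category_b = character(),
                      n_a = integer(), n_b = integer(),
                      statistic = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), significance = character(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  combos <- utils::combn(sort(ok), 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    ca <- combos[1, k]; cb <- combos[2, k]
    t <- wilcoxon_rank_sum(values[[ca]], values[[cb]])
    data.frame(category_a = ca, category_b = cb,
               n_a = t$n_a, n_b = t$n_b,
               statistic = t$statistic, p_value = t$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_value)
  out$significance <- significance_stars(out$p_adjusted)
  if (!is.null(metric)) out <- cbind(metric = metric, out)
  attr(out, "skipped") <- skipped
  out
}

#' Significance stars mirroring figure annotation
#' @param p Numeric p-values.
#' @return `"***"` for p <= 0.001, `"**"` <= 0.01, `"*"` <= 0.05,
#'   `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                   ifelse(p <= 0.05, "*", "ns")))
}
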