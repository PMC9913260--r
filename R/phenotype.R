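#' Growth-rate ratios from body weights
#'
#' Growth over the first two and four weeks of life, as the ratio of body
#' weight at 14 (28) days to day-old weight.
#'
#' @param bw1,bw14,bw28 Body weights in grams (vectorised); `bw1 > 0`.
#' @return A data frame with columns `gr2wk = bw14/bw1` and
#'   `gr4wk = bw28/bw1`.
#' @examples
#' growth_rates(47.5, 305.0, 1157.0) # 6.42, 24.36
#' @export
growth_rates <- function(bw1, bw14, bw28) {
  if (any(bw1 <= 0)) stop("growth_rates: bw1 must be > 0", call. = FALSE)
  data.frame(gr2wk = bw14 / bw1, gr4wk = bw28 / bw1)
}

#' Nitric-oxide oxidation rate
#'
#' The fraction of NO metabolites already oxidised to nitrate in the
#' embryo: `nitrate / (nod + nitrate) * 100` percent, where `nod` is the
#' concentration of NO-donor compounds.
#'
#' @param nod,nitrate Concentrations in uM (vectorised, >= 0).
#' @return Percentage between 0 and 100.
#' @examples
#' no_oxidation_rate(100, 100) # 50
#' @export
no_oxidation_rate <- function(nod, nitrate) {
  if (any(nod < 0 | nitrate < 0)) {
    stop("no_oxidation_rate: concentrations must be >= 0", call. = FALSE)
  }
  if (any(nod + nitrate == 0)) {
    stop("no_oxidation_rate: undefined when nod + nitrate = 0", call. = FALSE)
  }
  100 * nitrate / (nod + nitrate)
}

#' Shapiro-Wilk normality gate
#'
#' Tests each variable for normality and recommends a correlation method:
#' rank (Spearman) correlation as soon as any variable rejects normality
#' at `alpha`, product-moment (Pearson) otherwise. Constant variables are
#' reported as degenerate (`p = NA`) and do not influence the
#' recommendation.
#'
#' @param data A data frame (non-numeric columns are dropped) or a named
#'   list of numeric vectors; at least 3 values per variable.
#' @param alpha Rejection level (default 0.05).
#' @return A data frame `variable`, `W`, `p`, `degenerate`, with
#'   attribute `recommended` (`"spearman"` or `"pearson"`).
#' @export
normality_gate <- function(data, alpha = 0.05) {
  if (is.data.frame(data)) data <- as.list(data[vapply(data, is.numeric, logical(1L))])
  if (length(data) == 0L) stop("normality_gate: no numeric variables", call. = FALSE)
  rows <- lapply(names(data), function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(x) < 3L) {
      stop("normality_gate: variable '", v, "' has fewer than 3 values",
           call. = FALSE)
    }
    if (stats::var(x) == 0) {
      return(data.frame(variable = v, W = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    sw <- stats::shapiro.test(x)
    data.frame(variable = v, W = unname(sw$statistic), p = sw$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  recommended <- if (any(out$p < alpha, na.rm = TRUE)) "spearman" else "pearson"
  structure(out, recommended = recommended)
}

#' Pairwise correlation matrix with small-sample p-values
#'
#' Spearman rank (default, per the normality gate on breed-level traits)
#' or Pearson correlations between all numeric variables. For Spearman
#' with n <= `exact_max` untied observations the p-value is the exact
#' permutation probability; otherwise the asymptotic approximation is
#' used. Pairs involving a constant variable are reported as missing.
#'
#' @param data Data frame of breed-level variables (numeric columns used).
#' @param method `"spearman"` or `"pearson"`.
#' @param exact_max Largest n for which exact Spearman p-values are
#'   requested (default 8; exactness also requires tie-free data).
#' @param ln_normalize Optional character vector of variable names to
#'   transform with the natural logarithm before correlating (used for
#'   the K coefficients, which are closer to log-normal than normal).
#' @return An object of class `"correlation_report"`: list with
#'   `variables`, matrices `rho` and `p`, `method`, and `normality`
#'   (the [normality_gate()] table).
#' @export
correlation_matrix <- function(data, method = c("spearman", "pearson"),
                               exact_max = 8L, ln_normalize = character(0L)) {
  method <- match.arg(method)
  num <- as.data.frame(data)[vapply(data, is.numeric, logical(1L))]
  for (v in ln_normalize) {
    if (!v %in% names(num)) stop("correlation_matrix: no numeric variable '", v, "'",
                                 call. = FALSE)
    if (any(num[[v]] <= 0)) stop("correlation_matrix: ln_normalize needs positive values in '",
                                 v, "'", call. = FALSE)
    num[[v]] <- log(num[[v]])
  }
  vars <- names(num)
  k <- length(vars)
  if (k < 2L) stop("correlation_matrix: need at least 2 numeric variables", call. = FALSE)
  cc <- stats::complete.cases(num)
  if (sum(cc) < 4L) stop("correlation_matrix: need >= 4 complete observations", call. = FALSE)
  num <- num[cc, , drop = FALSE]
  rho <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  pmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1
  diag(pmat) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- num[[i]]
      xj <- num[[j]]
      if (stats::var(xi) == 0 || stats::var(xj) == 0) next # undefined pair
      n <- length(xi)
      tied <- anyDuplicated(xi) > 0L || anyDuplicated(xj) > 0L
      ct <- suppressWarnings(stats::cor.test(
        xi, xj, method = method,
        exact = (method == "spearman" && n <= exact_max && !tied)))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
  }
  structure(list(variables = vars, rho = rho, p = pmat, method = method,
                 normality = normality_gate(num)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3L, ...) {
  cat(sprintf("%s correlation matrix (%d variables)\n",
              x$method, length(x$variables)))
  print(round(x$rho, digits))
  cat("p-values:\n")
  print(round(x$p, digits))
  invisible(x)
}

#' One-way ANOVA of a breed-level variable across nominal categories
#'
#' @param values Numeric vector (one value per breed).
#' @param labels Category labels (coerced to factor), same length.
#' @param ln_normalize Take the natural log of `values` first (default
#'   FALSE; used for the K coefficients before the breed-type comparison).
#' @return A list with `F`, `p`, `df` (group and residual degrees of
#'   freedom) and the fitted `aov` object.
#' @export
category_anova <- function(values, labels, ln_normalize = FALSE) {
  labels <- factor(labels)
  if (length(values) != length(labels)) {
    stop("category_anova: values and labels differ in length", call. = FALSE)
  }
  if (nlevels(labels) < 2L) {
    stop("category_anova: need at least 2 categories", call. = FALSE)
  }
  if (all(table(labels) == 1L)) {
    stop("category_anova: all groups are singletons; no residual variance",
         call. = FALSE)
  }
  if (ln_normalize) {
    if (any(values <= 0)) {
      stop("category_anova: ln_normalize needs positive values", call. = FALSE)
    }
    values <- log(values)
  }
  fit <- stats::aov(values ~ labels)
  tab <- stats::anova(fit)
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df = c(group = tab[1L, "Df"], residual = tab[2L, "Df"]), fit = fit)
}

#' Benjamini-Hochberg annotation of a correlation report
#'
#' Adds q-values (BH-adjusted p-values over the upper triangle) to a
#' [correlation_matrix()] result. Annotation only — nothing is filtered.
#'
#' @param report A `"correlation_report"`.
#' @return The report with an extra `q` matrix.
#' @export
annotate_fdr <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  p <- report$p
  ut <- upper.tri(p)
  q <- p
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  report$q <- q
  report
}
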