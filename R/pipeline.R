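#' Run the full fractal expression analysis
#'
#' Orchestrates both models and the phenotype statistics on one expression
#' panel: ranked transforms and pooled fits, per-breed rank-exponential
#' fits and MGEI, log-log dimension fits and MGEFDI, portrait
#' bioconsolidation indices, and the correlation battery against
#' phenotypes. Results are written as deterministic TSV/JSON reports plus
#' a manifest; re-running with the same inputs reproduces the files
#' byte for byte.
#'
#' @param expression An [fc_table()] or path to an expression CSV/TSV.
#'   Defaults to the bundled panel when `NULL`.
#' @param phenotypes Phenotype data frame or file path (optional; the
#'   correlation stage is skipped when absent).
#' @param out_dir Output directory (created if needed).
#' @param windows Optional manual rank windows (data frame breed, tissue,
#'   lo, hi); defaults to the bundled windows when the bundled panel is
#'   used, otherwise automatic selection.
#' @param intercept_modes Optional intercept-mode map; defaults to the
#'   bundled map for the bundled panel, otherwise zero-intercept.
#' @param max_rank_breast,max_rank_thigh Rank cuts for model 1.
#' @param tol_line,ap_tol Model 2 tolerances.
#' @param ln_normalize_k Natural-log transform of K/MGEI columns before
#'   correlating (default FALSE).
#' @param digits Significant digits in the reports.
#' @return Invisibly, a list with every stage result and the paths of the
#'   written files.
#' @examples
#' \donttest{
#' res <- run_full_analysis(out_dir = tempfile("mf"))
#' res$model1$indices
#' }
#' @export
run_full_analysis <- function(expression = NULL, phenotypes = NULL,
                              out_dir = ".",
                              windows = NULL, intercept_modes = NULL,
                              max_rank_breast = 6L, max_rank_thigh = 4L,
                              tol_line = 0.015, ap_tol = 0.1,
                              ln_normalize_k = FALSE, digits = 6L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  bundled <- is.null(expression)
  inputs <- stage("input", {
    if (bundled) {
      panel <- chick_myogenesis()
      if (is.null(windows)) windows <- panel$windows
      if (is.null(intercept_modes)) intercept_modes <- panel$intercept_modes
      if (is.null(phenotypes)) phenotypes <- panel$phenotypes
      panel$expression
    } else if (is.character(expression)) {
      read_fc_table(expression)
    } else {
      fc_table(expression)
    }
  })
  if (is.character(phenotypes)) {
    phenotypes <- stage("input", read_phenotype_table(phenotypes))
  }

  pooled <- stage("pooled", {
    lapply(stats::setNames(c("breast", "thigh"), c("breast", "thigh")),
           function(tis) {
             max_rank <- if (tis == "breast") max_rank_breast else max_rank_thigh
             fit_pooled(inputs, tis, max_rank = max_rank)
           })
  })
  model1 <- stage("model1", breed_rank_fits(inputs, max_rank_breast,
                                            max_rank_thigh, intercept_modes))
  dims <- stage("dimension", breed_dimension_fits(inputs, windows = windows,
                                                  auto = is.null(windows)))
  model2 <- stage("model2", bioconsolidation_table(inputs, tol_line = tol_line,
                                                   ap_tol = ap_tol))

  corr <- NULL
  if (!is.null(phenotypes)) {
    corr <- stage("stats", {
      merged <- merge(phenotypes, model1$indices, by = "breed")
      merged <- merge(merged, dims$indices, by = "breed")
      merged <- merge(merged, model2[, c("breed", "ind")], by = "breed")
      vars <- intersect(c("bw1", "bw14", "bw28", "gr2wk", "gr4wk", "nod",
                          "nitrate", "no_oxidation", "k_breast", "k_thigh",
                          "mgei", "d_breast", "d_thigh", "mgefdi", "ind"),
                        names(merged))
      ln_vars <- if (ln_normalize_k) {
        intersect(c("k_breast", "k_thigh", "mgei"), vars)
      } else {
        character(0L)
      }
      correlation_matrix(merged[vars], method = "spearman",
                         ln_normalize = ln_vars)
    })
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage("report", {
    p <- list()
    m1 <- merge(model1$fits,
                model1$indices[, c("breed", "mgei")], by = "breed", sort = FALSE)
    p$model1 <- write_report(m1, file.path(out_dir, "model1.tsv"),
                             format = "tsv", digits = digits)
    dm <- merge(dims$fits, dims$indices[, c("breed", "mgefdi")],
                by = "breed", sort = FALSE)
    p$dims <- write_report(dm, file.path(out_dir, "dims.tsv"),
                           format = "tsv", digits = digits)
    p$model2 <- write_report(model2, file.path(out_dir, "model2.tsv"),
                             format = "tsv", digits = digits)
    if (!is.null(corr)) {
      corr_out <- list(method = corr$method,
                       variables = corr$variables,
                       rho = signif(corr$rho, digits),
                       p = signif(corr$p, digits))
      jsonlite::write_json(corr_out, file.path(out_dir, "corr.json"),
                           digits = NA, matrix = "rowmajor", pretty = TRUE)
      p$corr <- file.path(out_dir, "corr.json")
    }
    manifest <- list(
      package = "myofractal",
      version = as.character(utils::packageVersion("myofractal")),
      n_breeds = length(unique(inputs$breed)),
      n_genes = length(unique(inputs$gene)),
      parameters = list(max_rank_breast = max_rank_breast,
                        max_rank_thigh = max_rank_thigh,
                        tol_line = tol_line, ap_tol = ap_tol,
                        ln_normalize_k = ln_normalize_k),
      pooled = lapply(pooled, function(f) {
        list(K = f$K, r_pred_actual = f$pearson_pred_actual,
             adj_r2 = f$adj_r2, n = f$n)
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p$manifest <- file.path(out_dir, "manifest.json")
    p
  })

  invisible(list(expression = inputs, pooled = pooled, model1 = model1,
                 dimensions = dims, model2 = model2, correlations = corr,
                 paths = paths))
}
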