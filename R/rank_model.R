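#' Fit the rank-exponential expression model |FC-1| = a + K * exp(N)
#'
#' The model is linear in exp(N), so it is solved by ordinary least
#' squares — exactly and deterministically, with no iterative optimiser.
#' In `"zero"` intercept mode the slope has the closed form
#' K = sum(m * exp(N)) / sum(exp(2N)); in `"free"` mode both `a` and `K`
#' are estimated.
#'
#' @param magnitude Numeric vector of |FC - 1| magnitudes.
#' @param rank Integer vector of 1-based ranks N (same length).
#' @param intercept `"zero"` (through the origin, a = 0) or `"free"`.
#' @return An object of class `"rank_fit"`: a list with elements `a`, `K`,
#'   `mode`, `n`, `r2`, `adj_r2`, `pearson_pred_actual`, `ranks_used`
#'   (range of N), and the fitted points (`magnitude`, `rank`, `fitted`).
#'   `r2`/`adj_r2` follow the usual conventions: uncentred total sum of
#'   squares for zero-intercept fits, centred otherwise.
#' @examples
#' fit_rank_exponential(0.5 * exp(1:6), 1:6)$K # 0.5
#' @export
fit_rank_exponential <- function(magnitude, rank,
                                 intercept = c("zero", "free")) {
  intercept <- match.arg(intercept)
  if (length(magnitude) != length(rank)) {
    stop("fit_rank_exponential: magnitude and rank differ in length",
         call. = FALSE)
  }
  n <- length(magnitude)
  p <- if (intercept == "free") 2L else 1L
  if (n < p + 1L) {
    stop("fit_rank_exponential: need at least ", p + 1L,
         " points for the ", intercept, "-intercept fit", call. = FALSE)
  }
  e <- exp(rank)
  if (intercept == "zero") {
    K <- sum(magnitude * e) / sum(e * e)
    a <- 0
    fitted <- K * e
    tss <- sum(magnitude^2) # uncentred, no-intercept convention
  } else {
    fit <- stats::lm.fit(cbind(1, e), magnitude)
    a <- unname(fit$coefficients[1L])
    K <- unname(fit$coefficients[2L])
    fitted <- a + K * e
    tss <- sum((magnitude - mean(magnitude))^2)
  }
  rss <- sum((magnitude - fitted)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - (p - 1L)) / (n - p)
  pearson <- if (n >= 3L && stats::sd(fitted) > 0 && stats::sd(magnitude) > 0) {
    stats::cor(fitted, magnitude)
  } else {
    NA_real_
  }
  structure(list(a = a, K = K, mode = paste0(intercept, "_intercept"),
                 n = n, ranks_used = range(rank), r2 = r2, adj_r2 = adj_r2,
                 pearson_pred_actual = pearson,
                 magnitude = magnitude, rank = rank, fitted = fitted),
            class = "rank_fit")
}

#' @export
print.rank_fit <- function(x, ...) {
  cat(sprintf("Rank-exponential fit (%s): |FC-1| = %.5g + %.5g * exp(N)\n",
              x$mode, x$a, x$K))
  cat(sprintf("  n = %d (ranks %d..%d), R2 = %.4f, adj R2 = %.4f, r(pred, actual) = %.4f\n",
              x$n, x$ranks_used[1L], x$ranks_used[2L], x$r2, x$adj_r2,
              x$pearson_pred_actual))
  invisible(x)
}

#' Pooled rank-exponential fit across breeds
#'
#' Pools the (rank, magnitude) points of every breed's ranked series for
#' one tissue, keeps ranks up to `max_rank`, and fits the through-origin
#' model. On the bundled panel, breast ranks 1-6 give 48 points and slope
#' K = 0.12962; thigh ranks 1-4 give 32 points and K = 0.16990.
#'
#' @param table An [fc_table()].
#' @param tissue `"breast"` or `"thigh"`.
#' @param max_rank Highest rank pooled (breast default 6, thigh default 4).
#' @param intercept Passed to [fit_rank_exponential()]; default `"zero"`.
#' @return A `"rank_fit"` (see [fit_rank_exponential()]).
#' @export
fit_pooled <- function(table, tissue, max_rank = if (tissue == "breast") 6L else 4L,
                       intercept = "zero") {
  if (max_rank < 2L) stop("fit_pooled: max_rank must be >= 2", call. = FALSE)
  series <- rank_series_all(table, tissue)
  short <- names(series)[vapply(series, nrow, integer(1L)) < max_rank]
  if (length(short) > 0L) {
    stop("fit_pooled: breed(s) with fewer than max_rank = ", max_rank,
         " genes: ", paste(short, collapse = ", "), call. = FALSE)
  }
  pts <- do.call(rbind, lapply(series, function(s) s[s$rank <= max_rank,
                                                     c("magnitude", "rank")]))
  fit_rank_exponential(pts$magnitude, pts$rank, intercept = intercept)
}

#' Per-breed rank-exponential fit
#'
#' @param series A [rank_series()].
#' @param max_rank Highest rank used.
#' @param intercept `"zero"` or `"free"`, see [fit_rank_exponential()].
#' @return A `"rank_fit"`.
#' @export
fit_breed <- function(series, max_rank, intercept = c("zero", "free")) {
  stopifnot(inherits(series, "ranked_series"))
  if (max_rank > nrow(series)) {
    stop("fit_breed: max_rank = ", max_rank, " exceeds the ", nrow(series),
         "-gene panel of breed '", attr(series, "breed"), "'", call. = FALSE)
  }
  keep <- series$rank <= max_rank
  fit_rank_exponential(series$magnitude[keep], series$rank[keep],
                       intercept = match.arg(intercept))
}

#' Pearson correlation of fitted against observed magnitudes
#'
#' For a zero-intercept fit this equals `cor(magnitude, exp(rank))`
#' exactly, since the fitted values are a positive rescaling of exp(rank).
#'
#' @param fit A `"rank_fit"`.
#' @return Pearson correlation over the points used in the fit.
#' @export
predicted_vs_actual_correlation <- function(fit) {
  stopifnot(inherits(fit, "rank_fit"))
  if (fit$n < 3L) {
    stop("predicted_vs_actual_correlation: undefined for fewer than 3 points",
         call. = FALSE)
  }
  stats::cor(fit$fitted, fit$magnitude)
}

#' Myogenesis gene expression index, MGEI = K(breast) / K(thigh)
#'
#' @param k_breast,k_thigh Unrounded slope coefficients of the two tissues.
#' @return The ratio, a dimensionless index.
#' @examples
#' compute_mgei(0.0698, 0.0255)
#' @export
compute_mgei <- function(k_breast, k_thigh) {
  if (any(k_thigh == 0)) {
    stop("compute_mgei: undefined for k_thigh = 0", call. = FALSE)
  }
  k_breast / k_thigh
}

#' Per-breed rank-exponential fits and MGEI for a whole panel
#'
#' Runs [fit_breed()] for every breed and both tissues, using the given
#' intercept-mode map (or through-origin everywhere when `NULL`), and
#' derives MGEI from the unrounded slopes.
#'
#' @param table An [fc_table()] with both tissues per breed.
#' @param max_rank_breast,max_rank_thigh Rank cuts (defaults 6 and 4: the
#'   ranks the pooled exponential explains in each tissue).
#' @param intercept_modes Optional data frame `breed`, `tissue`, `mode`
#'   (`"zero"`/`"free"`), as in `chick_myogenesis()$intercept_modes`;
#'   unlisted combinations default to `"zero"`.
#' @return A list with `fits` (data frame: breed, tissue, mode, a, K, r2,
#'   adj_r2, n) and `indices` (data frame: breed, k_breast, k_thigh, mgei).
#' @examples
#' panel <- chick_myogenesis()
#' breed_rank_fits(panel$expression,
#'                 intercept_modes = panel$intercept_modes)$indices
#' @export
breed_rank_fits <- function(table, max_rank_breast = 6L, max_rank_thigh = 4L,
                            intercept_modes = NULL) {
  breeds <- unique(table$breed)
  mode_of <- function(b, tis) {
    if (is.null(intercept_modes)) return("zero")
    hit <- intercept_modes$breed == b & intercept_modes$tissue == tis
    if (any(hit)) intercept_modes$mode[which(hit)[1L]] else "zero"
  }
  rows <- list()
  idx <- list()
  for (b in breeds) {
    ks <- c(breast = NA_real_, thigh = NA_real_)
    for (tis in c("breast", "thigh")) {
      max_rank <- if (tis == "breast") max_rank_breast else max_rank_thigh
      fit <- fit_breed(rank_series(table, b, tis), max_rank,
                       intercept = mode_of(b, tis))
      ks[[tis]] <- fit$K
      rows[[length(rows) + 1L]] <- data.frame(
        breed = b, tissue = tis, mode = mode_of(b, tis), a = fit$a, K = fit$K,
        r2 = fit$r2, adj_r2 = fit$adj_r2, n = fit$n, stringsAsFactors = FALSE)
    }
    idx[[length(idx) + 1L]] <- data.frame(
      breed = b, k_breast = ks[["breast"]], k_thigh = ks[["thigh"]],
      mgei = compute_mgei(ks[["breast"]], ks[["thigh"]]),
      stringsAsFactors = FALSE)
  }
  list(fits = do.call(rbind, rows), indices = do.call(rbind, idx))
}
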