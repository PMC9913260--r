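#' Fractal dimension of a ranked expression series
#'
#' Fits the log-log line lg|FC - 1| = D * lg(N) + lg(c) by ordinary least
#' squares over a contiguous rank window: the slope is the fractal
#' dimension D, the back-transformed intercept is the offset c. Logs are
#' base 10 ("lg"); the slope is base-invariant but c is quoted in the
#' base-10 parameterisation.
#'
#' @param series A [rank_series()].
#' @param window Integer vector of ranks (contiguous, length >= 3), or a
#'   list/vector with elements `lo`, `hi`.
#' @return An object of class `"dimension_fit"`: list with `D`, `c`,
#'   `window` (c(lo, hi)), `r2`, `n` and the points used.
#' @examples
#' s <- structure(data.frame(gene = paste0("g", 1:6),
#'                           magnitude = 3 * (1:6)^1.7, rank = 1:6),
#'                class = c("ranked_series", "data.frame"))
#' fit_dimension(s, 1:6) # D = 1.7, c = 3
#' @export
fit_dimension <- function(series, window) {
  stopifnot(inherits(series, "ranked_series"))
  window <- as_rank_window(window)
  ranks <- seq.int(window[1L], window[2L])
  if (length(ranks) < 3L) {
    stop("fit_dimension: window must span at least 3 ranks", call. = FALSE)
  }
  if (window[2L] > nrow(series)) {
    stop("fit_dimension: window [", window[1L], ":", window[2L],
         "] exceeds the ", nrow(series), "-gene series", call. = FALSE)
  }
  keep <- series$rank %in% ranks
  m <- series$magnitude[keep]
  if (any(m <= 0)) {
    stop("fit_dimension: zero magnitude inside window (log undefined) for gene(s): ",
         paste(series$gene[keep][m <= 0], collapse = ", "), call. = FALSE)
  }
  lx <- log10(series$rank[keep])
  ly <- log10(m)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  D <- unname(fit$coefficients[2L])
  c0 <- 10^unname(fit$coefficients[1L])
  rss <- sum(fit$residuals^2)
  tss <- sum((ly - mean(ly))^2)
  structure(list(D = D, c = c0, window = window,
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(ly), rank = series$rank[keep], magnitude = m),
            class = "dimension_fit")
}

#' @export
print.dimension_fit <- function(x, ...) {
  cat(sprintf("Log-log dimension fit: D = %.4f, c = %.4g, window [%d:%d], R2 = %.4f\n",
              x$D, x$c, x$window[1L], x$window[2L], x$r2))
  invisible(x)
}

as_rank_window <- function(window) {
  if (is.list(window)) window <- unlist(window[c("lo", "hi")])
  window <- as.integer(window)
  w <- c(min(window), max(window))
  if (w[1L] < 1L) stop("rank window must start at rank >= 1", call. = FALSE)
  w
}

#' Pointwise log-ratio "dimension" (deprecated)
#'
#' The pointwise ratio lg|FC - 1| / lg(N) of a single gene. Kept for
#' completeness; it is not the estimator behind the reported per-breed
#' dimensions, which come from the regression slope of [fit_dimension()].
#' Undefined at rank 1 (lg 1 = 0).
#'
#' @param magnitude,rank Magnitude and rank of one gene (vectorised).
#' @return The pointwise ratio(s).
#' @keywords internal
#' @export
pointwise_dimension <- function(magnitude, rank) {
  .Deprecated("fit_dimension")
  if (any(magnitude <= 0) || any(rank <= 1)) {
    stop("pointwise_dimension: needs magnitude > 0 and rank > 1", call. = FALSE)
  }
  log10(magnitude) / log10(rank)
}

#' Automatic rank-window selection for the dimension fit
#'
#' Enumerates every contiguous window of length >= `min_len` inside the
#' tissue's default rank range extended by one extra rank, fits the
#' log-log line on each, and returns the window with the highest R2
#' (ties: longer window, then smaller starting rank). A manual `override`
#' always wins — the bundled panel uses the hand-picked windows of the
#' original analysis as overrides.
#'
#' @param series A [rank_series()].
#' @param min_len Minimum window length (>= 3).
#' @param default Default rank range as c(lo, hi); the search space is
#'   `lo .. min(hi + 1, panel size)`.
#' @param override Optional manual window; returned unchanged.
#' @return A window as c(lo, hi).
#' @export
select_window <- function(series, min_len = 3L, default = c(1L, 6L),
                          override = NULL) {
  stopifnot(inherits(series, "ranked_series"))
  if (!is.null(override)) return(as_rank_window(override))
  if (min_len < 3L) stop("select_window: min_len must be >= 3", call. = FALSE)
  if (nrow(series) < min_len) {
    stop("select_window: series shorter than min_len", call. = FALSE)
  }
  default <- as_rank_window(default)
  lo0 <- default[1L]
  hi0 <- min(default[2L] + 1L, nrow(series))
  best <- NULL
  best_key <- c(-Inf, -Inf, Inf) # r2, length, -lo
  for (lo in lo0:(hi0 - min_len + 1L)) {
    for (hi in (lo + min_len - 1L):hi0) {
      keep <- series$rank >= lo & series$rank <= hi
      if (any(series$magnitude[keep] <= 0)) next
      fit <- fit_dimension(series, c(lo, hi))
      key <- c(fit$r2, hi - lo + 1L, -lo)
      if (is.null(best) ||
          key[1L] > best_key[1L] + 1e-12 ||
          (abs(key[1L] - best_key[1L]) <= 1e-12 &&
           (key[2L] > best_key[2L] ||
            (key[2L] == best_key[2L] && key[3L] > best_key[3L])))) {
        best <- c(lo, hi)
        best_key <- key
      }
    }
  }
  if (is.null(best)) {
    stop("select_window: no window with positive magnitudes", call. = FALSE)
  }
  best
}

#' Myogenesis gene expression fractal dimension index,
#' MGEFDI = D(breast) / D(thigh)
#'
#' @param d_breast,d_thigh Unrounded fractal dimensions of the two tissues.
#' @return The ratio.
#' @export
compute_mgefdi <- function(d_breast, d_thigh) {
  if (any(d_thigh == 0)) {
    stop("compute_mgefdi: undefined for d_thigh = 0", call. = FALSE)
  }
  d_breast / d_thigh
}

#' Per-breed dimension fits and MGEFDI for a whole panel
#'
#' @param table An [fc_table()] with both tissues per breed.
#' @param windows Optional data frame `breed`, `tissue`, `lo`, `hi` of
#'   manual windows (as in `chick_myogenesis()$windows`). Combinations not
#'   listed fall back to `auto` selection or the tissue default range.
#' @param auto When `TRUE`, windows not manually given are chosen by
#'   [select_window()]; when `FALSE` the tissue default ranges (breast
#'   1-6, thigh 1-4) are used directly.
#' @param default_breast,default_thigh Default rank ranges per tissue.
#' @return A list with `fits` (breed, tissue, D, c, lo, hi, r2) and
#'   `indices` (breed, d_breast, d_thigh, mgefdi).
#' @examples
#' panel <- chick_myogenesis()
#' breed_dimension_fits(panel$expression, windows = panel$windows)$indices
#' @export
breed_dimension_fits <- function(table, windows = NULL, auto = FALSE,
                                 default_breast = c(1L, 6L),
                                 default_thigh = c(1L, 4L)) {
  breeds <- unique(table$breed)
  window_of <- function(s, b, tis) {
    if (!is.null(windows)) {
      hit <- windows$breed == b & windows$tissue == tis
      if (any(hit)) {
        return(c(windows$lo[which(hit)[1L]], windows$hi[which(hit)[1L]]))
      }
    }
    default <- if (tis == "breast") default_breast else default_thigh
    if (auto) select_window(s, default = default) else as_rank_window(default)
  }
  rows <- list()
  idx <- list()
  for (b in breeds) {
    ds <- c(breast = NA_real_, thigh = NA_real_)
    for (tis in c("breast", "thigh")) {
      s <- rank_series(table, b, tis)
      w <- window_of(s, b, tis)
      fit <- fit_dimension(s, w)
      ds[[tis]] <- fit$D
      rows[[length(rows) + 1L]] <- data.frame(
        breed = b, tissue = tis, D = fit$D, c = fit$c,
        lo = fit$window[1L], hi = fit$window[2L], r2 = fit$r2,
        stringsAsFactors = FALSE)
    }
    idx[[length(idx) + 1L]] <- data.frame(
      breed = b, d_breast = ds[["breast"]], d_thigh = ds[["thigh"]],
      mgefdi = compute_mgefdi(ds[["breast"]], ds[["thigh"]]),
      stringsAsFactors = FALSE)
  }
  list(fits = do.call(rbind, rows), indices = do.call(rbind, idx))
}

#' Linear regression of a breed trait on fractal dimension
#'
#' Relates per-breed dimensions (typically D in the breast muscle) to a
#' phenotype trait such as body weight at 28 days.
#'
#' @param dims Data frame with columns `breed` and `D` (e.g. a subset of
#'   `breed_dimension_fits()$fits`).
#' @param phenotypes Phenotype data frame with a `breed` column.
#' @param trait Name of the trait column in `phenotypes`.
#' @return A list with `slope`, `intercept`, `r2` and `n` of the OLS fit
#'   of trait on D across the breeds common to both tables.
#' @export
dimension_trait_regression <- function(dims, phenotypes, trait = "bw28") {
  merged <- merge(dims[, c("breed", "D")], phenotypes[, c("breed", trait)],
                  by = "breed")
  if (nrow(merged) < 3L) {
    stop("dimension_trait_regression: fewer than 3 breeds in common",
         call. = FALSE)
  }
  yv <- merged[[trait]]
  if (stats::var(yv) == 0) {
    return(list(slope = 0, intercept = yv[1L], r2 = 0, n = nrow(merged)))
  }
  fit <- stats::lm(yv ~ D, data = merged)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = summary(fit)$r.squared, n = nrow(merged))
}
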