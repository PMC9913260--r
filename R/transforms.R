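#' Magnitude of differential expression, |FC - 1|
#'
#' Folds the signed fold-change scale onto the positive half-axis: the
#' housekeeping reference (FC = 1) maps to 0, and an upregulated gene with
#' FC = 6 and a downregulated gene with FC = -4 both map to 5, i.e. the
#' same distance from the reference level. Direction is discarded,
#' magnitude preserved.
#'
#' @param fc Signed fold change(s); must be non-zero.
#' @return `abs(fc - 1)`, vectorised.
#' @examples
#' fc_to_magnitude(c(6, -4, 1)) # 5 5 0
#' @export
fc_to_magnitude <- function(fc) {
  if (any(!is.finite(fc) | fc == 0)) {
    stop("fc_to_magnitude: fc must be finite and non-zero", call. = FALSE)
  }
  abs(fc - 1)
}

#' Signed log2 recoding of a fold change
#'
#' The portrait transform: `-log2(fc)` for upregulated genes (fc > 0) and
#' `+log2(|fc|)` for downregulated ones (fc < 0), so that strong
#' downregulation maps to large positive values. The housekeeping
#' reference (fc = 1) maps to 0.
#'
#' @param fc Signed fold change(s); must be non-zero.
#' @return Transformed value(s) in log2 units.
#' @examples
#' fc_to_lg(4.89)    # -2.29
#' fc_to_lg(-685.02) #  9.42
#' @export
fc_to_lg <- function(fc) {
  if (any(!is.finite(fc) | fc == 0)) {
    stop("fc_to_lg: fc must be finite and non-zero", call. = FALSE)
  }
  ifelse(fc > 0, -log2(abs(fc)), log2(abs(fc)))
}

#' Rank a breed/tissue panel by expression-change magnitude
#'
#' Extracts one breed/tissue group from a fold-change table, converts FC
#' values to magnitudes |FC - 1|, and assigns ascending 1-based ranks N.
#' The housekeeping gene is excluded (its magnitude is 0 by definition and
#' carries no information for the rank models). Ties are broken by input
#' row order (stable sort), so ranking is deterministic and idempotent.
#'
#' @param table An [fc_table()].
#' @param breed,tissue Group selectors.
#' @param ties `"input"` (default; stable order of appearance) or
#'   `"average"` — with average ties the tied magnitudes share the mean of
#'   their order positions, which only matters for panels with exact ties.
#' @return A data frame of class `"ranked_series"` with columns `gene`,
#'   `magnitude`, `rank`, and attributes `breed` and `tissue`.
#' @examples
#' panel <- chick_myogenesis()
#' rank_series(panel$expression, "WC", "breast")
#' @export
rank_series <- function(table, breed, tissue, ties = c("input", "average")) {
  ties <- match.arg(ties)
  stopifnot(inherits(table, "fc_table"))
  idx <- table$breed == breed & table$tissue == tissue
  if (!any(idx)) {
    stop("rank_series: no rows for breed '", breed, "', tissue '", tissue, "'",
         call. = FALSE)
  }
  grp <- table[idx, , drop = FALSE]
  grp <- grp[grp$gene != housekeeping_gene(table), , drop = FALSE]
  if (nrow(grp) == 0L) {
    stop("rank_series: panel contains only the housekeeping gene", call. = FALSE)
  }
  m <- fc_to_magnitude(grp$fc)
  ord <- order(m) # stable: ties keep input order
  out <- data.frame(gene = grp$gene[ord], magnitude = m[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (ties == "average") {
    out$rank <- stats::ave(out$rank, out$magnitude, FUN = mean)
  }
  structure(out, class = c("ranked_series", "data.frame"),
            breed = breed, tissue = tissue)
}

#' @export
print.ranked_series <- function(x, ...) {
  cat(sprintf("Ranked |FC-1| series: %s / %s (%d genes)\n",
              attr(x, "breed"), attr(x, "tissue"), nrow(x)))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Ranked series for every breed of one tissue
#'
#' @param table An [fc_table()].
#' @param tissue Tissue selector.
#' @return Named list of [rank_series()] results, one per breed, in order
#'   of first appearance in `table`.
#' @export
rank_series_all <- function(table, tissue) {
  breeds <- unique(table$breed[table$tissue == tissue])
  if (length(breeds) == 0L) {
    stop("rank_series_all: no rows for tissue '", tissue, "'", call. = FALSE)
  }
  stats::setNames(lapply(breeds, function(b) rank_series(table, b, tissue)),
                  breeds)
}

#' Build a fractal portrait of a breed/tissue panel
#'
#' Each gene (including the housekeeping reference, appended with FC = 1
#' when absent) is transformed with [fc_to_lg()]; the panel minimum is
#' subtracted so the smallest shifted value is exactly 0 (the Y
#' coordinate), and the fractional part of Y gives the X coordinate in
#' [0, 1). Gene sets whose shifted values form an arithmetic progression
#' appear as collinear points in the portrait.
#'
#' @param table An [fc_table()].
#' @param breed,tissue Group selectors.
#' @return A data frame of class `"portrait"` with columns `gene`, `fc`,
#'   `lg`, `y`, `x` and attributes `breed`, `tissue`.
#' @examples
#' panel <- chick_myogenesis()
#' build_portrait(panel$expression, "WC", "breast")
#' @export
build_portrait <- function(table, breed, tissue) {
  stopifnot(inherits(table, "fc_table"))
  idx <- table$breed == breed & table$tissue == tissue
  if (!any(idx)) {
    stop("build_portrait: no rows for breed '", breed, "', tissue '", tissue,
         "'", call. = FALSE)
  }
  grp <- as.data.frame(table[idx, c("gene", "fc")])
  hk <- housekeeping_gene(table)
  if (!hk %in% grp$gene) {
    grp <- rbind(grp, data.frame(gene = hk, fc = 1))
  }
  lg <- fc_to_lg(grp$fc)
  y <- lg - min(lg)
  out <- data.frame(gene = grp$gene, fc = grp$fc, lg = lg, y = y,
                    x = y - floor(y), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("portrait", "data.frame"),
            breed = breed, tissue = tissue)
}

#' @export
print.portrait <- function(x, ...) {
  cat(sprintf("Fractal portrait: %s / %s (%d genes, min lg = %.4g)\n",
              attr(x, "breed"), attr(x, "tissue"), nrow(x), min(x$lg)))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Plot a fractal portrait
#'
#' Scatter of portrait points (X = fractional part of shifted expression,
#' Y = shifted expression) with dotted lines through detected expression
#' fractals.
#'
#' @param x A [build_portrait()] result.
#' @param sets Optional result of [detect_collinear_sets()]; computed at
#'   `tol` when `NULL`.
#' @param tol Collinearity tolerance forwarded to [detect_collinear_sets()].
#' @param ... Passed to [graphics::plot()].
#' @return `invisible(x)`.
#' @export
plot.portrait <- function(x, sets = NULL, tol = 0.015, ...) {
  if (is.null(sets)) sets <- detect_collinear_sets(x, tol = tol)
  graphics::plot(x$x, x$y, pch = 19, xlim = c(0, 1),
                 xlab = "fractional part of shifted expression",
                 ylab = "shifted expression (log2 units)",
                 main = sprintf("%s / %s", attr(x, "breed"), attr(x, "tissue")),
                 ...)
  graphics::text(x$x, x$y, labels = x$gene, pos = 4, cex = 0.7)
  for (s in sets) {
    if (is.finite(s$line[["slope"]])) {
      graphics::abline(a = s$line[["intercept"]], b = s$line[["slope"]], lty = 3)
    } else {
      graphics::abline(v = s$line[["intercept"]], lty = 3)
    }
  }
  invisible(x)
}
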