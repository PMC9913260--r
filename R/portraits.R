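#' Detect arithmetic progressions among shifted expression values
#'
#' An "expression fractal" in arithmetic-series form: a set of at least
#' three genes whose sorted shifted log expressions form an arithmetic
#' progression, i.e. the spread (max - min) of successive differences does
#' not exceed `tol`. All maximal qualifying subsets are returned
#' (overlaps allowed); subsets of a reported set are not reported again.
#'
#' @param values Named numeric vector (names = genes) of shifted
#'   expression values, e.g. the `y` column of [build_portrait()].
#' @param tol Absolute tolerance on the successive-difference spread.
#' @return A list of `"fractal_set"` objects (fields `genes`, `values`,
#'   `common_difference`, `spread`), sorted by size (descending) then by
#'   gene names; empty list when fewer than 3 values are supplied.
#' @examples
#' detect_arithmetic_sets(c(MSTN = 0.20, MYOD1 = 1.36, TBP = 2.49), tol = 0.05)
#' @export
detect_arithmetic_sets <- function(values, tol = 0.1) {
  if (tol <= 0) stop("detect_arithmetic_sets: tol must be > 0", call. = FALSE)
  if (length(values) < 3L) return(list())
  if (length(values) > 16L) {
    stop("detect_arithmetic_sets: exhaustive search supports panels of <= 16 genes",
         call. = FALSE)
  }
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  n <- length(values)
  hits <- list()
  for (k in n:3L) {
    for (cols in utils::combn(n, k, simplify = FALSE)) {
      y <- sort(values[cols])
      d <- diff(y)
      if (max(d) - min(d) <= tol) hits[[length(hits) + 1L]] <- cols
    }
  }
  hits <- .maximal_sets(hits)
  sets <- lapply(hits, function(cols) {
    y <- sort(values[cols])
    d <- diff(y)
    structure(list(genes = sort(names(values)[cols]), values = unname(y),
                   common_difference = mean(d), spread = max(d) - min(d)),
              class = "fractal_set")
  })
  .order_sets(sets)
}

#' Detect collinear gene sets in a fractal portrait
#'
#' The geometric form of an expression fractal: for every pair of portrait
#' points, all points within perpendicular distance `tol` of the line
#' through the pair are collected; sets of at least three points qualify,
#' and only maximal sets are kept.
#'
#' Points with shifted expression y < 1 lie on the identity line y = x by
#' construction (their fractional part equals the value itself), so
#' collinearity on that line carries no information about the expression
#' structure. For a candidate set lying wholly on the identity line the
#' detector therefore falls back to the defining arithmetic-progression
#' condition: the set is replaced by its maximal AP subsets at `ap_tol`
#' (see [detect_arithmetic_sets()]), which may be empty.
#'
#' @param points A [build_portrait()] result (or any data frame with
#'   columns `gene`, `x`, `y`).
#' @param tol Perpendicular-distance tolerance in portrait units. The
#'   default 0.015 is calibrated once on the bundled White Cornish
#'   portraits, where both tissues yield six member genes; the calibration
#'   is stable over roughly 0.013 to 0.016.
#' @param ap_tol Arithmetic-progression tolerance used only for
#'   identity-line candidates.
#' @return A list of `"fractal_set"` objects (fields `genes`, `line` =
#'   c(slope, intercept) — for vertical lines slope is `Inf` and intercept
#'   is the x position — and `max_residual`, the largest perpendicular
#'   distance among members), ordered by size then gene names.
#' @examples
#' panel <- chick_myogenesis()
#' detect_collinear_sets(build_portrait(panel$expression, "WC", "breast"))
#' @export
detect_collinear_sets <- function(points, tol = 0.015, ap_tol = 0.1) {
  if (tol <= 0) stop("detect_collinear_sets: tol must be > 0", call. = FALSE)
  pts <- as.data.frame(points)
  if (nrow(pts) < 3L) return(list())
  x <- pts$x
  y <- pts$y
  n <- nrow(pts)
  on_identity <- abs(y - x) < 1e-9
  hits <- list()
  lines <- list()
  resid <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      len <- sqrt(dx^2 + dy^2)
      if (len == 0) next
      d <- abs(dy * (x - x[i]) - dx * (y - y[i])) / len
      set <- which(d <= tol)
      if (length(set) < 3L) next
      if (all(on_identity[set])) {
        # fractional-part artifact: on y = x collinearity is vacuous, so
        # keep only subsets that satisfy the AP condition in their own right
        aps <- detect_arithmetic_sets(stats::setNames(y[set], set), tol = ap_tol)
        for (ap in aps) {
          sub <- as.integer(ap$genes)
          hits[[length(hits) + 1L]] <- sub
          lines[[length(lines) + 1L]] <- c(slope = 1, intercept = 0)
          resid[[length(resid) + 1L]] <- 0
        }
        next
      }
      hits[[length(hits) + 1L]] <- set
      lines[[length(lines) + 1L]] <- if (dx == 0) {
        c(slope = Inf, intercept = x[i])
      } else {
        c(slope = dy / dx, intercept = y[i] - dy / dx * x[i])
      }
      resid[[length(resid) + 1L]] <- max(d[set])
    }
  }
  keep <- .maximal_sets_idx(hits)
  sets <- lapply(keep, function(k) {
    structure(list(genes = sort(pts$gene[hits[[k]]]), line = lines[[k]],
                   max_residual = resid[[k]]),
              class = "fractal_set")
  })
  .order_sets(sets)
}

#' @export
print.fractal_set <- function(x, ...) {
  cat("Expression fractal: {", paste(x$genes, collapse = ", "), "}", sep = "")
  if (!is.null(x$line)) {
    cat(sprintf("  line slope = %.3g, max residual = %.3g",
                x$line[["slope"]], x$max_residual))
  } else {
    cat(sprintf("  common difference = %.3g, spread = %.3g",
                x$common_difference, x$spread))
  }
  cat("\n")
  invisible(x)
}

# maximal (not contained in a larger qualifying set) subsets; returns sets
.maximal_sets <- function(hits) {
  hits <- unique(lapply(hits, sort))
  hits[.maximal_filter(hits)]
}

# same but returns indices into hits (first occurrence of each unique set)
.maximal_sets_idx <- function(hits) {
  sorted <- lapply(hits, sort)
  first <- which(!duplicated(sorted))
  first[.maximal_filter(sorted[first])]
}

.maximal_filter <- function(sets) {
  if (length(sets) == 0L) return(logical(0L))
  vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && length(sets[[j]]) > length(sets[[i]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1L)))
  }, logical(1L))
}

.order_sets <- function(sets) {
  if (length(sets) == 0L) return(sets)
  sizes <- vapply(sets, function(s) length(s$genes), integer(1L))
  labels <- vapply(sets, function(s) paste(s$genes, collapse = ","), character(1L))
  sets[order(-sizes, labels)]
}

#' Bioconsolidation index of gene expression
#'
#' Ind = sqrt(N_B * N_T) / N_G: the geometric mean of the per-tissue
#' counts of genes belonging to any expression fractal, as a fraction of
#' the total number of controlled genes. Ranges from 0 (no fractal in at
#' least one tissue) to 1 (all genes consolidated in both tissues).
#'
#' @param n_breast,n_thigh Member-gene counts per tissue.
#' @param n_genes Total number of controlled genes (8 for the bundled
#'   seven-gene panel plus housekeeping).
#' @return The index, a value between 0 and 1.
#' @examples
#' bioconsolidation_index(6, 6, 8) # 0.75
#' @export
bioconsolidation_index <- function(n_breast, n_thigh, n_genes = 8L) {
  if (n_genes <= 0) stop("bioconsolidation_index: n_genes must be > 0", call. = FALSE)
  if (any(c(n_breast, n_thigh) < 0) || any(c(n_breast, n_thigh) > n_genes)) {
    stop("bioconsolidation_index: counts must lie in [0, n_genes]", call. = FALSE)
  }
  sqrt(n_breast * n_thigh) / n_genes
}

#' Run the portrait model for one breed
#'
#' Builds the breast and thigh portraits, detects collinear expression
#' fractals in each, counts the union of member genes per tissue, and
#' applies the bioconsolidation formula with N_G = panel size including
#' the housekeeping gene.
#'
#' @param table An [fc_table()] with both tissues for `breed`.
#' @param breed Breed identifier.
#' @param tol_line,ap_tol Tolerances, see [detect_collinear_sets()].
#' @return A list of class `"bioconsolidation"`: `breed`, `n_breast`,
#'   `n_thigh`, `n_genes`, `ind`, plus `sets_breast`, `sets_thigh`,
#'   `members_breast`, `members_thigh` and the two portraits.
#' @examples
#' panel <- chick_myogenesis()
#' run_model2(panel$expression, "WC")$ind # 0.75
#' @export
run_model2 <- function(table, breed, tol_line = 0.015, ap_tol = 0.1) {
  for (tis in c("breast", "thigh")) {
    if (!any(table$breed == breed & table$tissue == tis)) {
      stop("run_model2: breed '", breed, "' lacks tissue '", tis, "'",
           call. = FALSE)
    }
  }
  pb <- build_portrait(table, breed, "breast")
  pt <- build_portrait(table, breed, "thigh")
  if (nrow(pb) != nrow(pt)) {
    stop("run_model2: breast and thigh panels differ in size", call. = FALSE)
  }
  sb <- detect_collinear_sets(pb, tol = tol_line, ap_tol = ap_tol)
  st <- detect_collinear_sets(pt, tol = tol_line, ap_tol = ap_tol)
  mb <- sort(unique(unlist(lapply(sb, `[[`, "genes"))))
  mt <- sort(unique(unlist(lapply(st, `[[`, "genes"))))
  ng <- nrow(pb)
  structure(list(breed = breed, n_breast = length(mb), n_thigh = length(mt),
                 n_genes = ng,
                 ind = bioconsolidation_index(length(mb), length(mt), ng),
                 members_breast = mb, members_thigh = mt,
                 sets_breast = sb, sets_thigh = st,
                 portrait_breast = pb, portrait_thigh = pt),
            class = "bioconsolidation")
}

#' @export
print.bioconsolidation <- function(x, ...) {
  cat(sprintf("Bioconsolidation of %s: N_B = %d, N_T = %d of %d genes, Ind = %.4g\n",
              x$breed, x$n_breast, x$n_thigh, x$n_genes, x$ind))
  cat("  breast members:", paste(x$members_breast, collapse = ", "), "\n")
  cat("  thigh members: ", paste(x$members_thigh, collapse = ", "), "\n")
  invisible(x)
}

#' Bioconsolidation indices for every breed of a panel
#'
#' @param table An [fc_table()] with both tissues per breed.
#' @param tol_line,ap_tol Tolerances, see [detect_collinear_sets()].
#' @return Data frame: breed, n_breast, n_thigh, n_genes, ind.
#' @export
bioconsolidation_table <- function(table, tol_line = 0.015, ap_tol = 0.1) {
  breeds <- unique(table$breed)
  do.call(rbind, lapply(breeds, function(b) {
    r <- run_model2(table, b, tol_line = tol_line, ap_tol = ap_tol)
    data.frame(breed = b, n_breast = r$n_breast, n_thigh = r$n_thigh,
               n_genes = r$n_genes, ind = r$ind, stringsAsFactors = FALSE)
  }))
}
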