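# shared helpers and independent oracles for the test suite

# build a ranked_series directly from magnitudes (bypasses fc encoding)
make_series <- function(magnitude, breed = "s1", tissue = "breast") {
  ord <- order(magnitude)
  structure(data.frame(gene = paste0("g", seq_along(magnitude))[ord],
                       magnitude = magnitude[ord],
                       rank = seq_along(magnitude),
                       stringsAsFactors = FALSE),
            class = c("ranked_series", "data.frame"),
            breed = breed, tissue = tissue)
}

# exhaustive-triples oracle for collinear membership: a gene is a member
# iff it belongs to some triple in which all three points lie within tol
# of the line through two of them; identity-line triples (x == y for all
# three) count only if their y values form an arithmetic progression.
oracle_collinear_members <- function(pts, tol, ap_tol = 0.1) {
  n <- nrow(pts)
  members <- character(0)
  if (n < 3L) return(members)
  for (tri in utils::combn(n, 3L, simplify = FALSE)) {
    x <- pts$x[tri]; y <- pts$y[tri]
    hit <- FALSE
    for (p in 1:3) {
      ij <- setdiff(1:3, p)
      dx <- x[ij[2]] - x[ij[1]]; dy <- y[ij[2]] - y[ij[1]]
      len <- sqrt(dx^2 + dy^2)
      if (len == 0) next
      d <- abs(dy * (x[p] - x[ij[1]]) - dx * (y[p] - y[ij[1]])) / len
      if (d <= tol) { hit <- TRUE; break }
    }
    if (!hit) next
    if (all(abs(y - x) < 1e-9)) {
      dd <- diff(sort(y))
      if (max(dd) - min(dd) > ap_tol) next
    }
    members <- union(members, pts$gene[tri])
  }
  sort(members)
}

# brute-force AP enumeration via bit masks, independent of the package's
# combn-based search
oracle_ap_sets <- function(values, tol) {
  n <- length(values)
  found <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 3L) next
    d <- diff(sort(values[idx]))
    if (max(d) - min(d) <= tol) found[[length(found) + 1L]] <- sort(idx)
  }
  # keep maximal sets only
  keep <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      j != i && length(found[[j]]) > length(found[[i]]) &&
        all(found[[i]] %in% found[[j]])
    }, logical(1)))
  }, logical(1))
  unique(found[keep])
}

# portrait-consistent random point panel: y drawn, x = fractional part
random_portrait_points <- function(n, ymax = 8) {
  y <- sort(stats::runif(n, 0, ymax))
  y <- y - min(y)
  data.frame(gene = paste0("g", seq_len(n)), y = y, x = y - floor(y),
             stringsAsFactors = FALSE)
}

# union of member genes over a list of fractal_set objects
member_union <- function(sets) {
  sort(unique(as.character(unlist(lapply(sets, `[[`, "genes")))))
}
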