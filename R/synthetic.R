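#' Specification of a synthetic expression panel
#'
#' Describes a panel generator: the latent model, panel dimensions, model
#' parameters, noise level and seed. Identical specs generate identical
#' panels.
#'
#' @param model `"rank_exponential"` (|FC-1| = a + K*exp(N) plus additive
#'   Gaussian noise), `"power_law"` (|FC-1| = c*N^D times log-normal
#'   noise), or `"portrait_ap"` (arithmetic progressions of signed log2
#'   expression planted in fractal portraits).
#' @param n_breeds,n_genes Panel dimensions (regular genes, excluding the
#'   housekeeping reference).
#' @param params Named list of model parameters: `a`, `K` for
#'   `rank_exponential`; `c`, `D` for `power_law`; `n_members` (count of
#'   member genes per tissue, housekeeping included; 0 or >= 3) and
#'   `common_difference` for `portrait_ap`.
#' @param noise_sd Noise level (>= 0): SD of the additive Gaussian noise
#'   on magnitudes, or of the log-normal factor for `power_law`.
#' @param seed Integer seed; every random draw in the generator derives
#'   from it.
#' @return A validated list of class `"synth_spec"`.
#' @export
synth_spec <- function(model = c("rank_exponential", "power_law", "portrait_ap"),
                       n_breeds = 1L, n_genes = 7L, params = list(),
                       noise_sd = 0, seed = 1L) {
  model <- match.arg(model)
  if (n_breeds < 1L || n_genes < 1L) {
    stop("synth_spec: counts must be >= 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("synth_spec: noise_sd must be >= 0", call. = FALSE)
  defaults <- switch(model,
    rank_exponential = list(a = 0, K = 0.15),
    power_law = list(c = 1, D = 1.5),
    portrait_ap = list(n_members = 0L, common_difference = 1.11))
  params <- utils::modifyList(defaults, params)
  if (model == "portrait_ap") {
    nm <- params$n_members
    if (length(nm) == 1L) nm <- c(nm, nm)
    if (any(nm != 0 & nm < 3)) {
      stop("synth_spec: n_members must be 0 or >= 3 (a fractal needs 3 genes)",
           call. = FALSE)
    }
    if (any(nm > n_genes + 1L)) {
      stop("synth_spec: n_members exceeds the panel incl. housekeeping",
           call. = FALSE)
    }
    params$n_members <- as.integer(nm)
  }
  structure(list(model = model, n_breeds = as.integer(n_breeds),
                 n_genes = as.integer(n_genes), params = params,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

# encode a magnitude as a signed FC so that fc_to_magnitude() recovers it
# exactly: up m+1, or down -(m-1) when the magnitude admits |fc| >= 1
.encode_fc <- function(m, down) {
  ifelse(down & m >= 2, -(m - 1), m + 1)
}

#' Generate a panel obeying the rank-exponential model
#'
#' Per breed, latent magnitudes m_N = a + K*exp(N) (+ Gaussian noise with
#' SD `noise_sd`) are produced for ranks N = 1..n_genes and encoded back
#' to signed fold changes with a seeded random up/down direction per gene,
#' such that [fc_to_magnitude()] recovers m exactly. Downregulation is
#' only used where the magnitude admits a fold of at least 1.
#'
#' @param spec A [synth_spec()] with `model = "rank_exponential"`.
#' @param tissue Tissue label for the generated rows.
#' @return An [fc_table()] with breeds `b1..b<n>` and genes `g1..g<n>`.
#' @examples
#' tab <- generate_rank_exponential(synth_spec("rank_exponential",
#'                                  n_breeds = 4, params = list(K = 0.5)))
#' fit_pooled(tab, "breast", max_rank = 7)$K # 0.5
#' @export
generate_rank_exponential <- function(spec, tissue = "breast") {
  stopifnot(inherits(spec, "synth_spec"), spec$model == "rank_exponential")
  set.seed(spec$seed)
  a <- spec$params$a
  K <- spec$params$K
  rows <- lapply(seq_len(spec$n_breeds), function(b) {
    N <- seq_len(spec$n_genes)
    m <- a + K * exp(N)
    if (spec$noise_sd > 0) m <- m + stats::rnorm(spec$n_genes, sd = spec$noise_sd)
    if (any(m < 0)) {
      stop("generate_rank_exponential: parameters/noise yield negative magnitude",
           call. = FALSE)
    }
    down <- stats::runif(spec$n_genes) < 0.5
    data.frame(breed = paste0("b", b), tissue = tissue,
               gene = paste0("g", N), fc = .encode_fc(m, down),
               stringsAsFactors = FALSE)
  })
  fc_table(do.call(rbind, rows))
}

#' Generate a panel obeying the power-law (fractal dimension) model
#'
#' Per breed, m_N = c * N^D, optionally multiplied by a log-normal factor
#' exp(rnorm(0, noise_sd)) which keeps magnitudes positive, then encoded
#' as signed fold changes as in [generate_rank_exponential()].
#'
#' @param spec A [synth_spec()] with `model = "power_law"` (`c > 0`).
#' @param tissue Tissue label.
#' @return An [fc_table()].
#' @export
generate_power_law <- function(spec, tissue = "breast") {
  stopifnot(inherits(spec, "synth_spec"), spec$model == "power_law")
  if (spec$params$c <= 0) {
    stop("generate_power_law: c must be > 0", call. = FALSE)
  }
  set.seed(spec$seed)
  rows <- lapply(seq_len(spec$n_breeds), function(b) {
    N <- seq_len(spec$n_genes)
    m <- spec$params$c * N^spec$params$D
    if (spec$noise_sd > 0) m <- m * exp(stats::rnorm(spec$n_genes, sd = spec$noise_sd))
    down <- stats::runif(spec$n_genes) < 0.5
    data.frame(breed = paste0("b", b), tissue = tissue,
               gene = paste0("g", N), fc = .encode_fc(m, down),
               stringsAsFactors = FALSE)
  })
  fc_table(do.call(rbind, rows))
}

# invert fc_to_lg: lg <= 0 -> upregulated fc = 2^(-lg); lg > 0 ->
# downregulated fc = -(2^lg). lg = 0 gives fc = 1.
.decode_lg <- function(lg) {
  ifelse(lg > 0, -(2^lg), 2^(-lg))
}

#' Generate a portrait panel with planted arithmetic progressions
#'
#' For each tissue, `n_members` genes (the housekeeping reference counts
#' as one member whenever members are planted, since its transformed
#' expression 0 anchors the progression) receive signed log2 expressions
#' on an arithmetic progression with the requested common difference;
#' remaining genes are drawn away from the progression and re-drawn until
#' the collinear-set detector recovers exactly the planted membership.
#'
#' @param spec A [synth_spec()] with `model = "portrait_ap"`; `n_breeds`
#'   is honoured, `params$n_members` may be a scalar or a length-2 vector
#'   (breast, thigh).
#' @param tol_line,ap_tol Detector tolerances used for the planting check,
#'   see [detect_collinear_sets()].
#' @param max_retry Bounded rejection sampling per breed/tissue.
#' @return An [fc_table()] with both tissues per breed.
#' @examples
#' tab <- generate_portrait_panel(synth_spec("portrait_ap",
#'          params = list(n_members = 6), seed = 7))
#' run_model2(tab, "b1")$ind # 0.75 for 6 of 8
#' @export
generate_portrait_panel <- function(spec, tol_line = 0.015, ap_tol = 0.1,
                                    max_retry = 100L) {
  stopifnot(inherits(spec, "synth_spec"), spec$model == "portrait_ap")
  nm <- spec$params$n_members
  d <- spec$params$common_difference
  ng <- spec$n_genes # regular genes; panel incl. housekeeping = ng + 1
  if ((nm[1L] - 1L) > ng || (nm[2L] - 1L) > ng) {
    stop("generate_portrait_panel: n_members exceeds panel capacity", call. = FALSE)
  }
  if (abs(d - round(d)) * max(nm) >= 1) {
    stop("generate_portrait_panel: common_difference wraps the unit cell; ",
         "use a fractional part below 1/n_members", call. = FALSE)
  }
  set.seed(spec$seed)
  # would adding point (xc, yc) create a near-collinear triple with the
  # existing points, at the given perpendicular margin?
  creates_triple <- function(px, py, xc, yc, margin) {
    n <- length(px)
    if (n < 2L) return(FALSE)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        tx <- c(px[c(i, j)], xc)
        ty <- c(py[c(i, j)], yc)
        for (p in 1:3) {
          q <- setdiff(1:3, p)
          dx <- tx[q[2L]] - tx[q[1L]]
          dy <- ty[q[2L]] - ty[q[1L]]
          len <- sqrt(dx^2 + dy^2)
          if (len == 0) next
          if (abs(dy * (tx[p] - tx[q[1L]]) - dx * (ty[p] - ty[q[1L]])) / len <=
              margin) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }
  one_tissue <- function(b, tissue, k) {
    n_plant <- if (k == 0L) 0L else k - 1L # housekeeping is one member
    lat <- if (n_plant > 0L) d * seq_len(n_plant) else numeric(0L)
    n_decoy <- ng - n_plant
    # portrait coordinates of housekeeping + planted members (positive lg
    # keeps the housekeeping gene at the panel minimum, so the shift
    # leaves the planted progression anchored at 0)
    base_y <- c(0, lat)
    ymax <- max(c(lat, 3)) + 4
    for (attempt in seq_len(max_retry)) {
      py <- base_y
      px <- py - floor(py)
      decoys <- numeric(0L)
      ok <- TRUE
      for (dcy in seq_len(n_decoy)) {
        placed <- FALSE
        for (try in 1:50) {
          # above the unit cell so no decoy joins the identity line
          yc <- stats::runif(1L, 1.25, ymax)
          xc <- yc - floor(yc)
          if (!creates_triple(px, py, xc, yc, 2 * tol_line)) {
            decoys <- c(decoys, yc)
            px <- c(px, xc)
            py <- c(py, yc)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      lg <- c(lat, decoys)
      genes <- paste0("g", seq_len(ng))
      tab <- data.frame(breed = b, tissue = tissue, gene = genes,
                        fc = .decode_lg(lg), stringsAsFactors = FALSE)
      suppressWarnings(ft <- fc_table(tab))
      port <- build_portrait(ft, b, tissue)
      sets <- detect_collinear_sets(port, tol = tol_line, ap_tol = ap_tol)
      found <- sort(unique(as.character(unlist(lapply(sets, `[[`, "genes")))))
      want <- if (k == 0L) character(0L) else sort(c(genes[seq_len(n_plant)], "TBP"))
      if (identical(found, want)) return(tab)
    }
    stop("generate_portrait_panel: could not place ", n_decoy,
         " decoy gene(s) off every line in ", max_retry, " attempts",
         call. = FALSE)
  }
  rows <- list()
  for (b in seq_len(spec$n_breeds)) {
    rows[[length(rows) + 1L]] <- one_tissue(paste0("b", b), "breast", nm[1L])
    rows[[length(rows) + 1L]] <- one_tissue(paste0("b", b), "thigh", nm[2L])
  }
  suppressWarnings(fc_table(do.call(rbind, rows)))
}
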