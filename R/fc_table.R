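#' Construct a validated fold-change table
#'
#' A fold-change (FC) table holds signed relative expression values for a
#' panel of genes measured in one or more breeds and tissues. The signed
#' convention encodes an x-fold upregulated gene as `x` and an x-fold
#' downregulated gene as `-x`; the housekeeping reference gene has FC = 1
#' and may be stored implicitly (it is appended where a model needs it).
#'
#' @param x A data frame with columns `breed`, `tissue`, `gene`, `fc`.
#' @param housekeeping Identifier of the housekeeping reference gene
#'   (default `"TBP"`). It does not have to be present in `x`.
#'
#' @details Validation enforces the signed-FC convention: `fc` must be
#'   non-zero and finite, `(breed, tissue, gene)` keys must be unique, every
#'   `(breed, tissue)` group must cover the same gene set, and tissues must
#'   be `"breast"` or `"thigh"`. Values with `|fc| < 1` are admissible but
#'   raise a warning, since the convention reserves the open unit interval.
#'   Input row order is preserved; downstream ranking uses it as the
#'   deterministic tie-breaker.
#'
#' @return The validated data frame with class `"fc_table"` and attribute
#'   `housekeeping`.
#' @examples
#' fc_table(data.frame(breed = "WC", tissue = "breast",
#'                     gene = c("MSTN", "MYF5"), fc = c(4.89, -685.02)))
#' @export
fc_table <- function(x, housekeeping = "TBP") {
  required <- c("breed", "tissue", "gene", "fc")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("fc_table: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$breed <- as.character(x$breed)
  x$tissue <- as.character(x$tissue)
  x$gene <- as.character(x$gene)
  x$fc <- as.numeric(x$fc)
  rownames(x) <- NULL

  if (nrow(x) > 0L) {
    bad_tissue <- !x$tissue %in% c("breast", "thigh")
    if (any(bad_tissue)) {
      stop("fc_table: unknown tissue(s): ",
           paste(unique(x$tissue[bad_tissue]), collapse = ", "),
           " (expected 'breast' or 'thigh')", call. = FALSE)
    }
    zero <- which(!is.finite(x$fc) | x$fc == 0)
    if (length(zero) > 0L) {
      stop("fc_table: fc must be finite and non-zero; offending row(s): ",
           paste(zero, collapse = ", "), call. = FALSE)
    }
    key <- paste(x$breed, x$tissue, x$gene, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("fc_table: duplicate (breed, tissue, gene) key: ",
           gsub("\r", "/", dup), call. = FALSE)
    }
    sub_unit <- abs(x$fc) < 1
    if (any(sub_unit)) {
      warning("fc_table: ", sum(sub_unit), " value(s) with |fc| < 1; the ",
              "signed-FC convention encodes downregulation as negative fold",
              call. = FALSE)
    }
    gene_sets <- tapply(x$gene, paste(x$breed, x$tissue, sep = "\r"),
                        function(g) paste(sort(g), collapse = ","))
    if (length(unique(gene_sets)) > 1L) {
      stop("fc_table: every (breed, tissue) group must share the same gene set",
           call. = FALSE)
    }
  }
  structure(x, class = c("fc_table", "data.frame"),
            housekeeping = housekeeping)
}

#' @export
print.fc_table <- function(x, ...) {
  cat(sprintf("Fold-change table: %d breed(s) x %d tissue(s) x %d gene(s), housekeeping = %s\n",
              length(unique(x$breed)), length(unique(x$tissue)),
              length(unique(x$gene)), attr(x, "housekeeping")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Housekeeping gene of a fold-change table
#' @param x An `fc_table`.
#' @return The housekeeping gene identifier (single string).
#' @export
housekeeping_gene <- function(x) {
  hk <- attr(x, "housekeeping")
  if (is.null(hk)) "TBP" else hk
}

#' Read a fold-change table from CSV/TSV
#'
#' @param path Path to a delimited text file with header columns
#'   `breed`, `tissue`, `gene`, `fc` (extra columns are ignored).
#' @param sep Field separator. Defaults to `"\t"` for `.tsv` files and
#'   `","` otherwise.
#' @param housekeeping Housekeeping gene identifier, see [fc_table()].
#' @return An [fc_table()].
#' @export
read_fc_table <- function(path, sep = NULL, housekeeping = "TBP") {
  if (!file.exists(path)) stop("read_fc_table: no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  fc_table(raw, housekeeping = housekeeping)
}

#' Read a breed phenotype table from CSV/TSV
#'
#' Expects columns `breed`, `bw1`, `bw14`, `bw28`, `nod`, `nitrate`,
#' `breed_type`; further columns (nominal categories etc.) are carried
#' through. Growth-rate ratios `gr2wk`/`gr4wk` and the NO oxidation
#' percentage are derived on read when absent (see [growth_rates()] and
#' [no_oxidation_rate()]).
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; default as in [read_fc_table()].
#' @return A data frame of phenotype records, one row per breed.
#' @export
read_phenotype_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("read_phenotype_table: no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  ph <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("breed", "bw1", "bw14", "bw28", "nod", "nitrate", "breed_type")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols) > 0L) {
    stop("read_phenotype_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(ph$bw1 <= 0 | ph$bw14 <= 0 | ph$bw28 <= 0)) {
    stop("read_phenotype_table: body weights must be positive", call. = FALSE)
  }
  if (any(ph$nod < 0 | ph$nitrate < 0)) {
    stop("read_phenotype_table: NO metabolite concentrations must be >= 0",
         call. = FALSE)
  }
  if (!"gr2wk" %in% names(ph)) {
    gr <- growth_rates(ph$bw1, ph$bw14, ph$bw28)
    ph$gr2wk <- gr$gr2wk
    ph$gr4wk <- gr$gr4wk
  }
  if (!"no_oxidation_computed" %in% names(ph)) {
    ph$no_oxidation_computed <- ifelse(ph$nod + ph$nitrate > 0,
                                       no_oxidation_rate(ph$nod, ph$nitrate),
                                       NA_real_)
  }
  ph
}

#' The bundled eight-breed chick embryo panel
#'
#' Loads the complete printed dataset that the package models were
#' developed on: signed fold changes for seven myogenesis genes (MSTN,
#' GHR, MEF2C, MYOD1, MYOG, MYH1, MYF5; TBP as housekeeping reference) in
#' the breast and thigh muscles of day-14 embryos of eight chicken breeds
#' (BR, WC, PRW, YC, BB, OMF, LR, UG), the per-breed phenotype records
#' (body weights at 1/14/28 days, NO-donor and nitrate levels, utility
#' types), the per-breed/tissue rank windows used for the fractal
#' dimension fits, and the intercept-mode map used for the per-breed
#' rank-exponential fits.
#'
#' @return A list with components `expression` (an [fc_table()]),
#'   `phenotypes` (data frame), `windows` (data frame `breed`, `tissue`,
#'   `lo`, `hi`) and `intercept_modes` (data frame `breed`, `tissue`,
#'   `mode` with values `"zero"`/`"free"`).
#' @examples
#' panel <- chick_myogenesis()
#' subset(panel$expression, breed == "BR" & gene == "MSTN")
#' @export
chick_myogenesis <- function() {
  ext <- function(f) system.file("extdata", f, package = "myofractal", mustWork = TRUE)
  list(
    expression = read_fc_table(ext("expression_fc.csv")),
    phenotypes = read_phenotype_table(ext("phenotypes.csv")),
    windows = utils::read.csv(ext("rank_windows.csv"), stringsAsFactors = FALSE),
    intercept_modes = utils::read.csv(ext("intercept_modes.csv"), stringsAsFactors = FALSE)
  )
}

#' Write a model result table to TSV or JSON
#'
#' Columns are emitted in a deterministic order (as present in `results`)
#' and floats with a configurable number of significant digits, so that
#' repeated runs produce byte-identical files.
#'
#' @param results A data frame (or coercible) of results.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Significant digits for floating-point columns (default 6).
#' @return `invisible(path)`.
#' @export
write_report <- function(results, path, format = c("tsv", "json"), digits = 6L) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  num <- vapply(results, is.double, logical(1L))
  results[num] <- lapply(results[num], signif, digits = digits)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; guessed from the extension when `NULL`.
#' @return A data frame.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "tsv") {
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
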