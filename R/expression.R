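#' Expression matrix container
#'
#' A thin S3 wrapper around a gene-by-sample numeric matrix that records the
#' abundance unit. All pipeline stages operate on this container; the unit tag
#' is what distinguishes raw FPKM/RPKM input from the TPM values every
#' downstream stage expects.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). No missing values; non-negative when
#'   `unit` is `"FPKM"` or `"TPM"`.
#' @param unit One of `"FPKM"`, `"TPM"`, `"LOG2"`. RPKM data are declared as
#'   `"FPKM"`: the per-sample rescaling to TPM is identical for both.
#'
#' @return An object of class `expr_matrix` (a named numeric matrix with a
#'   `unit` attribute).
#' @export
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, "FPKM")
expression_matrix <- function(values, unit = c("TPM", "FPKM", "LOG2")) {
  unit <- match.arg(toupper(unit[1]), c("TPM", "FPKM", "LOG2"))
  check_named_matrix(values, "values")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "missing expression value for gene '%s', sample '%s'.",
      rownames(values)[bad[1L]], colnames(values)[bad[2L]]
    ))
  }
  if (unit %in% c("FPKM", "TPM") && any(values < 0)) {
    abort(sprintf("negative values are not allowed for unit %s.", unit))
  }
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples [%s]\n",
    nrow(x), ncol(x), attr(x, "unit")
  ))
  print(utils::head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out, unit = attr(x, "unit"), class = class(x))
  } else {
    out
  }
}

#' Unit of an expression matrix
#' @param m An [expression_matrix()].
#' @return The unit tag, one of `"FPKM"`, `"TPM"`, `"LOG2"`.
#' @export
expr_unit <- function(m) attr(m, "unit") %||% abort("`m` has no unit attribute.")

#' Tidy an expression matrix into long format
#'
#' @param x An [expression_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`, `unit`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)),
    unit = expr_unit(x)
  )
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text table whose first column holds gene IDs and whose
#' header row holds sample IDs. Duplicate gene rows are collapsed to their
#' per-sample maximum (the usual convention when multiple array probes or
#' transcript rows map to one symbol); a warning reports how many were
#' collapsed.
#'
#' @param path Path to a TSV/CSV file.
#' @param unit Declared unit of the stored values (see [expression_matrix()]).
#' @param delim Field delimiter; `NULL` (default) picks `,` for `.csv` files
#'   and tab otherwise.
#' @param na_action `"error"` (default) fails on any missing cell, naming the
#'   gene and sample; `"impute_median"` replaces missing cells with the
#'   per-gene median across samples.
#'
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "FPKM", "LOG2"),
                                   delim = NULL,
                                   na_action = c("error", "impute_median")) {
  na_action <- match.arg(na_action)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, name_repair = "minimal")
  if (ncol(df) < 2L || nrow(df) < 1L) abort("empty expression matrix.")
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample IDs in header: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  gene_ids <- as.character(df[[1L]])
  vals <- df[-1L]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    # readr leaves a column character when some cell fails to parse as numeric
    for (cn in sample_ids[non_num]) {
      suppressWarnings(num <- as.numeric(vals[[cn]]))
      bad <- which(is.na(num) & !is.na(vals[[cn]]))
      if (length(bad)) {
        abort(sprintf("non-numeric expression value for gene '%s', sample '%s'.",
                      gene_ids[bad[1L]], cn))
      }
      vals[[cn]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (anyNA(m)) {
    if (na_action == "error") {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      abort(sprintf("missing expression value for gene '%s', sample '%s'.",
                    gene_ids[bad[1L]], sample_ids[bad[2L]]))
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      med <- stats::median(m[i, ], na.rm = TRUE)
      m[i, is.na(m[i, ])] <- med
    }
    inform("missing values imputed with per-gene medians.")
  }
  if (anyDuplicated(gene_ids)) {
    n_dup <- sum(duplicated(gene_ids))
    keep <- unique(gene_ids)
    collapsed <- rowsum(m, group = gene_ids, reorder = FALSE)
    # rowsum sums; recompute max per duplicated gene
    m2 <- collapsed
    for (g in keep[keep %in% gene_ids[duplicated(gene_ids)]]) {
      rows <- m[gene_ids == g, , drop = FALSE]
      m2[g, ] <- apply(rows, 2L, max)
    }
    m <- m2[keep, , drop = FALSE]
    warn(sprintf("%d duplicate gene row(s) collapsed by per-sample maximum.", n_dup))
  }
  expression_matrix(m, unit = unit)
}

#' Write an expression matrix to a delimited file
#'
#' @param m An [expression_matrix()] or named numeric matrix.
#' @param path Output path; `.csv` extension selects comma delimiter.
#' @param id_column Name for the leading gene-ID column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  df <- as_tibble(unclass(m), rownames = id_column)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Convert FPKM/RPKM values to TPM
#'
#' Rescales each sample so its abundances sum to one million:
#' \eqn{TPM_{ij} = 10^6 \, FPKM_{ij} / \sum_i FPKM_{ij}}. TPM and FPKM differ
#' only by this per-sample scaling, so the transform needs no gene lengths.
#'
#' @param m An [expression_matrix()] with unit `"FPKM"`.
#' @return An [expression_matrix()] with unit `"TPM"`; every column sums to
#'   `1e6`.
#' @export
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1")), "FPKM")
#' fpkm_to_tpm(m)
fpkm_to_tpm <- function(m) {
  if (expr_unit(m) != "FPKM") {
    abort(sprintf("`m` has unit %s; fpkm_to_tpm() expects FPKM/RPKM input.",
                  expr_unit(m)))
  }
  cs <- colSums(m)
  if (any(cs <= 0)) {
    abort(sprintf("sample(s) with all-zero expression: %s",
                  paste(colnames(m)[cs <= 0], collapse = ", ")))
  }
  out <- sweep(unclass(m), 2L, cs, "/") * 1e6
  expression_matrix(out, unit = "TPM")
}

#' log2-transform a TPM matrix with a pseudocount
#'
#' @param m An [expression_matrix()] with unit `"TPM"` (or `"FPKM"`).
#' @param pseudocount Added before taking log2 (default 1).
#' @return An [expression_matrix()] with unit `"LOG2"`.
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (expr_unit(m) == "LOG2") return(m)
  expression_matrix(log2(unclass(m) + pseudocount), unit = "LOG2")
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `os_time`, `os_event`; keeps any additional
#' covariate columns, including the optional `response`
#' (responder/non-responder) label used by the immunotherapy validation.
#'
#' @param path TSV/CSV path.
#' @param delim Field delimiter; default as in [read_expression_matrix()].
#' @return A tibble, one row per sample.
#' @export
read_clinical_table <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  validate_clinical_table(df)
}

#' Validate a clinical table
#'
#' @param df A data frame with columns `sample_id`, `os_time`, `os_event`.
#' @return The validated tibble.
#' @export
validate_clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) {
    abort(sprintf("clinical table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample IDs in clinical table.")
  if (any(!is.finite(df$os_time)) || any(df$os_time <= 0)) {
    abort("`os_time` must be positive and finite.")
  }
  if (!all(df$os_event %in% c(0, 1))) abort("`os_event` must be 0 or 1.")
  df
}

#' Read / write GMT gene-set files
#'
#' The GMT format stores one gene set per line: set name, description, then
#' the member genes, all tab-separated. Duplicate genes within a line are
#' removed with a warning; duplicate set names are an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (the gene sets), with a
#'   `descriptions` attribute carrying the per-set description strings.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields.", short[1L]))
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate gene-set name(s): %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  n_dup <- sum(vapply(sets, anyDuplicated, integer(1)) > 0L)
  if (n_dup > 0L) {
    warn(sprintf("%d set(s) contained duplicate genes; deduplicated.", n_dup))
    sets <- lapply(sets, unique)
  }
  names(sets) <- nms
  attr(sets, "descriptions") <- setNames(desc, nms)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors; optional `descriptions`
#'   attribute (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path) {
  if (!length(sets) || is.null(names(sets))) abort("`sets` must be a named list.")
  desc <- attr(sets, "descriptions") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Filter copy-number segments into amplifications and deletions
#'
#' Keeps segments supported by at least `min_probes` probes whose log2 segment
#' mean exceeds `amp_thr` (labelled `"amplification"`) or falls below
#' `del_thr` (labelled `"deletion"`); both inequalities are strict. Everything
#' else is dropped.
#'
#' @param segments Data frame with columns `sample_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `n_probes`, `seg_mean`.
#' @param min_probes Minimum supporting probes (default 10).
#' @param amp_thr,del_thr Segment-mean thresholds (defaults +0.2 / -0.2).
#' @return A tibble of retained segments with an added `event` column.
#' @export
filter_copy_number_segments <- function(segments, min_probes = 10,
                                        amp_thr = 0.2, del_thr = -0.2) {
  if (!(del_thr < 0 && 0 < amp_thr)) abort("need del_thr < 0 < amp_thr.")
  need <- c("sample_id", "chrom", "start", "end", "n_probes", "seg_mean")
  missing_cols <- setdiff(need, colnames(segments))
  if (length(missing_cols)) {
    abort(sprintf("segment table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  segments <- as_tibble(segments)
  if (nrow(segments) == 0L) {
    return(dplyr::mutate(segments, event = character(0)))
  }
  if (any(segments$start > segments$end)) abort("segment with start > end.")
  if (any(segments$n_probes < 1)) abort("segment with n_probes < 1.")
  segments |>
    dplyr::filter(.data$n_probes >= min_probes,
                  .data$seg_mean > amp_thr | .data$seg_mean < del_thr) |>
    dplyr::mutate(event = ifelse(.data$seg_mean > amp_thr,
                                 "amplification", "deletion"))
}
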