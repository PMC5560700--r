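#' Construct a validated count matrix
#'
#' The basic data container of the package: raw read counts \eqn{R_{igs}} for
#' `m` entities (rows) across samples (columns), together with the per-sample
#' sequencing depths \eqn{R_{gs} = \sum_i R_{igs}}.
#'
#' @param counts numeric matrix of nonnegative integral read counts,
#'   entities x samples.
#' @param entity_ids character vector of unique row identifiers; defaults to
#'   `rownames(counts)`.
#' @param sample_ids character vector of unique column identifiers; defaults
#'   to `colnames(counts)`.
#' @return An object of class `count_matrix` with elements `counts`
#'   (dimnamed matrix), `entity_ids`, `sample_ids` and `sample_totals`.
#' @export
count_matrix <- function(counts, entity_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(entity_ids)) entity_ids <- paste0("entity", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(counts)))
  entity_ids <- as.character(entity_ids)
  sample_ids <- as.character(sample_ids)
  if (length(entity_ids) != nrow(counts))
    stop("entity_ids length does not match the number of rows")
  if (length(sample_ids) != ncol(counts))
    stop("sample_ids length does not match the number of columns")
  if (anyDuplicated(entity_ids))
    stop("duplicate entity ids: ",
         paste(unique(entity_ids[duplicated(entity_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0))
    stop("counts must be nonnegative")
  if (any(counts != round(counts)))
    stop("counts must be integral read counts")
  storage.mode(counts) <- "double"  # depths can exceed .Machine$integer.max
  dimnames(counts) <- list(entity_ids, sample_ids)
  structure(
    list(counts = counts,
         entity_ids = entity_ids,
         sample_ids = sample_ids,
         sample_totals = colSums(counts)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d entities x %d samples, depth range [%g, %g]\n",
              nrow(x$counts), ncol(x$counts),
              min(x$sample_totals), max(x$sample_totals)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Two dialects are supported: `tsv` (tab-separated, UTF-8; header row of
#' sample ids whose first cell is ignored, first column entity ids) and
#' `matrix-market` (sparse MatrixMarket file with sidecar id files
#' `<path>.rownames` and `<path>.colnames`, one id per line).
#'
#' @param path path to the matrix file.
#' @param dialect `"tsv"` or `"matrix-market"`.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "matrix-market")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    lines <- readLines(path, encoding = "UTF-8")
    if (length(lines) < 1L) stop("parse error in ", path, ": empty file")
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    sample_ids <- header[-1L]
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    m <- length(body)
    counts <- matrix(0, m, length(sample_ids))
    entity_ids <- character(m)
    for (k in seq_len(m)) {
      fields <- body[[k]]
      if (length(fields) != length(sample_ids) + 1L)
        stop("parse error in ", path, " line ", k + 1L,
             ": expected ", length(sample_ids) + 1L, " fields, got ",
             length(fields))
      entity_ids[k] <- fields[1L]
      vals <- suppressWarnings(as.numeric(fields[-1L]))
      if (anyNA(vals))
        stop("parse error in ", path, " line ", k + 1L,
             ": non-numeric count cell")
      counts[k, ] <- vals
    }
    count_matrix(counts, entity_ids, sample_ids)
  } else {
    mm <- as.matrix(Matrix::readMM(path))
    rn_path <- paste0(path, ".rownames")
    cn_path <- paste0(path, ".colnames")
    entity_ids <- if (file.exists(rn_path)) readLines(rn_path) else NULL
    sample_ids <- if (file.exists(cn_path)) readLines(cn_path) else NULL
    if (is.null(entity_ids)) entity_ids <- paste0("entity", seq_len(nrow(mm)))
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(mm)))
    count_matrix(mm, entity_ids, sample_ids)
  }
}

#' Write a count matrix to disk
#'
#' @inheritParams read_count_matrix
#' @param cm a [count_matrix()].
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, dialect = c("tsv", "matrix-market")) {
  stopifnot(inherits(cm, "count_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    header <- paste(c("entity_id", cm$sample_ids), collapse = "\t")
    rows <- vapply(seq_len(nrow(cm$counts)), function(k)
      paste(c(cm$entity_ids[k],
              format(cm$counts[k, ], scientific = FALSE, trim = TRUE)),
            collapse = "\t"), character(1))
    writeLines(c(header, rows), path, useBytes = TRUE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(cm$counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(cm$entity_ids, paste0(path, ".rownames"))
    writeLines(cm$sample_ids, paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Aggregate TCGA-style isoform quantification files to mature-miRNA counts
#'
#' Each input file holds one sample's miRNA-seq quantification: one line per
#' genomic interval with a read count and a region annotation. Lines whose
#' annotation carries a mature-miRNA accession (by default a miRBase
#' `MIMAT\\d+` identifier) are kept and all counts belonging to the same
#' accession within a file are summed, including reads mapped to different
#' genomic regions coding the same mature miRNA. All other lines (precursor,
#' stem-loop, unannotated) are dropped.
#'
#' @param files character vector of file paths, one per sample.
#' @param id_pattern regular expression extracting the mature accession from
#'   the annotation field.
#' @param sample_ids ids for the output columns; defaults to the file base
#'   names without extension.
#' @param region_col,count_col names of the annotation and count columns.
#' @return A [count_matrix()] with one column per file and one row per
#'   distinct accession, rows in lexicographic accession order.
#' @export
aggregate_isoform_quantification <- function(files,
                                             id_pattern = "MIMAT\\d+",
                                             sample_ids = NULL,
                                             region_col = "miRNA_region",
                                             count_col = "read_count") {
  if (length(files) == 0L) stop("no input files")
  if (is.null(sample_ids))
    sample_ids <- sub("\\.[^.]*$", "", basename(files))
  per_file <- vector("list", length(files))
  for (f in seq_along(files)) {
    tab <- utils::read.delim(files[[f]], header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (!all(c(region_col, count_col) %in% names(tab)))
      stop("file ", files[[f]], " lacks required columns '",
           region_col, "' and/or '", count_col, "'")
    hit <- regmatches(tab[[region_col]], regexpr(id_pattern, tab[[region_col]]))
    is_mature <- grepl(id_pattern, tab[[region_col]])
    if (!any(is_mature)) {
      warning("no mature-miRNA lines in ", files[[f]],
              "; sample will be all zeros")
      per_file[[f]] <- numeric(0)
    } else {
      per_file[[f]] <- tapply(as.numeric(tab[[count_col]][is_mature]),
                              hit, sum)
    }
  }
  all_ids <- sort(unique(unlist(lapply(per_file, names))))
  counts <- matrix(0, length(all_ids), length(files),
                   dimnames = list(all_ids, sample_ids))
  for (f in seq_along(files)) {
    v <- per_file[[f]]
    if (length(v)) counts[names(v), f] <- v
  }
  count_matrix(counts, all_ids, sample_ids)
}

#' Depth-normalize a count matrix
#'
#' Produces maximum-likelihood expression estimates
#' \eqn{\hat p_{igs} = R_{igs}/R_{gs}} (`fraction`), or reads per million
#' (`RPM`, \eqn{10^6 \hat p_{igs}}). Columns with zero total depth are left
#' all-zero and flagged rather than dropped.
#'
#' @param cm a [count_matrix()].
#' @param units `"fraction"` or `"RPM"`.
#' @return An object of class `expression_matrix`: `values`, `units`,
#'   `zero_total` (logical per sample).
#' @export
normalize_counts <- function(cm, units = c("fraction", "RPM")) {
  stopifnot(inherits(cm, "count_matrix"))
  units <- match.arg(units)
  totals <- cm$sample_totals
  zero <- totals == 0
  denom <- ifelse(zero, 1, totals)
  values <- sweep(cm$counts, 2L, denom, "/")
  if (units == "RPM") values <- values * 1e6
  if (any(zero))
    warning(sum(zero), " sample(s) with zero total reads left all-zero: ",
            paste(cm$sample_ids[zero], collapse = ", "))
  structure(list(values = values, units = units, zero_total = zero,
                 entity_ids = cm$entity_ids, sample_ids = cm$sample_ids),
            class = "expression_matrix")
}

#' Construct an expression matrix directly
#'
#' @param values nonnegative numeric matrix, entities x samples.
#' @param units `"fraction"` or `"RPM"`.
#' @return An `expression_matrix`.
#' @export
expression_matrix <- function(values, units = c("fraction", "RPM")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("entity", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample", seq_len(ncol(values)))
  csums <- colSums(values)
  target <- if (units == "fraction") 1 else 1e6
  zero <- csums == 0
  bad <- !zero & abs(csums - target) > 1e-6 * target
  if (any(bad))
    stop("columns do not sum to ", target, " for units '", units, "': ",
         paste(colnames(values)[bad], collapse = ", "))
  structure(list(values = values, units = units, zero_total = zero,
                 entity_ids = rownames(values), sample_ids = colnames(values)),
            class = "expression_matrix")
}

#' Construct a group assignment
#'
#' @param group_of named character vector mapping sample id to group label.
#' @return An object of class `group_assignment`: `group_of` (named factor),
#'   `groups` (level order), `group_sizes` (\eqn{n_g}) and `n` (number of
#'   groups).
#' @export
group_assignment <- function(group_of) {
  if (is.null(names(group_of)) || anyDuplicated(names(group_of)))
    stop("group_of must be named by unique sample ids")
  f <- factor(as.character(group_of))
  names(f) <- names(group_of)
  sizes <- table(f)
  if (any(sizes < 1L)) stop("every group must contain at least one sample")
  structure(list(group_of = f,
                 groups = levels(f),
                 group_sizes = as.integer(sizes),
                 n = nlevels(f)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment: %d samples in %d groups (sizes %s)\n",
              length(x$group_of), x$n,
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Read a sample-to-group table
#'
#' Two-column tab-separated table (`sample_id`, `group`), with or without a
#' header line. Every sample in `cm` must be assigned; samples in the table
#' absent from `cm` are ignored with a warning.
#'
#' @param path path to the table.
#' @param cm the companion [count_matrix()].
#' @return A [group_assignment()] covering exactly `cm`'s samples, in the
#'   column order of `cm`.
#' @export
read_group_assignment <- function(path, cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group table must have two columns")
  if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
  ids <- as.character(tab[[1L]])
  grp <- as.character(tab[[2L]])
  missing <- setdiff(cm$sample_ids, ids)
  if (length(missing))
    stop("samples missing from group table: ", paste(missing, collapse = ", "))
  extra <- setdiff(ids, cm$sample_ids)
  if (length(extra))
    warning("ignoring ", length(extra), " sample(s) not in the count matrix: ",
            paste(utils::head(extra, 5), collapse = ", "))
  keep <- match(cm$sample_ids, ids)
  group_assignment(stats::setNames(grp[keep], cm$sample_ids))
}

#' Write a group assignment as a two-column TSV
#'
#' @param groups a [group_assignment()].
#' @param path output path.
#' @export
write_group_assignment <- function(groups, path) {
  stopifnot(inherits(groups, "group_assignment"))
  utils::write.table(
    data.frame(sample_id = names(groups$group_of),
               group = as.character(groups$group_of)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# groups as list of integer column indices, in group level order
.group_index <- function(groups, sample_ids) {
  g <- groups$group_of[sample_ids]
  if (anyNA(g)) stop("samples without a group: ",
                     paste(sample_ids[is.na(g)], collapse = ", "))
  split(seq_along(sample_ids), g)
}
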