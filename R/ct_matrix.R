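#' Ct matrix container
#'
#' A `ct_matrix` is a numeric matrix of RT-qPCR cycle-threshold (Ct) values
#' with assays (miRNAs) in rows and measurement columns in columns. Missing
#' determinations are `NA`. When technical replicates are present each sample
#' contributes several columns; the per-column sample identity and replicate
#' label are carried in attributes and the matrix is said to be *uncollapsed*.
#' After [collapse_replicates()] there is exactly one column per sample.
#'
#' Determination-level quality flags (`"undetected"`, `"irregular_curve"`)
#' coming from an instrument export are carried in a flag table attached as
#' the `"flags"` attribute (see [ct_flags()]); the value itself stays `NA` or
#' numeric so that a missing value is distinguishable from a flagged one only
#' through the flag table.
#'
#' @param values numeric matrix; rownames are the assay (gene) identifiers.
#'   All non-missing values must be finite and within `[0, 45]` cycles.
#' @param sample_ids character vector, one per column. Defaults to
#'   `colnames(values)`. May repeat only when `replicate` is given.
#' @param replicate optional integer/character vector of per-column technical
#'   replicate labels; `(sample_id, replicate)` pairs must be unique.
#' @param flags optional flag table as returned by [ct_flags()]: a data frame
#'   with columns `gene_id`, `sample_id`, `replicate`, `flag`.
#' @return an object of class `ct_matrix`.
#' @examples
#' m <- ct_matrix(matrix(c(24, 25, 26, 27), 2,
#'                dimnames = list(c("miR-a", "miR-b"), c("s1", "s2"))))
#' ct_samples(m)
#' @export
ct_matrix <- function(values, sample_ids = colnames(values), replicate = NULL,
                      flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix of Ct values")
  gene_ids <- rownames(values)
  if (is.null(gene_ids) || anyNA(gene_ids) || any(gene_ids == ""))
    stop("rownames(values) must give a gene id for every row")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (is.null(sample_ids))
    stop("sample ids are required (colnames or 'sample_ids')")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) must equal ncol(values)")
  v <- values[!is.na(values)]
  if (length(v) && (any(!is.finite(v)) || any(v < 0) || any(v > 45)))
    stop("Ct values must be finite and in [0, 45] cycles")
  if (is.null(replicate)) {
    if (anyDuplicated(sample_ids))
      stop("duplicated sample ids (supply 'replicate' for technical replicates): ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
    colnames(values) <- sample_ids
  } else {
    replicate <- as.character(replicate)
    if (length(replicate) != ncol(values))
      stop("length(replicate) must equal ncol(values)")
    key <- paste(sample_ids, replicate, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("duplicated (sample, replicate) column: ",
           gsub("\r", " / rep ", d, fixed = TRUE))
    }
    colnames(values) <- paste(sample_ids, replicate, sep = ".")
  }
  structure(values,
            sample_ids = sample_ids,
            replicate  = replicate,
            flags      = validate_flags(flags, gene_ids, sample_ids, replicate),
            class      = c("ct_matrix", "matrix", "array"))
}

validate_flags <- function(flags, gene_ids, sample_ids, replicate) {
  if (is.null(flags) || nrow(flags) == 0L) return(NULL)
  need <- c("gene_id", "sample_id", "replicate", "flag")
  if (!all(need %in% names(flags)))
    stop("flag table needs columns: ", paste(need, collapse = ", "))
  flags <- flags[, need]
  ok <- c("ok", "undetected", "irregular_curve")
  if (!all(flags$flag %in% ok))
    stop("invalid flag value(s): ",
         paste(setdiff(unique(flags$flag), ok), collapse = ", "))
  if (!all(flags$gene_id %in% gene_ids))
    stop("flag table references unknown gene id(s): ",
         paste(setdiff(flags$gene_id, gene_ids), collapse = ", "))
  if (!all(flags$sample_id %in% sample_ids))
    stop("flag table references unknown sample id(s): ",
         paste(setdiff(flags$sample_id, sample_ids), collapse = ", "))
  flags <- flags[flags$flag != "ok", , drop = FALSE]
  if (nrow(flags) == 0L) return(NULL)
  rownames(flags) <- NULL
  flags
}

#' @rdname ct_matrix
#' @param x a `ct_matrix`.
#' @export
ct_genes <- function(x) rownames(x)

#' @rdname ct_matrix
#' @export
ct_samples <- function(x) unique(attr(x, "sample_ids"))

#' @rdname ct_matrix
#' @export
ct_flags <- function(x) {
  f <- attr(x, "flags")
  if (is.null(f))
    f <- data.frame(gene_id = character(), sample_id = character(),
                    replicate = character(), flag = character())
  f
}

#' @rdname ct_matrix
#' @export
has_replicates <- function(x) !is.null(attr(x, "replicate"))

#' Subset a Ct matrix by gene and/or column
#'
#' Keeps the sample/replicate bookkeeping and the flag table consistent with
#' the retained rows and columns.
#'
#' @param x a `ct_matrix`.
#' @param i row (gene) index: integer, logical or gene ids.
#' @param j column index: integer, logical or column names.
#' @param ... ignored.
#' @param drop ignored; subsetting always returns a `ct_matrix`.
#' @export
`[.ct_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass_ct(x)
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  jj <- seq_len(ncol(m))
  names(jj) <- colnames(m)
  jj <- unname(jj[j])
  out <- m[i, jj, drop = FALSE]
  sid <- attr(x, "sample_ids")[jj]
  rep <- attr(x, "replicate")
  if (!is.null(rep)) rep <- rep[jj]
  fl <- attr(x, "flags")
  if (!is.null(fl))
    fl <- fl[fl$gene_id %in% rownames(out) & fl$sample_id %in% sid, ,
             drop = FALSE]
  ct_matrix(out, sample_ids = sid, replicate = rep, flags = fl)
}

unclass_ct <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("Ct matrix: %d assays x %d columns (%d samples%s)\n",
              nrow(x), ncol(x), length(ct_samples(x)),
              if (has_replicates(x)) ", with technical replicates" else ""))
  nf <- nrow(ct_flags(x))
  if (nf > 0) cat(sprintf("  %d flagged determination(s)\n", nf))
  print(utils::head(unclass_ct(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more assays\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a Ct table from delimited text
#'
#' Reads comma- or tab-separated Ct tables in either of two dialects.
#' *wide*: first column gene id, remaining columns one per sample, cells
#' numeric, empty, or the literal token `"undetected"` (case-insensitive).
#' *long*: columns `gene_id`, `sample_id`, optional `replicate`, `ct`,
#' optional `flag` (`ok`, `undetected`, `irregular_curve`).
#' Empty and `"undetected"` cells become missing values flagged
#' `undetected`. The field separator is auto-detected from the header line.
#'
#' @param path path to a delimited text file.
#' @param dialect `"auto"` (default; long is recognised by its header),
#'   `"wide"` or `"long"`.
#' @return a [ct_matrix] with any determination flags attached (see
#'   [ct_flags()]).
#' @export
read_ct_table <- function(path, dialect = c("auto", "wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))))
    "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", strip.white = TRUE)
  if (dialect == "auto")
    dialect <- if (all(c("gene_id", "sample_id", "ct") %in% names(df)))
      "long" else "wide"
  if (dialect == "long") parse_long_ct(df) else parse_wide_ct(df)
}

parse_ct_cell <- function(cell, where) {
  # returns list(value, undetected) ; errors on junk tokens
  und <- is.na(cell) | cell == "" | tolower(cell) == "undetected"
  val <- suppressWarnings(as.numeric(cell))
  bad <- which(!und & is.na(val))
  if (length(bad))
    stop(sprintf("non-numeric Ct token '%s' at %s", cell[bad[1L]],
                 where[bad[1L]]))
  val[und] <- NA_real_
  list(value = val, undetected = und)
}

parse_wide_ct <- function(df) {
  if (ncol(df) < 2L) stop("wide Ct table needs a gene column plus samples")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id in wide table: ",
         gene_ids[duplicated(gene_ids)][1L])
  sample_ids <- names(df)[-1L]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  where <- outer(seq_along(gene_ids) + 1L, sample_ids,
                 function(r, s) sprintf("row %d, sample %s", r, s))
  p <- parse_ct_cell(as.vector(cells), as.vector(where))
  vals <- matrix(p$value, nrow = length(gene_ids),
                 dimnames = list(gene_ids, sample_ids))
  und <- matrix(p$undetected, nrow = length(gene_ids))
  flags <- NULL
  if (any(und)) {
    idx <- which(und, arr.ind = TRUE)
    flags <- data.frame(gene_id = gene_ids[idx[, 1L]],
                        sample_id = sample_ids[idx[, 2L]],
                        replicate = NA_character_,
                        flag = "undetected")
  }
  ct_matrix(vals, sample_ids = sample_ids, flags = flags)
}

parse_long_ct <- function(df) {
  need <- c("gene_id", "sample_id", "ct")
  if (!all(need %in% names(df)))
    stop("long Ct table needs columns gene_id, sample_id, ct")
  has_rep <- "replicate" %in% names(df)
  rep <- if (has_rep) df$replicate else rep("1", nrow(df))
  key <- paste(df$gene_id, df$sample_id, rep, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicate determination key (gene %s, sample %s, replicate %s)",
                 d[1L], d[2L], d[3L]))
  }
  p <- parse_ct_cell(df$ct, sprintf("row %d", seq_len(nrow(df)) + 1L))
  flag <- if ("flag" %in% names(df)) {
    f <- df$flag
    f[is.na(f) | f == ""] <- "ok"
    f
  } else rep("ok", nrow(df))
  flag[p$undetected & flag == "ok"] <- "undetected"

  gene_ids <- unique(df$gene_id)
  colkey <- paste(df$sample_id, rep, sep = "\r")
  ucol <- unique(colkey)
  vals <- matrix(NA_real_, length(gene_ids), length(ucol),
                 dimnames = list(gene_ids, NULL))
  vals[cbind(match(df$gene_id, gene_ids), match(colkey, ucol))] <- p$value
  parts <- do.call(rbind, strsplit(ucol, "\r", fixed = TRUE))
  flags <- data.frame(gene_id = df$gene_id, sample_id = df$sample_id,
                      replicate = if (has_rep) rep else NA_character_,
                      flag = flag)[flag != "ok", , drop = FALSE]
  if (nrow(flags) == 0L) flags <- NULL
  ct_matrix(vals, sample_ids = parts[, 1L],
            replicate = if (has_rep) parts[, 2L] else NULL,
            flags = flags)
}

#' Read a sample annotation table
#'
#' CSV/TSV with columns `sample_id`, `group` and optionally further covariate
#' columns (e.g. `age`, `sex`, `spike_in_ct` for an exogenous control such as
#' cel-miR-39-3p).
#'
#' @param path path to a delimited text file.
#' @return a data frame with one row per sample; `group` is a factor.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (!all(c("sample_id", "group") %in% names(ann)))
    stop("annotation needs columns sample_id and group")
  ann$sample_id <- as.character(ann$sample_id)
  if (anyDuplicated(ann$sample_id))
    stop("duplicated sample_id in annotation: ",
         ann$sample_id[duplicated(ann$sample_id)][1L])
  ann$group <- factor(ann$group)
  if (nlevels(ann$group) < 1L) stop("annotation must define >= 1 group level")
  ann
}

# Map a collapsed ct_matrix's samples onto annotation groups, in column order.
annotation_groups <- function(m, ann) {
  ann <- validate_annotation(ann)
  miss <- setdiff(ct_samples(m), ann$sample_id)
  if (length(miss))
    stop("samples without annotation: ", paste(miss, collapse = ", "))
  droplevels(ann$group[match(attr(m, "sample_ids"), ann$sample_id)])
}

#' Write a pipeline result to delimited text
#'
#' Writes any stage output (Ct matrices, candidate sets, geNorm / BestKeeper /
#' NormFinder results, QC reports, consensus tables) as a CSV with a header.
#' Ct matrices are written in the long dialect (`gene_id, sample_id,
#' [replicate,] ct, flag`) so that values, identifiers and flags survive a
#' round trip through [read_ct_table()] exactly.
#'
#' @param result a pipeline object.
#' @param path output file path (parent directory must exist).
#' @param ... passed to methods; `write_results.ct_matrix()` accepts
#'   `dialect = c("long", "wide")`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, ...) UseMethod("write_results")

check_writable <- function(path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': directory does not exist")
  path
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, check_writable(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
write_results.ct_matrix <- function(result, path,
                                    dialect = c("long", "wide"), ...) {
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    if (has_replicates(result))
      stop("wide dialect cannot represent technical replicates; use long")
    df <- data.frame(gene_id = ct_genes(result),
                     unclass_ct(result), check.names = FALSE)
    return(write_csv_plain(df, path))
  }
  sid <- attr(result, "sample_ids")
  rep <- attr(result, "replicate")
  ng <- nrow(result)
  df <- data.frame(
    gene_id   = rep(ct_genes(result), times = ncol(result)),
    sample_id = rep(sid, each = ng),
    ct        = as.vector(unclass_ct(result)))
  if (!is.null(rep)) df$replicate <- rep(rep, each = ng)
  fl <- ct_flags(result)
  df$flag <- "ok"
  if (nrow(fl)) {
    fk <- paste(fl$gene_id, fl$sample_id,
                if (is.null(rep)) NA_character_ else fl$replicate)
    dk <- paste(df$gene_id, df$sample_id,
                if (is.null(rep)) NA_character_ else df$replicate)
    df$flag[match(fk, dk)] <- fl$flag
  }
  df$ct <- ifelse(is.na(df$ct), "", format_num(df$ct))
  ord <- c("gene_id", "sample_id",
           if (!is.null(rep)) "replicate", "ct", "flag")
  write_csv_plain(df[, ord], path)
}

format_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE), "")
  out
}

#' @rdname write_results
#' @export
write_results.data.frame <- function(result, path, ...)
  write_csv_plain(result, path)
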