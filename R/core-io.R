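#' Read a delimited beta-value matrix
#'
#' Expects a comma- or tab-separated text file with a header row: one column of
#' sample identifiers (the first unnamed/id column, optional), one reserved
#' numeric age column, and one column per CpG site. Empty cells and the usual
#' NA spellings are read as missing — never silently as zero.
#'
#' @param path path to the file.
#' @param age_column name of the age column (default `"age"`); pass `NULL` for
#'   a matrix without ages.
#' @return a [methyl_dataset].
#' @export
read_methylation_matrix <- function(path, age_column = "age") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, na.strings = c("", "NA", "NaN", "null", "NULL"),
                          header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stop("no data rows in ", path)

  cn <- names(dt)
  if (anyDuplicated(cn))
    stop("duplicated column header(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))

  # a leading non-numeric column (commonly V1/sample_id) carries sample ids
  id_col <- NULL
  if (is.character(dt[[1]]) && !identical(cn[1], age_column)) id_col <- 1L
  sample_ids <- if (is.null(id_col)) paste0("sample", seq_len(nrow(dt)))
                else as.character(dt[[1]])
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  age <- NULL
  drop <- id_col
  if (!is.null(age_column)) {
    if (!age_column %in% cn) stop("age column '", age_column, "' not found")
    age_raw <- dt[[age_column]]
    age <- suppressWarnings(as.numeric(age_raw))
    if (any(is.na(age) & !is.na(age_raw)))
      stop("non-numeric age value(s), e.g. '",
           age_raw[which(is.na(age) & !is.na(age_raw))[1]], "'")
    drop <- c(drop, match(age_column, cn))
  }
  keep <- setdiff(seq_along(cn), drop)
  beta <- as.matrix(dt[, keep, drop = FALSE])
  if (!is.numeric(beta)) stop("non-numeric beta values in ", path)
  rownames(beta) <- sample_ids
  methyl_dataset(beta, age = age,
                 source = rep(basename(path), nrow(beta)))
}

#' Write a methylation dataset as a delimited matrix
#'
#' Inverse of [read_methylation_matrix()]: sample ids in the first column, the
#' age in a reserved `age` column, one column per site; missing betas become
#' empty cells.
#'
#' @param ds a [methyl_dataset].
#' @param path output path.
#' @param sep field separator.
#' @export
write_methylation_matrix <- function(ds, path, sep = ",") {
  df <- data.frame(sample_id = rownames(ds$beta), check.names = FALSE)
  if (!is.null(ds$age)) df$age <- ds$age
  df <- cbind(df, as.data.frame(ds$beta, check.names = FALSE))
  data.table::fwrite(df, path, sep = sep, na = "", quote = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix text dialect: metadata lines prefixed with `!`,
#' the expression/methylation table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` with probes in rows (first column `ID_REF`) and
#' samples in columns. The matrix is transposed to samples x sites. Ages are
#' extracted from `!Sample_characteristics_ch1` entries of the form
#' `"<key>: <value>"` for a configurable key; if no entry parses, the dataset
#' is returned with `age = NULL` and a warning.
#'
#' @param path path to an (uncompressed) series-matrix file.
#' @param age_field characteristics key holding the age (case-insensitive
#'   prefix match, default `"age"`).
#' @return a [methyl_dataset] (age possibly unset).
#' @export
read_geo_series_matrix <- function(path, age_field = "age") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stop("missing or malformed series-matrix table delimiters in ", path)

  tab <- data.table::fread(text = lines[(begin + 1L):(end - 1L)], sep = "\t",
                           header = TRUE, data.table = FALSE,
                           na.strings = c("", "NA", "null", "NULL"))
  if (!identical(toupper(names(tab)[1]), "ID_REF"))
    stop("first table column is not ID_REF")
  probe_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  beta <- t(m)  # samples x sites
  colnames(beta) <- probe_ids
  gsm <- rownames(beta)

  age <- parse_geo_ages(lines[seq_len(begin - 1L)], n = nrow(beta),
                        age_field = age_field)
  methyl_dataset(beta, age = age, sample_ids = gsm,
                 source = rep(basename(path), nrow(beta)))
}

# Scan !Sample_characteristics_ch* metadata rows for "<key>: <value>" fields.
parse_geo_ages <- function(meta_lines, n, age_field) {
  char_lines <- grep("^!Sample_characteristics_ch", meta_lines, value = TRUE)
  pattern <- paste0("^\\s*", age_field)
  for (line in char_lines) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]][-1]
    fields <- gsub("^\"|\"$", "", fields)
    hit <- grepl(pattern, fields, ignore.case = TRUE)
    if (!any(hit)) next
    vals <- rep(NA_real_, length(fields))
    parsed <- sub("^[^:]*:\\s*", "", fields[hit])
    vals[hit] <- suppressWarnings(as.numeric(parsed))
    if (all(is.na(vals[hit]))) next
    if (length(vals) != n) next
    return(vals)
  }
  warning("no parseable '", age_field, "' characteristics field; age left unset")
  NULL
}

#' Merge methylation datasets on their common CpG sites
#'
#' Concatenates the samples of several cohorts over the intersection of their
#' site sets, the standard first move when single studies are too small to
#' learn an age model from. Column order follows the first dataset restricted
#' to the intersection; per-sample provenance is retained in `$source`.
#' Duplicate sample ids across inputs are deduplicated by suffixing, with a
#' warning.
#'
#' @param datasets list of [methyl_dataset] objects, all with ages set.
#' @return the merged [methyl_dataset].
#' @export
merge_datasets <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  lapply(datasets, function(d) {
    stopifnot(inherits(d, "methyl_dataset"))
    if (is.null(d$age)) stop("all datasets must have ages set before merging")
  })
  if (length(datasets) == 1L) return(datasets[[1L]])

  common <- Reduce(intersect, lapply(datasets, site_ids))
  if (length(common) == 0L) stop("empty site intersection across datasets")
  common <- intersect(site_ids(datasets[[1L]]), common)  # first dataset's order

  beta <- do.call(rbind, lapply(datasets, function(d)
    d$beta[, common, drop = FALSE]))
  age <- unlist(lapply(datasets, `[[`, "age"), use.names = FALSE)
  src <- unlist(lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    if (!is.null(d$source)) d$source else rep(paste0("dataset", i), n_samples(d))
  }), use.names = FALSE)

  ids <- unlist(lapply(datasets, sample_ids), use.names = FALSE)
  if (anyDuplicated(ids)) {
    warning("duplicate sample ids across datasets; deduplicating by suffix")
    ids <- make.unique(ids, sep = "_dup")
  }
  rownames(beta) <- ids
  methyl_dataset(beta, age = age, source = src)
}

#' Selection reports
#'
#' A `selection_report` records, for one age group, the CpG sites retained by
#' the stepwise forward ranking in addition order, together with the
#' cross-validated MAD (years) measured right after each site entered the
#' model, and a final metric summary.
#'
#' @param group_label age-group label the report belongs to.
#' @param ranked_sites character vector of unique CpG ids, best first.
#' @param per_site_cv_mad numeric vector, CV MAD after each addition (same
#'   length as `ranked_sites`).
#' @param final_metrics optional [compute_metrics()]-style list.
#' @return an object of class `selection_report`.
#' @export
selection_report <- function(group_label, ranked_sites, per_site_cv_mad,
                             final_metrics = NULL) {
  ranked_sites <- as.character(ranked_sites)
  per_site_cv_mad <- as.numeric(per_site_cv_mad)
  if (anyDuplicated(ranked_sites)) stop("ranked_sites must be unique")
  if (length(ranked_sites) != length(per_site_cv_mad))
    stop("per_site_cv_mad must have one entry per ranked site")
  structure(list(group_label = as.character(group_label),
                 ranked_sites = ranked_sites,
                 per_site_cv_mad = per_site_cv_mad,
                 final_metrics = final_metrics),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report [group ", x$group_label, "]: ",
      length(x$ranked_sites), " ranked sites\n", sep = "")
  if (length(x$ranked_sites)) {
    top <- utils::head(x$ranked_sites, 5)
    cat("  top: ", paste(top, collapse = ", "),
        if (length(x$ranked_sites) > 5) ", ..." else "", "\n", sep = "")
    cat("  final CV MAD: ",
        round(x$per_site_cv_mad[length(x$per_site_cv_mad)], 3), " years\n",
        sep = "")
  }
  invisible(x)
}

#' Write / read a selection report
#'
#' The on-disk form is a tab-separated table with columns `rank`, `site_id`,
#' `cv_mad_after_addition` and a `# group: <label>` comment header — both
#' human-readable and machine-parseable; a write/read round trip reproduces
#' the report.
#'
#' @param report a [selection_report].
#' @param path output (input) path.
#' @return `write_selection_report`: the path, invisibly.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste0("# group: ", report$group_label), con)
  df <- data.frame(rank = seq_along(report$ranked_sites),
                   site_id = report$ranked_sites,
                   cv_mad_after_addition = report$per_site_cv_mad)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_selection_report
#' @return `read_selection_report`: the reconstructed [selection_report].
#' @export
read_selection_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# group: ", lines[1]))
    stop("not a selection report: ", path)
  label <- sub("^# group: ", "", lines[1])
  df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "numeric"))
  selection_report(label, df$site_id, df$cv_mad_after_addition)
}
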