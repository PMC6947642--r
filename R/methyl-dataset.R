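#' Construct a methylation dataset
#'
#' The central container of the package: a samples x CpG-sites matrix of
#' methylation beta values (fractions in \[0,1\], `NA` for missing) together
#' with the per-sample chronological age in years and an optional age-group
#' label. Missingness is carried as `NA` — never as 0 — so that downstream
#' imputation sees true missingness.
#'
#' @param beta numeric matrix, samples in rows, CpG sites in columns. Row and
#'   column names, when present, seed `sample_ids` / `site_ids`.
#' @param age numeric vector of non-negative ages in years (one per sample),
#'   or `NULL` when unknown.
#' @param sample_ids,site_ids character identifiers; defaults taken from
#'   `dimnames(beta)` or generated.
#' @param group optional character/factor vector of age-group labels.
#' @param source optional character vector recording the provenance (source
#'   file or cohort) of every sample.
#' @return An object of class `methyl_dataset` with elements `beta`, `age`,
#'   `group`, `source`.
#' @examples
#' ds <- methyl_dataset(matrix(runif(6), 3, 2,
#'                             dimnames = list(paste0("s", 1:3), c("cg1", "cg2"))),
#'                      age = c(1, 5, 9))
#' n_samples(ds)
#' @export
methyl_dataset <- function(beta, age = NULL, sample_ids = NULL, site_ids = NULL,
                           group = NULL, source = NULL) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  if (is.null(sample_ids)) sample_ids <- rownames(beta)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(beta)))
  if (is.null(site_ids)) site_ids <- colnames(beta)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(ncol(beta)))
  if (nrow(beta)) rownames(beta) <- as.character(sample_ids)
  if (ncol(beta)) colnames(beta) <- as.character(site_ids)
  ds <- structure(list(beta = beta,
                       age = if (is.null(age)) NULL else as.numeric(age),
                       group = if (is.null(group)) NULL else as.character(group),
                       source = if (is.null(source)) NULL else as.character(source)),
                  class = "methyl_dataset")
  validate_methyl_dataset(ds)
  ds
}

#' Validate a methylation dataset's invariants
#'
#' Checks dimension agreement, identifier uniqueness, the beta range
#' (non-missing values in \[0,1\]) and non-negative ages. Called by the
#' constructor and after every transformation that returns a dataset.
#'
#' @param ds a `methyl_dataset`.
#' @param check_beta_range check that betas lie in \[0,1\] (disable for
#'   intermediate representations such as normalized residuals).
#' @return `ds`, invisibly; stops with a descriptive error on violation.
#' @export
validate_methyl_dataset <- function(ds, check_beta_range = TRUE) {
  stopifnot(inherits(ds, "methyl_dataset"))
  b <- ds$beta
  if (anyDuplicated(rownames(b)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(b)[duplicated(rownames(b))]), collapse = ", "))
  if (anyDuplicated(colnames(b)))
    stop("duplicate site ids: ",
         paste(unique(colnames(b)[duplicated(colnames(b))]), collapse = ", "))
  if (check_beta_range && nrow(b) && ncol(b) && !all(is.na(b))) {
    rng <- range(b, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("beta values outside [0,1]: range ", rng[1], " .. ", rng[2])
  }
  if (!is.null(ds$age)) {
    if (length(ds$age) != nrow(b))
      stop("age length (", length(ds$age), ") != sample count (", nrow(b), ")")
    if (any(!is.na(ds$age) & ds$age < 0)) stop("negative ages present")
  }
  if (!is.null(ds$group) && length(ds$group) != nrow(b))
    stop("group length != sample count")
  if (!is.null(ds$source) && length(ds$source) != nrow(b))
    stop("source length != sample count")
  invisible(ds)
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat("methyl_dataset: ", nrow(x$beta), " samples x ", ncol(x$beta),
      " CpG sites\n", sep = "")
  if (!is.null(x$age))
    cat("  age: ", round(min(x$age), 1), "-", round(max(x$age), 1),
        " years\n", sep = "")
  nmiss <- sum(is.na(x$beta))
  if (nmiss) cat("  missing beta cells: ", nmiss, "\n", sep = "")
  if (!is.null(x$group))
    cat("  groups: ", paste(names(table(x$group)), table(x$group),
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname methyl_dataset
#' @export
n_samples <- function(ds) nrow(ds$beta)

#' @rdname methyl_dataset
#' @export
n_sites <- function(ds) ncol(ds$beta)

#' @rdname methyl_dataset
#' @export
sample_ids <- function(ds) rownames(ds$beta)

#' @rdname methyl_dataset
#' @export
site_ids <- function(ds) colnames(ds$beta)

#' Subset a methylation dataset by samples and/or sites
#'
#' @param ds a `methyl_dataset`.
#' @param samples,sites index vectors (integer, logical or character) into the
#'   sample/site dimension; `NULL` keeps everything.
#' @return the subsetted `methyl_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(ds$beta))
  if (is.character(samples)) samples <- match(samples, rownames(ds$beta))
  if (is.logical(samples)) samples <- which(samples)
  if (is.null(sites)) sites <- seq_len(ncol(ds$beta))
  if (is.character(sites)) {
    idx <- match(sites, colnames(ds$beta))
    if (anyNA(idx)) stop("unknown site ids: ",
                         paste(sites[is.na(idx)], collapse = ", "))
    sites <- idx
  }
  if (is.logical(sites)) sites <- which(sites)
  methyl_dataset(ds$beta[samples, sites, drop = FALSE],
                 age = ds$age[samples],
                 group = if (!is.null(ds$group)) ds$group[samples],
                 source = if (!is.null(ds$source)) ds$source[samples])
}
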