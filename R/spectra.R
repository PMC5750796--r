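#' Construct a spectra dataset
#'
#' Bundles an absorbance matrix (samples in rows, wavenumber channels in
#' columns) with its wavenumber axis, class labels and sample identifiers,
#' and validates their mutual consistency. The axis is canonicalised to
#' strictly ascending order; columns are permuted accordingly, so datasets
#' stored with a descending axis (common in instrument exports) load
#' identically to ascending ones.
#'
#' @param absorbance numeric matrix, `m` samples by `n` wavenumber channels.
#'   Absorbance units (dimensionless). No missing values allowed.
#' @param wavenumbers numeric vector of length `n`, the axis in cm^-1.
#'   Must be strictly monotonic (ascending or descending).
#' @param labels character vector of length `m`, the class label of each
#'   sample (e.g. `"cancer"` / `"colitis"`).
#' @param sample_ids character vector of length `m`, unique sample names.
#'   Defaults to `s1, s2, ...`.
#' @param regions optional list of `c(low, high)` intervals recording region
#'   membership (set by [select_regions()]); `NULL` means a single
#'   contiguous region spanning the axis.
#'
#' @return An object of class `"spectra_dataset"`: a list with elements
#'   `absorbance`, `wavenumbers`, `labels`, `sample_ids`, `regions`.
#' @seealso [read_spectra()], [write_spectra()], [select_regions()]
#' @export
spectra_dataset <- function(absorbance, wavenumbers, labels, sample_ids = NULL,
                            regions = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  labels <- as.character(labels)
  m <- nrow(absorbance)
  n <- ncol(absorbance)
  if (m < 1L) stop("spectra_dataset: at least one sample is required")
  if (length(wavenumbers) != n)
    stop("spectra_dataset: length(wavenumbers) [", length(wavenumbers),
         "] must equal ncol(absorbance) [", n, "]")
  if (anyNA(absorbance) || anyNA(wavenumbers))
    stop("spectra_dataset: missing values in absorbance or wavenumbers")
  if (length(labels) != m)
    stop("spectra_dataset: length(labels) must equal nrow(absorbance)")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(m))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != m)
    stop("spectra_dataset: length(sample_ids) must equal nrow(absorbance)")
  if (anyDuplicated(sample_ids))
    stop("spectra_dataset: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  d <- diff(wavenumbers)
  if (n > 1L) {
    if (all(d < 0)) {            # descending axis: canonicalise
      ord <- rev(seq_len(n))
      wavenumbers <- wavenumbers[ord]
      absorbance <- absorbance[, ord, drop = FALSE]
    } else if (!all(d > 0)) {
      stop("spectra_dataset: wavenumbers must be strictly monotonic")
    }
  }
  dimnames(absorbance) <- list(sample_ids, format_wavenumber(wavenumbers))

  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 labels = labels, sample_ids = sample_ids,
                 regions = regions),
            class = "spectra_dataset")
}

# round-trip-safe decimal rendering of axis values
format_wavenumber <- function(x) {
  formatC(x, format = "g", digits = 15, width = 1)
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("Spectra dataset: ", nrow(x$absorbance), " samples x ",
      ncol(x$absorbance), " wavenumbers (",
      format_wavenumber(min(x$wavenumbers)), "-",
      format_wavenumber(max(x$wavenumbers)), " cm^-1)\n", sep = "")
  tab <- table(x$labels)
  cat("Classes: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$regions))
    cat("Regions: ",
        paste(vapply(x$regions, function(r) paste(r, collapse = "-"), ""),
              collapse = ", "), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$absorbance)

#' Subset a spectra dataset by sample
#'
#' @param x a [spectra_dataset()].
#' @param i sample index vector (integer, logical or sample-id character).
#' @param ... unused.
#' @return A `spectra_dataset` with the selected samples.
#' @export
`[.spectra_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectra_dataset(x$absorbance[i, , drop = FALSE], x$wavenumbers,
                  x$labels[i], x$sample_ids[i], regions = x$regions)
}

#' Read spectra from a flat CSV file
#'
#' The expected dialect is UTF-8 comma-separated text: first column `id`,
#' one label column (default name `label`), and remaining column headers
#' that parse as wavenumbers in cm^-1. A descending wavenumber axis is
#' silently reordered to ascending.
#'
#' @param path path to the CSV file.
#' @param label_column name of the label column. Default `"label"`.
#' @return A [spectra_dataset()].
#' @export
read_spectra <- function(path, label_column = "label") {
  if (!file.exists(path)) stop("read_spectra: file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("read_spectra: cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (!"id" %in% names(df))
    stop("read_spectra: missing 'id' column in ", path)
  if (!label_column %in% names(df))
    stop("read_spectra: missing label column '", label_column, "' in ", path)
  spec_cols <- setdiff(names(df), c("id", label_column))
  if (length(spec_cols) == 0L)
    stop("read_spectra: no wavenumber columns in ", path)
  wn <- suppressWarnings(as.numeric(spec_cols))
  if (anyNA(wn))
    stop("read_spectra: non-numeric wavenumber header(s): ",
         paste(spec_cols[is.na(wn)], collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[spec_cols], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), ncol = length(spec_cols))
  if (anyNA(vals))
    stop("read_spectra: missing or non-numeric absorbance cells in ", path)
  spectra_dataset(vals, wn, labels = df[[label_column]], sample_ids = df$id)
}

#' Write spectra to a flat CSV file
#'
#' Inverse of [read_spectra()]: values are rendered with enough decimal
#' digits that a read-back reproduces the dataset to double-precision
#' round-trip accuracy.
#'
#' @param ds a [spectra_dataset()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(ds, path) {
  stopifnot(inherits(ds, "spectra_dataset"))
  header <- c("id", "label", format_wavenumber(ds$wavenumbers))
  body <- cbind(ds$sample_ids, ds$labels,
                matrix(formatC(ds$absorbance, format = "g", digits = 17,
                               width = 1),
                       nrow = nrow(ds$absorbance)))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("write_spectra: cannot open ",
                                           path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Restrict spectra to wavenumber regions
#'
#' Keeps only the channels whose wavenumber lies in a closed interval
#' `[low, high]` of `regions`, and records region membership so that
#' downstream SNV normalisation can act on each region independently.
#' Biological tissue shows essentially no absorbance between 1800 and
#' 2800 cm^-1, so the conventional choice is
#' `list(c(1000, 1800), c(2800, 3800))`.
#'
#' @param ds a [spectra_dataset()].
#' @param regions list of length-2 numeric vectors `c(low, high)` in cm^-1;
#'   intervals must be non-overlapping.
#' @return A `spectra_dataset` containing only the selected channels, with
#'   `$regions` set.
#' @export
select_regions <- function(ds, regions) {
  stopifnot(inherits(ds, "spectra_dataset"))
  regions <- validate_regions(regions)
  keep <- region_membership(ds$wavenumbers, regions)
  if (!any(!is.na(keep)))
    stop("select_regions: no wavenumbers fall inside the requested regions")
  idx <- which(!is.na(keep))
  out <- spectra_dataset(ds$absorbance[, idx, drop = FALSE],
                         ds$wavenumbers[idx], ds$labels, ds$sample_ids,
                         regions = regions)
  out
}

validate_regions <- function(regions) {
  if (is.numeric(regions) && length(regions) == 2L) regions <- list(regions)
  if (!is.list(regions) || length(regions) == 0L)
    stop("regions must be a non-empty list of c(low, high) intervals")
  regions <- lapply(regions, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2])
      stop("each region must be c(low, high) with low <= high")
    r
  })
  regions <- regions[order(vapply(regions, `[`, 0, 1L))]
  lo <- vapply(regions, `[`, 0, 1L)
  hi <- vapply(regions, `[`, 0, 2L)
  if (length(regions) > 1L && any(lo[-1L] <= hi[-length(hi)]))
    stop("regions must be non-overlapping")
  regions
}

# per-channel region index (NA = outside all regions)
region_membership <- function(wavenumbers, regions) {
  member <- rep(NA_integer_, length(wavenumbers))
  for (r in seq_along(regions)) {
    inside <- wavenumbers >= regions[[r]][1] & wavenumbers <= regions[[r]][2]
    member[inside] <- r
  }
  member
}
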