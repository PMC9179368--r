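#' Read and write single spectra
#'
#' The on-disk spectrum format is a UTF-8 TSV: `#key<TAB>value` header
#' lines carrying the metadata (`id`, `label`, `field_strength_T`,
#' `transmitter_frequency_MHz` (optional), `spectral_width_Hz`, `n_points`,
#' `echo_time_ms` (optional), `center_ppm` (optional)) followed by one
#' intensity value per line at full double precision. The round trip
#' `write_spectrum()` then `read_spectrum()` is lossless.
#'
#' @param path File path.
#' @return `read_spectrum()` returns a one-row [mrs_cohort()] tibble.
#' @examples
#' co <- simulate_cohort(sim_config(), n_mut = 1, n_wt = 0, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_spectrum(co, f)
#' identical(read_spectrum(f)$intensities, co$intensities)
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]

  kv <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop(sprintf("%s: malformed header line '%s'.", path, hdr[bad][1]),
         call. = FALSE)
  }
  meta <- stats::setNames(
    vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L)
  )
  need <- c("id", "field_strength_T", "spectral_width_Hz", "n_points")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop(sprintf("%s: missing mandatory metadata key(s): %s.",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  num <- function(key, default = NULL) {
    if (!key %in% names(meta)) return(default)
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (is.na(v)) {
      stop(sprintf("%s: metadata key '%s' is not numeric ('%s').",
                   path, key, meta[[key]]), call. = FALSE)
    }
    v
  }
  params <- acq_params(
    field_strength = num("field_strength_T"),
    spectral_width = num("spectral_width_Hz"),
    n_points = num("n_points"),
    transmitter_frequency = num("transmitter_frequency_MHz", NULL),
    echo_time = num("echo_time_ms", NA_real_),
    center_ppm = num("center_ppm", 4.7)
  )
  intens <- suppressWarnings(as.numeric(body))
  if (anyNA(intens)) {
    stop(sprintf("%s: non-numeric intensity at line %d.",
                 path, which(is.na(intens))[1]), call. = FALSE)
  }
  if (length(intens) != params$n_points) {
    stop(sprintf("%s: %d intensity rows but n_points = %d.",
                 path, length(intens), params$n_points), call. = FALSE)
  }
  mrs_cohort(meta[["id"]], list(intens), params,
             label = if ("label" %in% names(meta)) meta[["label"]] else "unknown")
}

#' @rdname read_spectrum
#' @param cohort A one-row `mrs_cohort` tibble (use [write_cohort()] for
#'   several spectra).
#' @export
write_spectrum <- function(cohort, path) {
  stopifnot(nrow(cohort) == 1)
  hdr <- c(
    sprintf("#id\t%s", cohort$id),
    sprintf("#label\t%s", cohort$label),
    sprintf("#field_strength_T\t%s", fmt_full(cohort$field_strength_T)),
    sprintf("#transmitter_frequency_MHz\t%s",
            fmt_full(cohort$transmitter_frequency_MHz)),
    sprintf("#spectral_width_Hz\t%s", fmt_full(cohort$spectral_width_Hz)),
    sprintf("#n_points\t%d", cohort$n_points),
    if (!is.na(cohort$echo_time_ms))
      sprintf("#echo_time_ms\t%s", fmt_full(cohort$echo_time_ms)),
    sprintf("#center_ppm\t%s", fmt_full(cohort$center_ppm))
  )
  writeLines(c(hdr, fmt_full(cohort$intensities[[1]])), path,
             useBytes = TRUE)
  invisible(path)
}

# full round-trip double precision
fmt_full <- function(x) sprintf("%.17g", x)

#' Read and write cohorts via a manifest
#'
#' A cohort manifest is a TSV with columns `path`, `id`, `label`; each
#' `path` (relative to the manifest's directory, or absolute) points to a
#' spectrum file in the [read_spectrum()] format. The manifest order is
#' preserved and ids must be unique.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return An [mrs_cohort()] tibble with an empty exclusion ledger.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, sep = "\t",
                           colClasses = "character")
  need <- c("path", "id", "label")
  if (!all(need %in% names(man))) {
    stop("Manifest must have columns path, id, label.", call. = FALSE)
  }
  if (anyDuplicated(man$id)) {
    stop("Manifest has duplicate ids: ",
         paste(unique(man$id[duplicated(man$id)]), collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  rows <- lapply(seq_along(paths), function(i) {
    sp <- read_spectrum(paths[i])
    sp$id <- man$id[i]
    sp$label <- normalize_label(man$label[i])
    sp
  })
  out <- as_mrs_cohort(dplyr::bind_rows(rows))
  if (anyDuplicated(out$id)) {
    stop("Duplicate spectrum ids after reading manifest.", call. = FALSE)
  }
  attr(out, "exclusion_ledger") <- empty_ledger()
  out
}

#' @rdname read_cohort
#' @param cohort An `mrs_cohort` tibble.
#' @param dir Output directory (created if absent); one TSV per spectrum
#'   plus `manifest.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.tsv", cohort$id)
  for (i in seq_len(nrow(cohort))) {
    write_spectrum(cohort[i, ], file.path(dir, files[i]))
  }
  man <- data.frame(path = files, id = cohort$id, label = cohort$label)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

empty_ledger <- function() {
  tibble::tibble(reason = character(), n = integer())
}
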