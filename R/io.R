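#' Read and write single spectra
#'
#' `read_spectrum()` reads a two-column delimited text file (wavenumber,
#' intensity). The delimiter is auto-detected among comma, tab and
#' whitespace, and a non-numeric first line is treated as a header.
#' `write_spectrum()` writes a comma-separated file with a header at full
#' double precision.
#'
#' @param path File path.
#' @return `read_spectrum()`: a spectrum tibble.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty spectrum file.")
  delim <- if (grepl(",", lines[1])) "," else if (grepl("\t", lines[1])) "\t" else " "
  splitter <- function(l) {
    if (delim == " ") strsplit(trimws(l), "\\s+") else strsplit(l, delim, fixed = TRUE)
  }
  first <- suppressWarnings(as.numeric(splitter(lines[1])[[1]]))
  has_header <- any(is.na(first))
  body <- if (has_header) lines[-1] else lines
  vals <- lapply(splitter(body), function(x) suppressWarnings(as.numeric(x)))
  ncols <- lengths(vals)
  if (any(ncols < 2)) abort("malformed rows: need two numeric columns.")
  m <- t(vapply(vals, function(v) v[1:2], numeric(2)))
  if (any(is.na(m))) abort("malformed rows: non-numeric values.")
  as_spectrum(tibble(wavenumber = m[, 1], intensity = m[, 2]))
}

#' @rdname read_spectrum
#' @param data Spectrum tibble.
#' @export
write_spectrum <- function(data, path) {
  data <- as_spectrum(data)
  readr::write_csv(data[, c("wavenumber", "intensity")], path)
  invisible(path)
}

#' Read and write multi-spectrum datasets
#'
#' A dataset on disk is a directory holding wide matrix CSVs — first
#' column `wavenumber`, one column per spectrum, column names = spectrum
#' ids — for the intensities and, when known, the true baselines and
#' signals, plus a JSON manifest carrying `id`, `shape_label`, `seed` and
#' `snr` per spectrum. Numeric payloads round-trip at full double
#' precision.
#'
#' @param dataset Nested dataset tibble.
#' @param dir Directory path (created if missing).
#' @return `read_dataset()`: the nested dataset tibble.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wn <- dataset$spectrum[[1]]$wavenumber
  write_wide <- function(col, file) {
    if (is.null(dataset$spectrum[[1]][[col]])) return(invisible(NULL))
    m <- vapply(dataset$spectrum, function(s) s[[col]], numeric(length(wn)))
    df <- as.data.frame(m)
    names(df) <- as.character(dataset$id)
    readr::write_csv(dplyr::bind_cols(tibble(wavenumber = wn), df),
                     file.path(dir, file))
  }
  write_wide("intensity", "intensities.csv")
  write_wide("true_baseline", "baselines.csv")
  write_wide("true_signal", "signals.csv")
  manifest <- purrr::pmap(
    list(dataset$id, dataset$shape_label, dataset$seed, dataset$snr),
    function(id, shape, seed, snr) {
      m <- list(id = id, shape_label = shape, seed = seed)
      if (!is.na(snr)) m$snr <- snr
      m
    })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ipath <- file.path(dir, "intensities.csv")
  if (!file.exists(ipath)) abort(paste0("no intensities.csv under ", dir))
  read_wide <- function(file) {
    p <- file.path(dir, file)
    if (!file.exists(p)) return(NULL)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  intens <- read_wide("intensities.csv")
  basel <- read_wide("baselines.csv")
  sigs <- read_wide("signals.csv")
  ids <- setdiff(names(intens), "wavenumber")
  if (anyDuplicated(ids)) abort("duplicate spectrum ids in dataset.")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  meta <- dplyr::bind_rows(purrr::map(manifest, function(m) {
    s <- m$snr
    tibble(id = as.integer(m$id), shape_label = m$shape_label,
           seed = as.integer(m$seed),
           snr = if (is.null(s) || length(s) == 0) NA_real_ else as.numeric(s))
  }))
  wn <- intens$wavenumber
  specs <- purrr::map(ids, function(cid) {
    sp <- tibble(wavenumber = wn, intensity = intens[[cid]])
    if (!is.null(basel)) sp$true_baseline <- basel[[cid]]
    if (!is.null(sigs)) sp$true_signal <- sigs[[cid]]
    sp
  })
  out <- meta[match(as.integer(ids), meta$id), ]
  out$spectrum <- specs
  as_tibble(out)
}
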