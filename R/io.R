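#' Read and write spectra as CSV
#'
#' The on-disk format is two plain CSV files: a wide spectra table whose
#' header row holds the wavenumbers (one row per sample, first column
#' `sample_id`) and a metadata table (`sample_id`, `la_conc`, `day`,
#' `replicate`, `role`, plus any extra columns).
#'
#' @param s a [spectra_set()].
#' @param spectra_file,meta_file output / input paths.
#' @return `write_spectra` returns the input invisibly; `read_spectra`
#'   returns a `mir_spectra`.
#' @export
write_spectra <- function(s, spectra_file, meta_file) {
  wide <- data.frame(sample_id = s$meta$sample_id, s$absorbance,
                     check.names = FALSE)
  names(wide) <- c("sample_id", sprintf("%.6f", s$wavenumbers))
  write.csv(wide, spectra_file, row.names = FALSE)
  write.csv(s$meta, meta_file, row.names = FALSE)
  invisible(s)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(spectra_file, meta_file) {
  wide <- read.csv(spectra_file, check.names = FALSE)
  meta <- read.csv(meta_file, stringsAsFactors = FALSE)
  wn <- as.numeric(names(wide)[-1])
  X <- as.matrix(wide[, -1, drop = FALSE])
  ord <- match(wide$sample_id, meta$sample_id)
  if (anyNA(ord)) stop("sample ids in spectra and metadata files do not match")
  spectra_set(wn, X, meta[ord, , drop = FALSE])
}

#' Write / read a simulation or run configuration as YAML
#'
#' @param cfg a [sim_config()] or [run_config()] list.
#' @param file path to a YAML file.
#' @export
write_config <- function(cfg, file) {
  cls <- class(cfg)
  lst <- unclass(cfg)
  lst$.class <- cls[1]
  yaml::write_yaml(lst, file)
  invisible(cfg)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  lst <- yaml::read_yaml(file)
  cls <- lst$.class %||% "list"
  lst$.class <- NULL
  for (nm in c("baseline_bands", "analyte_bands", "interferent_bands"))
    if (!is.null(lst[[nm]])) lst[[nm]] <- as.data.frame(lst[[nm]])
  structure(lst, class = cls)
}
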