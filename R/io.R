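#' Write a table as TSV with a provenance header
#'
#' All pipeline outputs are tab-separated text with a single leading `#`
#' comment line carrying run provenance (never timestamps, so identical
#' runs produce identical files).
#'
#' @param x Data frame.
#' @param path Output file.
#' @param provenance Character scalar written after `# `.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_flux_tsv()]
#'
#' @param path File path.
#' @return A tibble (the `#` provenance line is skipped).
#' @export
read_flux_tsv <- function(path) {
  tibble::as_tibble(
    utils::read.delim(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  )
}

#' Read an optical-density plate table
#'
#' Expects the plate TSV schema: first column `time_h`, then one OD column
#' per well.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_od_plate <- function(path) {
  plate <- read_flux_tsv(path)
  if (names(plate)[1L] != "time_h") {
    stop("first column must be time_h")
  }
  plate
}

#' Read long-format flow-cytometry events
#'
#' Expects columns `sample_id`, `fluorescence` and returns one
#' `flow_sample` per sample id.
#'
#' @param path File path.
#' @param arrested Logical flag attached to every sample.
#' @return Named list of `flow_sample` objects.
#' @export
read_flow_events <- function(path, arrested = FALSE) {
  df <- read_flux_tsv(path)
  if (!all(c("sample_id", "fluorescence") %in% names(df))) {
    stop("need columns sample_id, fluorescence")
  }
  lapply(split(df$fluorescence, df$sample_id), function(ev) {
    structure(list(sample_id = NULL, events = ev, arrested = arrested),
              class = "flow_sample")
  })
}

#' Read a per-chromosome coverage table
#'
#' Expects columns `chromosome`, `mapped_sites`, `ref_sites`.
#'
#' @param path File path.
#' @return List with named vectors `counts` and `ref`, ready for
#'   [coverage_ratios()].
#' @export
read_coverage <- function(path) {
  df <- read_flux_tsv(path)
  need <- c("chromosome", "mapped_sites", "ref_sites")
  if (!all(need %in% names(df))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  list(
    counts = setNames(df$mapped_sites, df$chromosome),
    ref = setNames(df$ref_sites, df$chromosome)
  )
}
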