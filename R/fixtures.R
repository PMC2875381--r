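.fixture_files <- c(
  table1 = "table1_mcrs.tsv",
  table2 = "table2_candidates.tsv"
)

.fixture_md5 <- c(
  table1 = "e505a35ec233bb2ea90abd908168c18e",
  table2 = "715033558e3db149b075393635e33a5e"
)

#' Load a packaged published-table fixture
#'
#' Two transcriptions ship with the package, checksum-verified at load:
#' `"table1"`, the 13 high-confidence primary-melanoma MCRs (cytoband,
#' half-open coordinates, width, peak log2, tumor recurrence, resident gene
#' count), and `"table2"`, the 30 candidate genes amplified and overexpressed
#' in metastatic versus primary melanoma (R-segment coordinates, probe id,
#' relative expression, SAM q, gene symbol). Printed widths equal
#' `end - start` in both tables.
#'
#' @param name `"table1"` or `"table2"`.
#' @return A tibble of the transcribed rows.
#' @export
#' @examples
#' load_fixture("table1")
load_fixture <- function(name) {
  if (length(name) != 1 || !name %in% names(.fixture_files)) {
    abort(sprintf("unknown fixture '%s'; available: %s", name,
                  paste(names(.fixture_files), collapse = ", ")))
  }
  path <- system.file("extdata", .fixture_files[[name]], package = "igcomp")
  if (!nzchar(path)) abort("fixture file not found in installed package")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]]))) {
    abort(sprintf("fixture %s failed checksum verification", name))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (name == "table1") {
    tab$direction <- if_else(tab$peak >= 0, "gain", "loss")
  }
  tab
}
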