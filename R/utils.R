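#' @importFrom utils read.table write.table packageVersion head tail
#' @importFrom stats rbinom rpois sd setNames aggregate
NULL

TE_ORDERS <- c("LTR", "LINE", "TIR", "Helitron", "Maverick", "Others", "Unknown")

#' Write a table as TSV with a provenance header
#'
#' Output files carry `#`-prefixed header lines recording the package
#' version and any parameters supplied, so every table is traceable to the
#' run that produced it. Timestamps are deliberately omitted: a re-run with
#' identical inputs yields a byte-identical file.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param meta named list of provenance fields (parameters, seed, inputs).
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, meta = list()) {
  meta <- c(list(tool = paste0("tecensus ", as.character(packageVersion("tecensus")))), meta)
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, function(v) paste(format(v), collapse = ","), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read a TSV written by [write_tsv_prov()]
#'
#' @param path file path.
#' @return data frame (provenance header lines skipped).
#' @export
read_tsv_prov <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

# run code with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
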