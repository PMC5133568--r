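LINEAGE_COLUMNS <- c("cell_id", "mother_id", "t", "x", "y", "z",
                     "type", "volume", "surface")

#' Read a digital lineage table
#'
#' Reads the tab-separated lineage dialect used throughout the package: one
#' row per (cell, time step), with the canonical column set
#' `cell_id  mother_id  t  x  y  z  type  volume  surface`. Leading comment
#' lines starting with `#` may declare `# time_unit: min` (default) or
#' `# time_unit: hpf` (hours post-fertilisation, converted to minutes on
#' read) and `# window: <start> <end>`. Divisions are encoded by two rows
#' sharing the same `mother_id` at the time step following the mother's
#' last one.
#'
#' @param path Path to a lineage file.
#' @param validate Run [validate_lineage()] (default `TRUE`).
#' @return A [lineage_tree()].
#' @export
read_lineage <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("empty lineage file: ", path)
    if (!startsWith(ln, "#")) break
    head_lines <- c(head_lines, ln)
  }
  header <- strsplit(ln, "\t", fixed = TRUE)[[1]]
  if (!identical(header, LINEAGE_COLUMNS)) {
    stop("unexpected header; expected columns: ",
         paste(LINEAGE_COLUMNS, collapse = ", "))
  }
  body <- read.table(con, sep = "\t", header = FALSE, col.names = LINEAGE_COLUMNS,
                     na.strings = "NA", stringsAsFactors = FALSE,
                     colClasses = c("integer", "integer", "numeric", "numeric",
                                    "numeric", "numeric", "character", "numeric",
                                    "numeric"))
  time_unit <- "min"
  window <- NULL
  for (h in head_lines) {
    h2 <- sub("^#\\s*", "", h)
    if (grepl("^time_unit:", h2)) {
      time_unit <- trimws(sub("^time_unit:", "", h2))
    } else if (grepl("^window:", h2)) {
      window <- as.numeric(strsplit(trimws(sub("^window:", "", h2)), "\\s+")[[1]])
    }
  }
  if (!time_unit %in% c("min", "hpf")) stop("unknown time_unit: ", time_unit)
  if (time_unit == "hpf") {
    body$t <- body$t * 60
    if (!is.null(window)) window <- window * 60
  }
  lineage_tree(body, window = window, validate = validate)
}

# deterministic plain-decimal rendering so write -> read -> write is stable
fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "NA" else format(z, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  out
}

#' Write a lineage tree to a tab-separated file
#'
#' Inverse of [read_lineage()]; writes the canonical column order with a
#' `# time_unit: min` and `# window:` header so that
#' `write_lineage(read_lineage(f), f2)` reproduces a canonical file byte for
#' byte.
#'
#' @param tree A [lineage_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(tree, path) {
  rec <- tree$records[, LINEAGE_COLUMNS]
  rec <- rec[order(rec$cell_id, rec$t), , drop = FALSE]
  lines <- c(
    "# time_unit: min",
    sprintf("# window: %s %s", fmt_num(tree$window[1]), fmt_num(tree$window[2])),
    paste(LINEAGE_COLUMNS, collapse = "\t"),
    paste(fmt_num(rec$cell_id), fmt_num(rec$mother_id), fmt_num(rec$t),
          fmt_num(rec$x), fmt_num(rec$y), fmt_num(rec$z),
          ifelse(is.na(rec$type), "NA", rec$type),
          fmt_num(rec$volume), fmt_num(rec$surface), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
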