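#' Read and write 2D fields as plain-text TSV
#'
#' Lightweight interchange for the package's 2D quantities. Complex fields
#' are stored as a real/imaginary pair of files (`<stem>_real.tsv`,
#' `<stem>_imag.tsv`), matching the convention of storing complex volumes as
#' two real volumes; integer label maps and real maps use a single file.
#' Values are tab-separated, one matrix row per line, no headers.
#'
#' @param x Numeric or complex matrix.
#' @param path Output file (real matrix) or stem (complex matrix).
#' @return `write_field()` returns the path(s) invisibly; `read_field()`
#'   returns a numeric matrix, `read_field_complex()` a complex matrix.
#' @export
write_field <- function(x, path) {
  if (is.complex(x)) {
    paths <- paste0(path, c("_real.tsv", "_imag.tsv"))
    utils::write.table(Re(x), paths[1], sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(Im(x), paths[2], sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    return(invisible(paths))
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' @rdname write_field
#' @param stem Path stem used when the complex field was written.
#' @export
read_field_complex <- function(stem) {
  re <- read_field(paste0(stem, "_real.tsv"))
  im <- read_field(paste0(stem, "_imag.tsv"))
  matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
}

#' Write an elastogram bundle to a directory
#'
#' Writes the five parameter maps, the validity mask and a JSON-like
#' metadata file (frequency, density) as plain-text files.
#'
#' @param elastogram An `mre_elastogram`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_elastogram <- function(elastogram, dir) {
  stopifnot(inherits(elastogram, "mre_elastogram"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_field(elastogram$gstar, file.path(dir, "gstar"))
  for (nm in c("gp", "gpp", "absg", "phi"))
    write_field(elastogram[[nm]], file.path(dir, paste0(nm, ".tsv")))
  write_field(elastogram$valid_mask * 1, file.path(dir, "valid_mask.tsv"))
  meta <- sprintf('{"frequency": %g, "density": %g}',
                  elastogram$frequency, elastogram$density)
  writeLines(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

#' Write/read a study or count table as CSV
#'
#' Long-format CSV with the exact column names of the table.
#'
#' @param table A data.frame (StudyTable or CountRecord table).
#' @param path CSV file path.
#' @return `write_study_table()` the path invisibly; `read_study_table()`
#'   the data.frame with `treatment`/`time_point` restored as factors.
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time_point" %in% names(out)) {
    lev <- intersect(.study_time_points, unique(as.character(out$time_point)))
    out$time_point <- factor(as.character(out$time_point), levels = lev)
  }
  if ("treatment" %in% names(out)) out$treatment <- factor(out$treatment)
  out
}
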