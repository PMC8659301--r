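#' @keywords internal
"_PACKAGE"

# Shared internal helpers: TSV I/O conventions used by every reader/writer
# (tab-separated, header required, '#' comment lines ignored, UTF-8).

read_tsv_table <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  # Only whole lines starting with '#' are comments; '#' is data elsewhere
  # (SMILES use it for triple bonds).
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(
    text = lines,
    header = TRUE, sep = "\t", quote = "",
    comment.char = "", stringsAsFactors = FALSE,
    colClasses = "character", fill = FALSE
  )
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(
      "missing required column(s) in ", path, ": ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

write_tsv_table <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
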