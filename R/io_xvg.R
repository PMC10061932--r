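#' Read a GROMACS XVG columnar text file
#'
#' Skips `#` comment and `@` directive lines; numeric rows are whitespace
#' separated. When `@ s<i> legend "..."` directives are present the data
#' columns after the first are named accordingly (the first column is named
#' from the xaxis label when available, else `"x"`).
#'
#' @param path path to an `.xvg` file.
#' @return data.frame, one column per XVG column.
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  data_lines <- trimws(lines[!is_comment])
  if (!length(data_lines)) stop("XVG file contains no data rows: ", path)
  toks <- strsplit(data_lines, "\\s+")
  nfield <- lengths(toks)
  if (length(unique(nfield)) != 1L) {
    bad <- which(nfield != nfield[1])[1]
    stop("ragged XVG row ", bad, " in ", path, " (", nfield[bad],
         " fields, expected ", nfield[1], ")")
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(toks)),
                                  ncol = nfield[1], byrow = TRUE))
  if (anyNA(vals)) stop("non-numeric field in XVG data of ", path)
  df <- as.data.frame(vals)
  leg <- regmatches(lines, regexec("^@\\s*s(\\d+)\\s+legend\\s+\"([^\"]*)\"", lines))
  leg <- leg[lengths(leg) == 3L]
  nm <- paste0("V", seq_len(ncol(df)))
  nm[1] <- "x"
  xax <- regmatches(lines, regexec("^@\\s*xaxis\\s+label\\s+\"([^\"]*)\"", lines))
  xax <- xax[lengths(xax) == 2L]
  if (length(xax)) nm[1] <- make.names(xax[[1]][2])
  for (l in leg) {
    i <- as.integer(l[2]) + 2L
    if (i <= ncol(df)) nm[i] <- make.names(l[3])
  }
  names(df) <- nm
  df
}

#' Write a data.frame as a GROMACS-style XVG file
#'
#' Column names are emitted as `@ s<i> legend` directives so that
#' [read_xvg()] round-trips the table.
#'
#' @param df data.frame of numeric columns; the first column is the abscissa.
#' @param path output path.
#' @param title optional title directive.
#' @export
write_xvg <- function(df, path, title = "psurftools series") {
  stopifnot(is.data.frame(df), ncol(df) >= 1L)
  hdr <- c(sprintf("# generated by psurftools"),
           sprintf("@    title \"%s\"", title),
           sprintf("@    xaxis  label \"%s\"", names(df)[1]))
  if (ncol(df) > 1L) {
    hdr <- c(hdr, sprintf("@ s%d legend \"%s\"",
                          seq_len(ncol(df) - 1L) - 1L, names(df)[-1]))
  }
  body <- do.call(sprintf, c(list(paste(rep("%.8g", ncol(df)), collapse = " ")),
                             unname(as.list(df))))
  writeLines(c(hdr, body), path)
  invisible(path)
}
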