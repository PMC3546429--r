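.splitLine <- function(line, delim) {
  # strsplit drops a trailing empty field; pad it back
  out <- strsplit(line, delim, fixed = TRUE)[[1L]]
  if (nchar(line) && substring(line, nchar(line)) == delim)
    out <- c(out, "")
  out
}

.isNumericField <- function(x) {
  x != "" & !is.na(suppressWarnings(as.numeric(x)))
}

.detectDelimiter <- function(line, delimiter) {
  switch(delimiter,
    tab = "\t",
    comma = ",",
    auto = if (grepl("\t", line, fixed = TRUE)) "\t" else ",",
    stop("unknown delimiter '", delimiter, "'", call. = FALSE))
}

#' Read a named numeric matrix from delimited text
#'
#' Reads a TSV/CSV table into a validated numeric matrix. A header row
#' (detected by non-numeric fields, or forced by an empty leading
#' field) supplies column names and a leading non-numeric column
#' supplies row names; when either is absent, 1-based indices are
#' assigned automatically as names. Ragged rows, non-numeric data
#' cells and duplicated names are rejected with the offending location.
#'
#' @param path file to read.
#' @param delimiter \code{"auto"} (tab if the first line contains one,
#'   else comma), \code{"tab"} or \code{"comma"}.
#' @return Named numeric matrix.
#' @export
readMatrix <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(lines != ""), 0L))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  delim <- .detectDelimiter(lines[1L], delimiter)
  rows <- lapply(lines, .splitLine, delim = delim)

  first <- rows[[1L]]
  hasHeader <- first[1L] == "" || any(!.isNumericField(first[-1L]))
  body <- if (hasHeader) rows[-1L] else rows
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)

  width <- length(body[[1L]])
  for (i in seq_along(body))
    if (length(body[[i]]) != width)
      stop(sprintf("ragged input: line %d has %d fields, expected %d",
                   i + hasHeader, length(body[[i]]), width), call. = FALSE)

  firstCol <- vapply(body, `[`, character(1L), 1L)
  hasRowNames <- any(!.isNumericField(firstCol)) ||
    (hasHeader && length(first) == width && first[1L] == "") ||
    (hasHeader && length(first) == width - 1L)

  n <- width - hasRowNames
  if (n < 1L) stop("no data columns in ", path, call. = FALSE)

  colNames <- if (hasHeader) {
    h <- first
    # header may carry a leading field for the row-name column
    if (hasRowNames && length(h) == width) h <- h[-1L]
    if (length(h) != n)
      stop(sprintf("header has %d name(s) for %d data column(s)",
                   length(h), n), call. = FALSE)
    h
  } else rep("", n)

  vals <- matrix(NA_real_, length(body), n)
  for (i in seq_along(body)) {
    cells <- body[[i]][(1L + hasRowNames):width]
    num <- suppressWarnings(as.numeric(cells))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      stop(sprintf("non-numeric value '%s' at line %d, column %d",
                   cells[j], i + hasHeader, j), call. = FALSE)
    }
    vals[i, ] <- num
  }
  rownames(vals) <- tryCatch(
    .autoNames(if (hasRowNames) firstCol else NULL, length(body), "row"),
    error = function(e) stop(conditionMessage(e), " in ", path,
                             call. = FALSE))
  colnames(vals) <- .autoNames(colNames, n, "column")
  asDataMatrix(vals)
}

#' Write a named numeric matrix as delimited text
#'
#' Inverse of [readMatrix()]: a header row with an empty leading field
#' followed by the column names, then one row per matrix row beginning
#' with its name. Values are written with 17 significant digits so the
#' numeric round trip is exact.
#'
#' @param M numeric matrix (names auto-assigned if missing).
#' @param path output file.
#' @param delimiter \code{"tab"} (default) or \code{"comma"}.
#' @return \code{path}, invisibly.
#' @export
writeMatrix <- function(M, path, delimiter = c("tab", "comma")) {
  delimiter <- match.arg(delimiter)
  delim <- if (delimiter == "tab") "\t" else ","
  M <- asDataMatrix(M)
  header <- paste(c("", colnames(M)), collapse = delim)
  bodyRows <- vapply(seq_len(nrow(M)), function(i)
    paste(c(rownames(M)[i], sprintf("%.17g", M[i, ])), collapse = delim),
    character(1L))
  writeLines(c(header, bodyRows), path)
  invisible(path)
}

#' Write the files describing a CUR decomposition
#'
#' Writes, under a common file prefix: the factors \code{C}, \code{U}
#' and (full mode) \code{R} as delimited matrices; a scores table with
#' one row per row and column of the input (name, axis, leverage score,
#' selected flag); and a run summary (k, c, r, method, seed, relative
#' error) as \code{key: value} lines, sufficient to reproduce the run
#' exactly.
#'
#' @param result a \linkS4class{CURDecomposition}.
#' @param prefix path prefix for the output files
#'   (\code{<prefix>_C.tsv} etc.).
#' @param seed the seed the run used, recorded in the summary
#'   (\code{NA} if none).
#' @return Character vector of the files written, invisibly.
#' @export
writeOutputs <- function(result, prefix, seed = NULL) {
  stopifnot(is(result, "CURDecomposition"))
  files <- c(C = paste0(prefix, "_C.tsv"), U = paste0(prefix, "_U.tsv"))
  writeMatrix(result@C, files[["C"]])
  writeMatrix(result@U, files[["U"]])
  if (!result@restricted) {
    files[["R"]] <- paste0(prefix, "_R.tsv")
    writeMatrix(result@R, files[["R"]])
  }

  lev <- result@leverage
  rowSel <- if (is.null(result@rowSelection)) integer(0)
            else result@rowSelection@indices
  scores <- rbind(
    data.frame(name = names(lev@rowScores), axis = "rows",
               leverage = unname(lev@rowScores),
               selected = seq_along(lev@rowScores) %in% rowSel),
    data.frame(name = names(lev@columnScores), axis = "columns",
               leverage = unname(lev@columnScores),
               selected = seq_along(lev@columnScores) %in%
                 result@columnSelection@indices))
  files[["scores"]] <- paste0(prefix, "_scores.tsv")
  utils::write.table(scores, files[["scores"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  files[["summary"]] <- paste0(prefix, "_summary.txt")
  writeLines(c(
    paste0("k: ", result@k),
    paste0("c: ", length(result@columnSelection@indices)),
    paste0("r: ", if (result@restricted) "all" else length(rowSel)),
    paste0("method: ", result@columnSelection@method),
    paste0("seed: ", if (is.null(seed)) "NA" else seed),
    paste0("restricted: ", result@restricted),
    paste0("relative_error: ", if (is.null(result@relativeError)) "NA"
           else sprintf("%.17g", result@relativeError))),
    files[["summary"]])
  invisible(files)
}

#' Read a sample-labels file
#'
#' Two-column delimited text (sample name, group), no header.
#'
#' @param path file to read.
#' @param delimiter as in [readMatrix()].
#' @return Named character vector of group labels.
#' @export
readLabels <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  lines <- readLines(path)
  lines <- lines[lines != ""]
  if (!length(lines)) stop("empty labels file: ", path, call. = FALSE)
  delim <- .detectDelimiter(lines[1L], delimiter)
  rows <- lapply(lines, .splitLine, delim = delim)
  bad <- which(vapply(rows, length, integer(1L)) != 2L)
  if (length(bad))
    stop(sprintf("labels file line %d does not have 2 fields", bad[1L]),
         call. = FALSE)
  labs <- vapply(rows, `[`, character(1L), 2L)
  names(labs) <- vapply(rows, `[`, character(1L), 1L)
  labs
}
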