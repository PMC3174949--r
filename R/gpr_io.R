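#' Read a GenePix Result (GPR/ATF) file
#'
#' Parses an Axon Text File (ATF) quantification table as exported by
#' GenePix Pro. The ATF format consists of a version line (`ATF 1.0`),
#' a line with the number of optional header records and data columns,
#' the optional header records (`"Key=Value"`), a tab-separated column
#' name row and the data rows. Both Unix and Windows line endings are
#' accepted, and the version line may be space- or tab-separated.
#'
#' The spot intensity is taken from `intensity_column` (by convention
#' `"F635 Mean"` for incubation scans and `"F532 Mean"` for
#' scatterlight quality-control scans: the mean foreground intensity
#' without background subtraction). All remaining numeric columns are
#' preserved as extra per-spot features; non-numeric columns other than
#' the spot identifiers (`ID`, `Name`, `Sequence`) are dropped with a
#' notice.
#'
#' @param source path to a GPR file, or a character vector of its lines.
#' @param intensity_column name of the column holding the spot intensity.
#' @param channel label for the scan channel stored on the result
#'   (e.g. `"635"` for an incubation scan); defaults to a label parsed
#'   from `intensity_column`.
#' @return A `spot_table`: a list with elements `spots` (data frame with
#'   columns `block`, `row`, `column`, `id`, `sequence`, `intensity`,
#'   `flag`, and one column per extra feature), `feature_names`,
#'   `channel` and `header` (named character vector of ATF header
#'   records).
#' @seealso [write_gpr()], [join_scans()]
#' @export
read_gpr <- function(source, intensity_column = "F635 Mean", channel = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- as.character(source)
    if (length(lines) == 1L) lines <- strsplit(lines, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) {
    stop("malformed ATF header: file has fewer than 3 lines", call. = FALSE)
  }
  v <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  if (length(v) != 2L || toupper(v[[1L]]) != "ATF") {
    stop("malformed ATF header: first line is not an ATF version line",
         call. = FALSE)
  }
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[[2L]]), "[ \t]+")[[1L]]))
  if (length(counts) != 2L || anyNA(counts) || any(counts < 0L)) {
    stop("malformed ATF header: second line must give header and column counts",
         call. = FALSE)
  }
  n_hdr <- counts[[1L]]
  if (length(lines) < 2L + n_hdr + 1L) {
    stop("malformed ATF header: fewer header records than declared",
         call. = FALSE)
  }
  hdr_lines <- if (n_hdr > 0L) lines[3L:(2L + n_hdr)] else character(0)
  hdr_lines <- gsub('^"|"$', "", hdr_lines)
  keys <- sub("=.*$", "", hdr_lines)
  vals <- sub("^[^=]*=", "", hdr_lines)
  header <- stats::setNames(vals, keys)

  body <- lines[(3L + n_hdr):length(lines)]
  body <- body[nzchar(body)]
  dat <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, quote = "\"",
                           stringsAsFactors = FALSE)
  names(dat) <- gsub('^"|"$', "", names(dat))
  for (need in c("Block", "Row", "Column")) {
    if (!need %in% names(dat)) {
      stop(sprintf("malformed ATF header: required column '%s' missing", need),
           call. = FALSE)
    }
  }
  if (!intensity_column %in% names(dat)) {
    stop(sprintf("intensity column '%s' not present in file (columns: %s)",
                 intensity_column, paste(names(dat), collapse = ", ")),
         call. = FALSE)
  }

  addr <- paste(dat$Block, dat$Row, dat$Column, sep = ":")
  if (anyDuplicated(addr)) {
    dup <- unique(addr[duplicated(addr)])
    stop(sprintf("duplicate spot address(es) (block:row:column): %s",
                 paste(utils::head(dup, 10L), collapse = ", ")),
         call. = FALSE)
  }

  id <- if ("ID" %in% names(dat)) as.character(dat$ID)
        else if ("Name" %in% names(dat)) as.character(dat$Name)
        else sprintf("spot_%06d", seq_len(nrow(dat)))
  seqs <- if ("Sequence" %in% names(dat)) as.character(dat$Sequence)
          else rep(NA_character_, nrow(dat))
  flag <- if ("Flags" %in% names(dat)) as.integer(dat$Flags)
          else rep(0L, nrow(dat))

  intensity <- as.numeric(dat[[intensity_column]])
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("negative raw intensities found; ATF intensity columns must be >= 0",
         call. = FALSE)
  }

  reserved <- c("Block", "Row", "Column", "ID", "Name", "Sequence", "Flags",
                intensity_column)
  rest <- setdiff(names(dat), reserved)
  # an empty table carries no values to infer types from: keep all
  # declared feature columns as numeric
  numeric_rest <- if (nrow(dat) == 0L) rest
                  else rest[vapply(dat[rest], is.numeric, logical(1L))]
  dropped <- setdiff(rest, numeric_rest)
  if (length(dropped)) {
    message("dropping non-numeric column(s): ", paste(dropped, collapse = ", "))
  }

  spots <- data.frame(block = as.integer(dat$Block),
                      row = as.integer(dat$Row),
                      column = as.integer(dat$Column),
                      id = id, sequence = seqs,
                      intensity = intensity, flag = flag,
                      stringsAsFactors = FALSE, check.names = FALSE)
  for (col in numeric_rest) spots[[col]] <- as.numeric(dat[[col]])

  if (is.null(channel)) {
    channel <- if (grepl("532", intensity_column)) "532" else
               if (grepl("635", intensity_column)) "635" else intensity_column
  }
  new_spot_table(spots, feature_names = numeric_rest, channel = channel,
                 header = header, intensity_column = intensity_column)
}

new_spot_table <- function(spots, feature_names, channel, header,
                           intensity_column) {
  structure(list(spots = spots, feature_names = feature_names,
                 channel = channel, header = header,
                 intensity_column = intensity_column),
            class = "spot_table")
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d spots, channel %s, %d extra feature(s)\n",
              nrow(x$spots), x$channel, length(x$feature_names)))
  invisible(x)
}

#' Write a spot table as a GPR/ATF file
#'
#' Emits an `ATF 1.0` file readable by [read_gpr()]: the stored header
#' records, then columns `Block`, `Row`, `Column`, `ID`, (`Sequence` if
#' present), `Flags`, the intensity column, and the extra feature
#' columns, in that deterministic order. Numeric values are written
#' with 17 significant digits so that a write/read round trip
#' reproduces doubles bit-exactly.
#'
#' @param table a `spot_table` as returned by [read_gpr()].
#' @param destination output file path.
#' @return `destination`, invisibly.
#' @export
write_gpr <- function(table, destination) {
  stopifnot(inherits(table, "spot_table"))
  sp <- table$spots
  has_seq <- nrow(sp) > 0L && !all(is.na(sp$sequence))
  cols <- c("Block", "Row", "Column", "ID",
            if (has_seq) "Sequence", "Flags",
            table$intensity_column, table$feature_names)

  fmt_num <- function(x) {
    out <- sprintf("%.17g", x)
    int <- is.finite(x) & x == round(x) & abs(x) < 2^53
    out[int] <- sprintf("%.0f", x[int])
    out
  }
  mat <- matrix("", nrow = nrow(sp), ncol = length(cols))
  colnames(mat) <- cols
  if (nrow(sp) > 0L) {
    mat[, "Block"] <- as.character(sp$block)
    mat[, "Row"] <- as.character(sp$row)
    mat[, "Column"] <- as.character(sp$column)
    mat[, "ID"] <- sp$id
    if (has_seq) mat[, "Sequence"] <- ifelse(is.na(sp$sequence), "", sp$sequence)
    mat[, "Flags"] <- as.character(sp$flag)
    mat[, table$intensity_column] <- fmt_num(sp$intensity)
    for (f in table$feature_names) mat[, f] <- fmt_num(sp[[f]])
  }

  hdr <- table$header
  out <- c("ATF\t1.0",
           sprintf("%d\t%d", length(hdr), length(cols)),
           if (length(hdr)) sprintf('"%s=%s"', names(hdr), unname(hdr)),
           paste(sprintf('"%s"', cols), collapse = "\t"),
           apply(mat, 1L, paste, collapse = "\t"))
  con <- tryCatch(file(destination, open = "wt"),
                  error = function(e) stop("cannot write to '", destination,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(out, con)
  invisible(destination)
}

#' Join an incubation scan with its scatterlight QC scan
#'
#' Appends the scatterlight scan's intensity and feature columns to the
#' incubation table, spot by spot, under a distinguishing prefix. Both
#' tables must cover exactly the same spot addresses; the incubation
#' intensity is retained as the table's intensity.
#'
#' @param incubation `spot_table` from the 635 nm incubation scan.
#' @param scatterlight `spot_table` from the 532 nm scatterlight scan.
#' @param prefix prefix for the appended scatterlight columns.
#' @return A `spot_table` with the combined feature set.
#' @export
join_scans <- function(incubation, scatterlight, prefix = "SL.") {
  stopifnot(inherits(incubation, "spot_table"),
            inherits(scatterlight, "spot_table"))
  key <- function(sp) paste(sp$block, sp$row, sp$column, sep = ":")
  ki <- key(incubation$spots); ks <- key(scatterlight$spots)
  only_i <- setdiff(ki, ks); only_s <- setdiff(ks, ki)
  if (length(only_i) || length(only_s)) {
    stop("scan address sets differ; only in incubation: {",
         paste(utils::head(only_i, 10L), collapse = ", "),
         "}; only in scatterlight: {",
         paste(utils::head(only_s, 10L), collapse = ", "), "}",
         call. = FALSE)
  }
  idx <- match(ki, ks)
  sp <- incubation$spots
  sl_cols <- c(scatterlight$intensity_column, scatterlight$feature_names)
  sl <- scatterlight$spots
  sl$..intensity <- sl$intensity
  added <- character(0)
  for (col in sl_cols) {
    src <- if (col == scatterlight$intensity_column) "..intensity" else col
    newname <- paste0(prefix, col)
    sp[[newname]] <- sl[[src]][idx]
    added <- c(added, newname)
  }
  new_spot_table(sp, feature_names = c(incubation$feature_names, added),
                 channel = incubation$channel, header = incubation$header,
                 intensity_column = incubation$intensity_column)
}
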