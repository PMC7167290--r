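# GenePix Results (GPR / ATF) reading and writing, and assembly of spot
# records into a UbLArraySet. The dialect is GPR v3-style: an ATF preamble,
# quoted "key=value" header records, then a tab-delimited table with
# Block/Column/Row/Name/ID, F<wavelength> Median and B<wavelength> Median
# per channel, and Flags. Extra columns are tolerated and ignored.

.gprCols <- function(wavelengths) {
  c("Block", "Column", "Row", "Name", "ID",
    as.vector(rbind(paste0("F", wavelengths, " Median"),
                    paste0("B", wavelengths, " Median"))),
    "Flags")
}

#' Write spot data as a GPR (ATF) file
#'
#' Emits the GPR v3-style dialect read back by [readGPR()]. Used by the
#' simulator; exact round-trip of intensities is guaranteed because values
#' are printed in full precision.
#'
#' @param spots data.frame with columns `block`, `column`, `row`, `name`,
#'   `id`, and per wavelength `F<w>` and `B<w>`, plus `flags`.
#' @param path Output file path.
#' @param wavelengths Integer vector of scanner wavelengths (default
#'   `c(635, 532)`).
#' @param header Named character vector of extra header records
#'   (e.g. `c(ArrayID = "exp1_array1")`).
#' @return `path`, invisibly.
#' @export
writeGPR <- function(spots, path, wavelengths = c(635L, 532L),
                     header = character()) {
  records <- c("Type=GenePix Results 3",
               paste0("Wavelengths=", paste(wavelengths, collapse = "\t")),
               if (length(header)) paste0(names(header), "=", header))
  colnames_ <- .gprCols(wavelengths)
  dataCols <- cbind(spots$block, spots$column, spots$row)
  txt <- c(
    "ATF\t1.0",
    sprintf("%d\t%d", length(records), length(colnames_)),
    sprintf("\"%s\"", records),
    paste(sprintf("\"%s\"", colnames_), collapse = "\t"))
  body <- do.call(paste, c(list(spots$block, spots$column, spots$row,
                                sprintf("\"%s\"", spots$name),
                                sprintf("\"%s\"", spots$id)),
                           unlist(lapply(wavelengths, function(w) {
                             list(sprintf("%.6g", spots[[paste0("F", w)]]),
                                  sprintf("%.6g", spots[[paste0("B", w)]]))
                           }), recursive = FALSE),
                           list(spots$flags, sep = "\t")))
  writeLines(c(txt, body), path, useBytes = TRUE)
  invisible(path)
}

stripQuotes <- function(x) gsub('^"|"$', "", x)

#' Read a GPR (GenePix Results) file into spot records
#'
#' Parses the ATF preamble, retains the header records, and returns one spot
#' record per data row and wavelength. Rows with an empty `Name`/`ID` are
#' kept but marked unmapped (`mapped = FALSE`). Spots with a negative flag
#' code have their intensities set to `NA` downstream (bad-spot semantics);
#' the raw flag is preserved here.
#'
#' @param path Path to a GPR file.
#' @return data.frame with columns `array_id`, `block`, `column`, `row`,
#'   `protein_id`, `protein_name`, `wavelength`, `fg`, `bg`, `flags`,
#'   `mapped`; header records in `attr(, "header")`.
#' @export
readGPR <- function(path) {
  if (!file.exists(path)) stopf("GPR file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !grepl("^ATF", lines[[1L]]))
    stopf("%s: not an ATF/GPR file (missing ATF magic)", path)
  counts <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  nHead <- suppressWarnings(as.integer(counts[[1L]]))
  if (is.na(nHead)) stopf("%s: malformed ATF record-count line", path)
  if (length(lines) < 2L + nHead + 1L)
    stopf("%s: header terminator missing (declared %d header records)",
          path, nHead)
  headerLines <- stripQuotes(lines[2L + seq_len(nHead)])
  kv <- regmatches(headerLines, regexpr("=", headerLines),
                   invert = TRUE)
  header <- vapply(kv, function(p) if (length(p) == 2L) p[[2L]] else "",
                   character(1))
  names(header) <- vapply(kv, `[[`, character(1), 1L)
  hval <- function(k) if (k %in% names(header)) header[[k]] else NULL
  wl <- hval("Wavelengths") %||% "635\t532"
  wavelengths <- as.integer(strsplit(wl, "[\t ]+")[[1L]])
  colLineNo <- 3L + nHead
  cols <- stripQuotes(strsplit(lines[[colLineNo]], "\t", fixed = TRUE)[[1L]])
  fCols <- grep("^F[0-9]+ Median$", cols, value = TRUE)
  gotWl <- sort(as.integer(sub("^F([0-9]+) Median$", "\\1", fCols)))
  if (!length(fCols))
    stopf("%s: no 'F<wavelength> Median' columns found", path)
  if (!setequal(gotWl, wavelengths))
    stopf("%s: wavelength columns (%s) disagree with header (%s)",
          path, paste(gotWl, collapse = ","),
          paste(wavelengths, collapse = ","))
  need <- .gprCols(wavelengths)
  miss <- setdiff(need, cols)
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  dataLines <- lines[-seq_len(colLineNo)]
  dataLines <- dataLines[nzchar(dataLines)]
  arrayId <- hval("ArrayID") %||% sub("\\.[^.]*$", "", basename(path))
  if (!length(dataLines)) {
    out <- data.frame(array_id = character(), block = integer(),
                      column = integer(), row = integer(),
                      protein_id = character(), protein_name = character(),
                      wavelength = integer(), fg = numeric(), bg = numeric(),
                      flags = integer(), mapped = logical())
    attr(out, "header") <- header
    return(out)
  }
  fields <- strsplit(dataLines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc < length(cols))) {
    bad <- which(nc < length(cols))[[1L]]
    stopf("%s: line %d has %d field(s), expected >= %d",
          path, colLineNo + bad, nc[[bad]], length(cols))
  }
  tab <- do.call(rbind, fields)
  colnames(tab) <- cols[seq_len(ncol(tab))]
  getNum <- function(cn) {
    v <- suppressWarnings(as.numeric(tab[, cn]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[[1L]]
      stopf("%s: line %d: non-numeric value '%s' in column '%s'",
            path, colLineNo + bad, tab[bad, cn], cn)
    }
    v
  }
  base <- data.frame(
    array_id = arrayId,
    block = as.integer(getNum("Block")),
    column = as.integer(getNum("Column")),
    row = as.integer(getNum("Row")),
    protein_id = stripQuotes(tab[, "ID"]),
    protein_name = stripQuotes(tab[, "Name"]),
    flags = as.integer(getNum("Flags")),
    stringsAsFactors = FALSE)
  base$mapped <- nzchar(base$protein_id) & nzchar(base$protein_name)
  out <- do.call(rbind, lapply(wavelengths, function(w) {
    d <- base
    d$wavelength <- w
    d$fg <- getNum(paste0("F", w, " Median"))
    d$bg <- getNum(paste0("B", w, " Median"))
    d
  }))
  if (any(out$fg < 0) || any(out$bg < 0))
    stopf("%s: negative intensity encountered", path)
  rownames(out) <- NULL
  attr(out, "header") <- header
  out
}

#' Write / read a UbLArraySet as TSV + sidecar metadata CSV + JSON log
#'
#' `writeIntensityMatrix()` writes one `<modifier>.tsv` (proteins x
#' arrays) per assay, an `array_metadata.csv` sidecar and a
#' `transform_log.json`; `readIntensityMatrix()` restores the set.
#'
#' @param x A [UbLArraySet-class].
#' @param dir Directory to write to / read from.
#' @param level Level recorded on read-back (`"protein"` or `"spot"`).
#' @return `writeIntensityMatrix()`: `dir`, invisibly;
#'   `readIntensityMatrix()`: a [UbLArraySet-class].
#' @export
writeIntensityMatrix <- function(x, dir) {
  stopifnot(is(x, "UbLArraySet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in assayNames(x)) {
    d <- data.frame(row_id = rownames(x), assay(x, nm),
                    check.names = FALSE)
    write.table(d, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  write.csv(arrayMeta(x), file.path(dir, "array_metadata.csv"),
            row.names = FALSE, quote = TRUE)
  jsonlite::write_json(
    list(level = intensityLevel(x), assays = assayNames(x),
         transformLog = transformLog(x)),
    file.path(dir, "transform_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeIntensityMatrix
#' @export
readIntensityMatrix <- function(dir, level = NULL) {
  logPath <- file.path(dir, "transform_log.json")
  if (!file.exists(logPath)) stopf("no transform_log.json in %s", dir)
  info <- jsonlite::read_json(logPath, simplifyVector = TRUE)
  meta <- read.csv(file.path(dir, "array_metadata.csv"))
  assays <- lapply(info$assays, function(nm) {
    d <- read.delim(file.path(dir, paste0(nm, ".tsv")),
                    check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$row_id
    m[, meta$array_id, drop = FALSE]
  })
  names(assays) <- info$assays
  cd <- DataFrame(meta, row.names = meta$array_id)
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(
      protein_id = sub("\\.[0-9]+$", "", rownames(assays[[1L]])),
      row.names = rownames(assays[[1L]])),
    colData = cd)
  metadata(se)$transformLog <- as.character(info$transformLog)
  new("UbLArraySet", se, level = level %||% info$level)
}

#' Default wavelength-to-modifier channel map
#'
#' 635 nm detects the anti-SUMO-1 (Alexa 647-class) channel and 532 nm the
#' anti-Flag/ubiquitin (Alexa 546-class) channel.
#' @return Named character vector mapping wavelength to modifier.
#' @export
defaultChannelMap <- function() c("635" = "SUMO1", "532" = "ubiquitin")

#' Assemble spot records into a duplicate-level UbLArraySet
#'
#' Combines per-array spot records with array metadata into the central
#' intensity container: one foreground and one background assay per modifier
#' channel, duplicate spots kept as separate sub-rows (`<protein>.1`,
#' `<protein>.2`). All arrays must share an identical protein grid.
#' Spots with negative flag codes are set to `NA` (bad-spot semantics).
#'
#' @param spots data.frame of spot records ([readGPR()] output, possibly
#'   row-bound over arrays) or a list of such data.frames.
#' @param meta data.frame of array metadata with columns `array_id`,
#'   `experiment`, `cell_line`, `condition`, `nem_control`.
#' @param channelMap Named character vector wavelength -> modifier.
#' @return A [UbLArraySet-class] at spot level.
#' @export
assembleMatrix <- function(spots, meta, channelMap = defaultChannelMap()) {
  if (is.list(spots) && !is.data.frame(spots))
    spots <- do.call(rbind, spots)
  stopifnot(is.data.frame(spots), is.data.frame(meta))
  meta$nem_control <- as.logical(meta$nem_control)
  arrays <- unique(spots$array_id)
  missingMeta <- setdiff(arrays, meta$array_id)
  if (length(missingMeta))
    stopf("array(s) without metadata: %s",
          paste(missingMeta, collapse = ", "))
  meta <- meta[meta$array_id %in% arrays, , drop = FALSE]
  spots <- spots[spots$mapped, , drop = FALSE]
  # verify identical grids
  gridOf <- function(d) {
    g <- unique(d[order(d$block, d$row, d$column),
                  c("block", "row", "column", "protein_id")])
    paste(g$block, g$row, g$column, g$protein_id, sep = ":")
  }
  grids <- lapply(split(spots, spots$array_id), gridOf)
  ref <- grids[[1L]]
  for (a in names(grids)) {
    if (!identical(grids[[a]], ref)) {
      off <- unique(sub(".*:", "", c(setdiff(grids[[a]], ref),
                                     setdiff(ref, grids[[a]]))))
      stopf("protein grid of array '%s' differs from '%s' (e.g. %s)",
            a, names(grids)[[1L]],
            paste(head(off, 5L), collapse = ", "))
    }
  }
  # duplicate index per protein within an array/wavelength, by grid order
  ord <- order(spots$array_id, spots$wavelength, spots$protein_id,
               spots$block, spots$row, spots$column)
  spots <- spots[ord, , drop = FALSE]
  key <- paste(spots$array_id, spots$wavelength, spots$protein_id)
  spots$dup <- stats::ave(seq_along(key), key, FUN = seq_along)
  spots$rowid <- paste0(spots$protein_id, ".", spots$dup)
  rowids <- unique(spots$rowid[order(spots$protein_id, spots$dup)])
  arrayIds <- meta$array_id
  badFlag <- spots$flags < 0
  spots$fg[badFlag] <- NA_real_
  spots$bg[badFlag] <- NA_real_
  assays <- list()
  for (wl in names(channelMap)) {
    sub <- spots[spots$wavelength == as.integer(wl), , drop = FALSE]
    if (!nrow(sub))
      stopf("no spots for wavelength %s declared in channelMap", wl)
    fg <- matrix(NA_real_, length(rowids), length(arrayIds),
                 dimnames = list(rowids, arrayIds))
    bg <- fg
    idx <- cbind(match(sub$rowid, rowids), match(sub$array_id, arrayIds))
    fg[idx] <- sub$fg
    bg[idx] <- sub$bg
    mod <- channelMap[[wl]]
    assays[[mod]] <- fg
    assays[[paste0(mod, ".bg")]] <- bg
  }
  rowDat <- DataFrame(
    protein_id = sub("\\.[0-9]+$", "", rowids),
    spot = as.integer(sub("^.*\\.", "", rowids)),
    row.names = rowids)
  cd <- DataFrame(meta, row.names = meta$array_id)
  se <- SummarizedExperiment(assays = assays, rowData = rowDat, colData = cd)
  metadata(se)$channelMap <- channelMap
  metadata(se)$transformLog <- character()
  new("UbLArraySet", se, level = "spot")
}
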