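# Readers and writers for the plain-text interchange formats: census TSV,
# superkingdom map TSV, calibration TSV, NEXUS / relaxed-PHYLIP character
# matrices, and the synthetic-truth JSON.

#' Read an abundance census from a TSV file
#'
#' Expected layout: a header row of domain ids, then one row per proteome
#' whose first field is the proteome id and remaining fields are
#' non-negative integer counts. Ragged rows, non-integer cells and
#' duplicated ids are reported with their line number.
#'
#' @param path path to the TSV file.
#' @param superkingdoms optional named character vector (or path to a
#'   two-column TSV, see [readSuperkingdomMap()]) mapping proteome to
#'   superkingdom.
#' @return An [AbundanceCensus-class].
#' @seealso [writeCensusTable()]
#' @export
readCensusTable <- function(path, superkingdoms = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 1L) stop("census file is empty: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    # tolerate an (empty or labelled) corner cell above the proteome ids
    domains <- if (length(fields) > 1L &&
                   length(header) == length(fields[[2L]])) header[-1L]
               else header
    ncolExp <- length(domains) + 1L
    if (anyDuplicated(domains))
        stop("line 1: duplicate domain id(s): ",
             paste(unique(domains[duplicated(domains)]), collapse = ", "))
    body <- fields[-1L]
    counts <- matrix(0L, nrow = length(body), ncol = length(domains))
    proteomes <- character(length(body))
    for (i in seq_along(body)) {
        f <- body[[i]]
        line <- i + 1L
        if (length(f) != ncolExp)
            stop(sprintf("line %d: expected %d fields, found %d",
                         line, ncolExp, length(f)))
        proteomes[i] <- f[1L]
        vals <- suppressWarnings(as.numeric(f[-1L]))
        if (anyNA(vals))
            stop(sprintf("line %d: non-numeric cell '%s'",
                         line, f[-1L][which(is.na(vals))[1L]]))
        if (any(vals != floor(vals)) || any(vals < 0))
            stop(sprintf("line %d: cell '%s' is not a non-negative integer",
                         line,
                         f[-1L][which(vals != floor(vals) | vals < 0)[1L]]))
        counts[i, ] <- as.integer(vals)
    }
    dup <- which(duplicated(proteomes))
    if (length(dup))
        stop(sprintf("line %d: duplicate proteome id '%s'",
                     dup[1L] + 1L, proteomes[dup[1L]]))
    dimnames(counts) <- list(proteomes, domains)
    if (is.character(superkingdoms) && length(superkingdoms) == 1L &&
        is.null(names(superkingdoms)) && file.exists(superkingdoms))
        superkingdoms <- readSuperkingdomMap(superkingdoms)
    AbundanceCensus(t(counts), superkingdoms = superkingdoms)
}

#' Write an abundance census as TSV
#'
#' Inverse of [readCensusTable()]: header row of domain ids, one row per
#' proteome.
#'
#' @param census an [AbundanceCensus-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCensusTable <- function(census, path) {
    g <- censusCounts(census, "proteomes")
    lines <- c(paste(c("proteome", colnames(g)), collapse = "\t"),
               vapply(seq_len(nrow(g)), function(i)
                   paste(c(rownames(g)[i], g[i, ]), collapse = "\t"), ""))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a proteome-to-superkingdom map
#'
#' Two-column TSV (`proteome`, `superkingdom`), with or without a header
#' line.
#'
#' @param path file path.
#' @param map named character vector proteome -> superkingdom.
#' @return `readSuperkingdomMap()`: a named character vector;
#'   `writeSuperkingdomMap()`: `path`, invisibly.
#' @export
readSuperkingdomMap <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("superkingdom map needs two columns: ", path)
    if (tolower(df[1L, 1L]) %in% c("proteome", "id"))
        df <- df[-1L, , drop = FALSE]
    setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname readSuperkingdomMap
#' @export
writeSuperkingdomMap <- function(map, path) {
    writeLines(c("proteome\tsuperkingdom",
                 paste(names(map), map, sep = "\t")), path)
    invisible(path)
}

#' Read / write a calibration table
#'
#' A calibration point ties either a named domain or a literal nd value to
#' a geological age in Gy. TSV columns: `id` (domain id, or empty/NA when
#' `nd` is given), `nd`, `age_Gy`, `label`.
#'
#' @param path file path.
#' @param cal data.frame with columns `id`, `nd`, `age_Gy` and optionally
#'   `label`.
#' @return `readCalibrationTable()`: a data.frame as above.
#' @seealso [fitClock()]
#' @export
readCalibrationTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = c("NA", ""))
    if (!all(c("age_Gy", "id") %in% colnames(df)) &&
        !all(c("age_Gy", "nd") %in% colnames(df)))
        stop("calibration table needs 'age_Gy' plus 'id' and/or 'nd' columns")
    if (is.null(df$id)) df$id <- NA_character_
    if (is.null(df$nd)) df$nd <- NA_real_
    if (is.null(df$label)) df$label <- NA_character_
    if (any(df$age_Gy < 0, na.rm = TRUE))
        stop("calibration ages must be >= 0 Gy")
    df[, c("id", "nd", "age_Gy", "label")]
}

#' @rdname readCalibrationTable
#' @export
writeCalibrationTable <- function(cal, path) {
    if (is.null(cal$nd)) cal$nd <- NA_real_
    if (is.null(cal$label)) cal$label <- NA_character_
    utils::write.table(cal[, c("id", "nd", "age_Gy", "label")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a coded character matrix to NEXUS or relaxed PHYLIP
#'
#' The NEXUS output declares the full 24-symbol alphabet and an ASSUMPTIONS
#' block marking every character linearly ordered (Wagner); relaxed PHYLIP
#' writes `name<space>states` with one symbol per character and no spaces
#' inside the state string.
#'
#' @param m a [CodedMatrix-class].
#' @param path output path.
#' @param format `"nexus"` (default) or `"phylip-relaxed"`.
#' @return `path`, invisibly.
#' @seealso [readCharacterMatrix()]
#' @export
writeCharacterMatrix <- function(m, path, format = c("nexus", "phylip-relaxed")) {
    format <- match.arg(format)
    st <- codedStates(m)
    taxa <- rownames(st)
    if (is.null(taxa)) stop("coded matrix has no taxon labels")
    safe <- gsub("[^A-Za-z0-9_.]", "_", taxa)
    rows <- vapply(seq_len(nrow(st)), function(i)
        paste(stateToSymbol(st[i, ]), collapse = ""), "")
    if (format == "nexus") {
        pad <- formatC(safe, width = max(nchar(safe)), flag = "-")
        lines <- c(
            "#NEXUS",
            sprintf("[domClock character matrix; orientation=%s scheme=%s gmax=%s]",
                    orientation(m), m@scheme, format(m@gmax)),
            "BEGIN DATA;",
            sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
            paste0("  FORMAT DATATYPE=STANDARD RESPECTCASE MISSING=? GAP=- ",
                   "SYMBOLS=\"", paste(codingAlphabet(), collapse = ""), "\";"),
            "  MATRIX",
            paste0("    ", pad, "  ", rows),
            "  ;",
            "END;",
            "BEGIN ASSUMPTIONS;",
            "  OPTIONS DEFTYPE=ORD POLYTCOUNT=MINSTEPS;",
            sprintf("  TYPESET * ordered = ord: 1-%d;", ncol(st)),
            "END;")
    } else {
        lines <- c(sprintf("%d %d", nrow(st), ncol(st)),
                   paste(safe, rows, sep = "  "))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a coded character matrix from NEXUS
#'
#' Parses STANDARD-datatype NEXUS matrices of the dialect written by
#' [writeCharacterMatrix()] (one row per taxon, states as a contiguous
#' symbol string). Unknown symbols are rejected.
#'
#' @param path NEXUS file path.
#' @param orientation orientation to stamp on the result (`"ToL"` or
#'   `"ToD"`); the annotation comment written by [writeCharacterMatrix()]
#'   is honoured when present and `orientation` is missing.
#' @return A [CodedMatrix-class].
#' @export
readCharacterMatrix <- function(path, orientation = NULL) {
    lines <- readLines(path)
    if (!length(lines) || !grepl("^#NEXUS", lines[1L], ignore.case = TRUE))
        stop("not a NEXUS file: ", path)
    meta <- regmatches(lines, regexec(
        "orientation=(ToL|ToD) scheme=(\\S+) gmax=([^]\\s]+)", lines))
    meta <- Filter(length, meta)
    scheme <- NA_character_; gm <- NA_real_
    if (length(meta)) {
        if (is.null(orientation)) orientation <- meta[[1L]][2L]
        scheme <- meta[[1L]][3L]
        gm <- suppressWarnings(as.numeric(meta[[1L]][4L]))
    }
    if (is.null(orientation)) orientation <- "ToL"
    inMatrix <- FALSE
    taxa <- character(); rows <- character()
    for (ln in lines) {
        s <- trimws(ln)
        if (!inMatrix) {
            if (toupper(s) == "MATRIX") inMatrix <- TRUE
            next
        }
        if (s == ";" || toupper(s) == "END;") break
        if (!nzchar(s)) next
        parts <- strsplit(s, "[ \t]+")[[1L]]
        if (length(parts) < 2L)
            stop("malformed NEXUS matrix row: ", s)
        taxa <- c(taxa, parts[1L])
        rows <- c(rows, paste(parts[-1L], collapse = ""))
    }
    if (!length(taxa)) stop("no MATRIX block found in ", path)
    nch <- unique(nchar(rows))
    if (length(nch) != 1L)
        stop("NEXUS matrix rows have unequal lengths")
    st <- t(vapply(rows, function(r)
        symbolToState(strsplit(r, "")[[1L]]), integer(nch)))
    dimnames(st) <- list(taxa, sprintf("char%03d", seq_len(nch)))
    CodedMatrix(st, orientation = orientation, scheme = scheme, gmax = gm)
}

#' Write synthetic-truth records as JSON
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSyntheticTruth <- function(truth, path) {
    obj <- list(
        birth_time = as.list(truth@birthTime),
        tree_newick = ape::write.tree(truth@tree),
        loss_events = truth@lossEvents,
        root_repertoire = truth@rootRepertoire)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
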