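#' @include AllClasses.R conditions.R
NULL

.sa_log <- function(...) {
    if (isTRUE(getOption("sumoarray.verbose", FALSE))) message(...)
    invisible(NULL)
}

.addr_key <- function(block, row, col) paste(block, row, col, sep = ":")

#' Read an array design from TSV
#'
#' The design file is tab-separated with header columns `Block`, `Row`,
#' `Column`, `ID`, `Name`, `Role`, `DupGroup` (1-based coordinates, GPR
#' convention). Grid dimensions are inferred from the maxima unless given.
#'
#' @param path path to the design TSV.
#' @param nBlocks,blockRows,blockCols optional grid dimensions; inferred from
#'   the file when `NULL`.
#' @return A validated [ArrayDesign-class].
#' @export
readDesign <- function(path, nBlocks = NULL, blockRows = NULL,
                       blockCols = NULL) {
    if (!file.exists(path)) stop("design file not found: ", path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    need <- c("Block", "Row", "Column", "ID", "Name", "Role", "DupGroup")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("design file missing columns: ", paste(miss, collapse = ", "))
    spots <- data.frame(
        block = as.integer(d$Block), row = as.integer(d$Row),
        col = as.integer(d$Column), protein_id = as.character(d$ID),
        gene_symbol = as.character(d$Name), role = as.character(d$Role),
        dup_group = as.character(d$DupGroup), stringsAsFactors = FALSE)
    spots$dup_group[!nzchar(spots$dup_group) | is.na(spots$dup_group)] <- NA
    new("ArrayDesign",
        nBlocks = as.integer(nBlocks %||% max(spots$block)),
        blockRows = as.integer(blockRows %||% max(spots$row)),
        blockCols = as.integer(blockCols %||% max(spots$col)),
        spots = spots)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an array design to TSV
#'
#' @param design an [ArrayDesign-class].
#' @param path output path. UTF-8, LF line endings, header row.
#' @return Invisibly, `path`.
#' @export
writeDesign <- function(design, path) {
    stopifnot(is(design, "ArrayDesign"))
    sp <- design@spots
    out <- data.frame(Block = sp$block, Row = sp$row, Column = sp$col,
                      ID = sp$protein_id, Name = sp$gene_symbol,
                      Role = sp$role,
                      DupGroup = ifelse(is.na(sp$dup_group), "",
                                        sp$dup_group))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}

## locate the ATF/GPR column-name row: first tab-separated line whose first
## field is "Block" (quotes stripped); header length before it is arbitrary
.gpr_table <- function(lines) {
    first <- vapply(strsplit(lines, "\t", fixed = TRUE),
                    function(x) gsub('"', "", x[1] %||% ""), character(1))
    hdr <- which(first == "Block")[1]
    if (is.na(hdr)) stop("no column row containing 'Block' found (not a GPR?)")
    utils::read.delim(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a spot-quantified scan against a design
#'
#' Two dialects are supported. `"gpr"` is the GenePix Results dialect:
#' ATF-style header of any length, a column row located by the presence of
#' `Block`, and at minimum the columns `Block`, `Row`, `Column`, `ID`, the
#' foreground/background columns (default `F532 Median` / `B532 Median`,
#' override via `columns` for other wavelengths) and `Flags`. Negative GenePix
#' flags map to `bad`; if an `F532 % Sat.` column (or `columns$sat`) is
#' present, spots above `satPercent` map to `saturated`. `"tsv"` is the
#' package's own scan format as written by [writeScan()], which carries the
#' condition metadata in `#`-prefixed header lines.
#'
#' Addresses absent from the design are skipped with a warning and counted in
#' the `skipped` attribute of the result; the scan never contains spots the
#' design does not.
#'
#' @param path scan file.
#' @param design the [ArrayDesign-class] the scan is validated against.
#' @param dialect `"gpr"` or `"tsv"`.
#' @param condition,replicate condition metadata; required for `"gpr"` (GPR
#'   files carry none), optional overrides for `"tsv"`.
#' @param columns optional list with elements `fg`, `bg` and optionally `sat`
#'   naming the foreground/background/saturation columns.
#' @param satPercent saturation percentage above which a spot is `saturated`.
#' @return An [ArrayScan-class] with attribute `skipped` (number of file rows
#'   whose address is not in the design).
#' @export
readScan <- function(path, design, dialect = c("tsv", "gpr"),
                     condition = NULL, replicate = NULL, columns = NULL,
                     satPercent = 50) {
    dialect <- match.arg(dialect)
    stopifnot(is(design, "ArrayDesign"))
    if (!file.exists(path)) stop("scan file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    if (dialect == "gpr") {
        if (is.null(condition) || is.null(replicate))
            stop("GPR files carry no condition metadata; supply 'condition' and 'replicate'")
        tab <- .gpr_table(lines)
        fg <- (columns %||% list())$fg %||% "F532 Median"
        bg <- (columns %||% list())$bg %||% "B532 Median"
        satcol <- (columns %||% list())$sat %||% "F532 % Sat."
        need <- c("Block", "Row", "Column", "ID", fg, bg, "Flags")
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop("GPR missing mandatory columns: ", paste(miss, collapse = ", "))
        flag <- rep("ok", nrow(tab))
        if (satcol %in% names(tab))
            flag[as.numeric(tab[[satcol]]) > satPercent] <- "saturated"
        flag[as.numeric(tab$Flags) < 0] <- "bad"
        m <- data.frame(block = as.integer(tab$Block),
                        row = as.integer(tab$Row),
                        col = as.integer(tab$Column),
                        foreground = as.numeric(tab[[fg]]),
                        background = as.numeric(tab[[bg]]),
                        flag = flag, stringsAsFactors = FALSE)
    } else {
        meta_lines <- grep("^#", lines, value = TRUE)
        meta <- list()
        for (ml in meta_lines) {
            kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
            if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
        }
        tab <- utils::read.delim(text = paste(grep("^#", lines, value = TRUE,
                                                   invert = TRUE),
                                              collapse = "\n"),
                                 stringsAsFactors = FALSE, check.names = FALSE)
        need <- c("Block", "Row", "Column", "ID", "F", "B", "Flag")
        miss <- setdiff(need, names(tab))
        if (length(miss))
            stop("scan TSV missing columns: ", paste(miss, collapse = ", "))
        if (is.null(condition)) {
            if (is.null(meta$e1e2_level))
                stop("scan TSV lacks condition metadata; supply 'condition'")
            condition <- conditionLabel(meta$e1e2_level, meta$e3 %||% "none",
                                        meta$isoform)
        }
        replicate <- replicate %||% as.integer(meta$replicate)
        m <- data.frame(block = as.integer(tab$Block),
                        row = as.integer(tab$Row),
                        col = as.integer(tab$Column),
                        foreground = as.numeric(tab$F),
                        background = as.numeric(tab$B),
                        flag = as.character(tab$Flag),
                        stringsAsFactors = FALSE)
    }
    known <- .addr_key(design@spots$block, design@spots$row, design@spots$col)
    key <- .addr_key(m$block, m$row, m$col)
    skipped <- sum(!key %in% known)
    if (skipped > 0) {
        warning(skipped, " spot(s) at addresses absent from the design were skipped")
        m <- m[key %in% known, , drop = FALSE]
    }
    scan <- new("ArrayScan", condition = condition,
                replicate = as.integer(replicate), measurements = m)
    attr(scan, "skipped") <- skipped
    scan
}

#' Write a scan to disk
#'
#' The `"tsv"` dialect stores condition metadata in `#`-prefixed header lines
#' followed by a `Block/Row/Column/ID/F/B/Flag` table and round-trips through
#' [readScan()]. The `"gpr"` dialect writes a minimal GenePix-style file
#' (ATF header, `F532 Median`/`B532 Median`/`Flags` columns) for
#' interoperability; condition metadata is not representable there.
#'
#' @param scan an [ArrayScan-class].
#' @param design the matching [ArrayDesign-class] (provides spot IDs).
#' @param path output path.
#' @param dialect `"tsv"` or `"gpr"`.
#' @return Invisibly, `path`.
#' @export
writeScan <- function(scan, design, path, dialect = c("tsv", "gpr")) {
    dialect <- match.arg(dialect)
    stopifnot(is(scan, "ArrayScan"), is(design, "ArrayDesign"))
    m <- scan@measurements
    sp <- design@spots
    ids <- sp$protein_id[match(.addr_key(m$block, m$row, m$col),
                               .addr_key(sp$block, sp$row, sp$col))]
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (dialect == "tsv") {
        cl <- scan@condition
        writeLines(c(paste0("# e1e2_level=", cl@e1e2Level),
                     paste0("# e3=", cl@e3),
                     paste0("# isoform=", cl@sumoIsoform),
                     paste0("# replicate=", scan@replicate),
                     paste(c("Block", "Row", "Column", "ID", "F", "B", "Flag"),
                           collapse = "\t"),
                     paste(m$block, m$row, m$col, ids,
                           format(m$foreground, digits = 15, trim = TRUE,
                                  scientific = FALSE),
                           format(m$background, digits = 15, trim = TRUE,
                                  scientific = FALSE),
                           m$flag, sep = "\t")),
                   con, sep = "\n")
    } else {
        flags <- ifelse(m$flag == "bad", -100L, 0L)
        sat <- ifelse(m$flag == "saturated", 100L, 0L)
        hdr <- c("ATF\t1.0", "2\t8",
                 '"Type=GenePix Results 3"', '"Wavelengths=532"')
        colrow <- paste(c('"Block"', '"Row"', '"Column"', '"ID"',
                          '"F532 Median"', '"B532 Median"', '"F532 % Sat."',
                          '"Flags"'), collapse = "\t")
        body <- paste(m$block, m$row, m$col, paste0('"', ids, '"'),
                      round(m$foreground), round(m$background), sat, flags,
                      sep = "\t")
        writeLines(c(hdr, colrow, body), con, sep = "\n")
    }
    invisible(path)
}

#' Validate a scan against a design
#'
#' Checks that every scanned address exists in the design and reports the
#' flagged-spot and coverage summary.
#'
#' @param scan an [ArrayScan-class].
#' @param design an [ArrayDesign-class].
#' @return Invisibly, a list with `n_spots`, `n_missing` (design addresses not
#'   scanned), `n_flagged`, `saturation_fraction`.
#' @export
validateScan <- function(scan, design) {
    stopifnot(is(scan, "ArrayScan"), is(design, "ArrayDesign"))
    m <- scan@measurements
    sp <- design@spots
    key <- .addr_key(m$block, m$row, m$col)
    known <- .addr_key(sp$block, sp$row, sp$col)
    bad <- setdiff(key, known)
    if (length(bad))
        stop("scan contains addresses absent from the design, e.g. ", bad[1])
    invisible(list(n_spots = nrow(m), n_missing = sum(!known %in% key),
                   n_flagged = sum(m$flag != "ok"),
                   saturation_fraction = mean(m$flag == "saturated")))
}

#' Replace non-official gene names in a hit table
#'
#' Every substrate name present in `mapping` (alias to official symbol) is
#' replaced by its official symbol; unmapped names pass through unchanged.
#' When two rows collapse onto one official symbol, the evidence is merged:
#' maximal replicate support and mean ratio, union of filter tags, and the
#' merge is logged. Applying the same mapping twice equals applying it once.
#'
#' @param table a [HitTable-class].
#' @param mapping named character vector, `names = aliases`,
#'   `values = official symbols`. May be partial or empty.
#' @return A [HitTable-class] with official symbols.
#' @export
mapGeneSymbols <- function(table, mapping) {
    stopifnot(is(table, "HitTable"))
    h <- table@hits
    if (length(mapping) == 0L || nrow(h) == 0L) return(table)
    stopifnot(!is.null(names(mapping)))
    hit <- h$substrate %in% names(mapping)
    unmapped <- setdiff(h$substrate, names(mapping))
    if (length(unmapped))
        .sa_log("unmapped names passed through: ",
                paste(unmapped, collapse = ", "))
    h$substrate[hit] <- unname(mapping[h$substrate[hit]])
    if (anyDuplicated(h$substrate)) {
        merged <- unique(h$substrate[duplicated(h$substrate)])
        .sa_log("merged aliases of: ", paste(merged, collapse = ", "))
        h <- do.call(rbind, lapply(split(h, h$substrate), function(g) {
            data.frame(substrate = g$substrate[1],
                       replicate_support = max(g$replicate_support),
                       mean_ratio = max(g$mean_ratio),
                       passed_negative_filter = any(g$passed_negative_filter),
                       e3_dependent = any(g$e3_dependent),
                       filters_passed = paste(sort(unique(unlist(
                           strsplit(g$filters_passed, ",", fixed = TRUE)))),
                           collapse = ","),
                       stringsAsFactors = FALSE)
        }))
    }
    h <- h[order(h$substrate), , drop = FALSE]
    rownames(h) <- NULL
    new("HitTable", condition = table@condition, hits = h)
}

#' Write hit tables to TSV
#'
#' Columns: `condition`, `substrate`, `n_replicates_supporting`,
#' `mean_normalized_ratio`, `filters_passed`; rows ordered by condition then
#' substrate. An empty input yields a header-only file.
#'
#' @param tables a [HitTable-class] or list of them.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeHitTable <- function(tables, path) {
    if (is(tables, "HitTable")) tables <- list(tables)
    stopifnot(all(vapply(tables, is, logical(1), "HitTable")))
    rows <- lapply(tables, function(t) {
        h <- t@hits
        if (!nrow(h)) return(NULL)
        data.frame(condition = conditionName(t@condition),
                   substrate = h$substrate,
                   n_replicates_supporting = h$replicate_support,
                   mean_normalized_ratio = h$mean_ratio,
                   filters_passed = h$filters_passed,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(condition = character(), substrate = character(),
                          n_replicates_supporting = integer(),
                          mean_normalized_ratio = numeric(),
                          filters_passed = character())
    out <- out[order(out$condition, out$substrate), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
    invisible(path)
}

#' Read hit tables written by [writeHitTable()]
#'
#' @param path a hit-table TSV.
#' @return A named list of [HitTable-class] objects (names are condition
#'   names), empty list for a header-only file.
#' @export
readHitTable <- function(path) {
    if (!file.exists(path)) stop("hit table not found: ", path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("condition", "substrate", "n_replicates_supporting",
              "mean_normalized_ratio", "filters_passed")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("hit table missing columns: ", paste(miss, collapse = ", "))
    if (!nrow(d)) return(list())
    out <- lapply(split(d, d$condition), function(g) {
        tags <- strsplit(g$filters_passed, ",", fixed = TRUE)
        h <- data.frame(substrate = g$substrate,
                        replicate_support = as.integer(g$n_replicates_supporting),
                        mean_ratio = as.numeric(g$mean_normalized_ratio),
                        passed_negative_filter =
                            vapply(tags, function(x) "negctrl" %in% x, logical(1)),
                        e3_dependent =
                            vapply(tags, function(x) "e3dep" %in% x, logical(1)),
                        filters_passed = g$filters_passed,
                        stringsAsFactors = FALSE)
        h <- h[order(h$substrate), , drop = FALSE]
        rownames(h) <- NULL
        new("HitTable", condition = parseConditionName(g$condition[1]),
            hits = h)
    })
    out[sort(names(out))]
}
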