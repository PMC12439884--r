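# Readers and writers for the external formats the pipeline touches:
# MatrixMarket count triplets with gene/barcode sidecars, SpaceRanger-style
# tissue-position CSVs (both dialects), affine-transform JSON, homology
# tables and BED intervals. Readers never reorder observations relative to
# file order, and every reader/writer pair round-trips.

POSITION_COLUMNS <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pxl_row_in_fullres", "pxl_col_in_fullres")

#' Read a 10x-style sparse count triplet
#'
#' Reads a MatrixMarket coordinate file together with plain-text gene and
#' barcode lists, returning a sparse genes x observations count matrix with
#' the gene identifiers as rownames and barcodes as colnames.
#'
#' @param matrixPath path to the MTX file.
#' @param genesPath path to a one-gene-per-line text file (a second
#'   tab-separated column, e.g. a gene symbol, is tolerated; the first
#'   column is used).
#' @param barcodesPath path to a one-barcode-per-line text file.
#' @return A \code{dgCMatrix} of non-negative integer counts.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
#'                           dims = c(3, 2))
#' writeCountsTriplet(m, file.path(dir, "m.mtx"), file.path(dir, "g.tsv"),
#'                    file.path(dir, "b.tsv"),
#'                    genes = paste0("g", 1:3), barcodes = paste0("b", 1:2))
#' counts <- readCountsTriplet(file.path(dir, "m.mtx"),
#'                             file.path(dir, "g.tsv"), file.path(dir, "b.tsv"))
#' sum(counts)
#' @export
readCountsTriplet <- function(matrixPath, genesPath, barcodesPath) {
    m <- Matrix::readMM(matrixPath)
    if (methods::is(m, "nMatrix"))   # pattern dialect (e.g. empty files)
        m <- methods::as(m, "dMatrix")
    genes <- utils::read.table(genesPath, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.table(barcodesPath, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes))
        stop(sprintf("format error: %s declares %d rows but %s lists %d genes",
                     matrixPath, nrow(m), genesPath, length(genes)))
    if (ncol(m) != length(barcodes))
        stop(sprintf(
            "format error: %s declares %d columns but %s lists %d barcodes",
            matrixPath, ncol(m), barcodesPath, length(barcodes)))
    if (any(m@x < 0))
        stop(sprintf("format error: negative counts in %s", matrixPath))
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(genes, barcodes)
    m
}

#' Write a sparse count matrix as an MTX triplet with sidecars
#'
#' @param counts sparse genes x observations matrix.
#' @param matrixPath,genesPath,barcodesPath output paths.
#' @param genes,barcodes identifier vectors; default to the dimnames.
#' @return Invisibly, the matrix path.
#' @export
writeCountsTriplet <- function(counts, matrixPath, genesPath, barcodesPath,
                               genes = rownames(counts),
                               barcodes = colnames(counts)) {
    if (is.null(genes) || is.null(barcodes))
        stop("gene and barcode identifiers are required")
    Matrix::writeMM(methods::as(counts, "CsparseMatrix"), matrixPath)
    writeLines(genes, genesPath)
    writeLines(barcodes, barcodesPath)
    invisible(matrixPath)
}

#' Read a SpaceRanger-style tissue-positions CSV
#'
#' Supports both dialects: the headerless \code{tissue_positions_list.csv}
#' and the headered \code{tissue_positions.csv}. Columns are barcode,
#' in_tissue, array_row, array_col, pxl_row_in_fullres, pxl_col_in_fullres.
#' Pixel coordinates follow the (row, col) = (y, x) convention of the
#' source files.
#'
#' @param path CSV path.
#' @param dialect \code{"headered"}, \code{"headerless"} or \code{"auto"}
#'   (sniff the first line).
#' @param validateNative when TRUE, enforce the native capture-area bounds
#'   array_row in [0, 77] and array_col in [0, 127]; stitched grids exceed
#'   these and must be read with the default FALSE.
#' @return data.frame of spot position records, in file order.
#' @details Native arrays carry a parity convention (array_row + array_col
#'   even); a violation raises a warning rather than an error because
#'   stitched artificial grids may adopt either parity.
#' @export
readSpotPositions <- function(path, dialect = c("auto", "headered",
                                                "headerless"),
                              validateNative = FALSE) {
    dialect <- match.arg(dialect)
    if (dialect == "auto") {
        first <- readLines(path, n = 1L)
        dialect <- if (grepl("barcode", first, fixed = TRUE))
            "headered" else "headerless"
    }
    df <- utils::read.csv(path, header = dialect == "headered",
                          stringsAsFactors = FALSE)
    if (ncol(df) != 6L)
        stop(sprintf("format error: %s has %d columns, expected 6",
                     path, ncol(df)))
    names(df) <- POSITION_COLUMNS
    dup <- df$barcode[duplicated(df$barcode)]
    if (length(dup))
        stop(sprintf("duplicate barcode(s) in %s: %s", path,
                     paste(unique(dup), collapse = ", ")))
    if (validateNative) {
        bad <- which(df$array_row < 0 | df$array_row > 77 |
                     df$array_col < 0 | df$array_col > 127)
        if (length(bad))
            stop(sprintf(
                "native array bounds violated (array_row in [0,77], array_col in [0,127]) at row(s): %s",
                paste(bad, collapse = ", ")))
    }
    if (any((df$array_row + df$array_col) %% 2 != 0))
        warning("array_row + array_col parity is not even for all spots; ",
                "expected for native capture areas, possible for stitched grids")
    df
}

#' Write a tissue-positions CSV
#'
#' @param positions data.frame with the six position columns.
#' @param path output path.
#' @param dialect whether to write a header line.
#' @return Invisibly, the path.
#' @export
writeSpotPositions <- function(positions, path,
                               dialect = c("headerless", "headered")) {
    dialect <- match.arg(dialect)
    stopifnot(all(POSITION_COLUMNS %in% names(positions)))
    utils::write.table(positions[, POSITION_COLUMNS], path, sep = ",",
                       row.names = FALSE, col.names = dialect == "headered",
                       quote = FALSE)
    invisible(path)
}

#' Read ImageJ-style affine transforms from JSON
#'
#' The file is a JSON object keyed by capture-area id, each value a 2x3
#' affine matrix (rotation/scale block plus translation column, pixel
#' units) stored as a list of two rows.
#'
#' @param path JSON path.
#' @param areas optional character vector of capture-area ids that must be
#'   covered; with \code{allowMissing = TRUE} identity transforms are
#'   inserted for areas absent from the file.
#' @param allowMissing insert identities for missing areas instead of
#'   erroring.
#' @return Named list of 2x3 numeric matrices.
#' @export
readAffineJson <- function(path, areas = NULL, allowMissing = FALSE) {
    raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    out <- lapply(raw, function(m) {
        m <- matrix(as.numeric(unlist(m)), nrow = 2, byrow = is.list(m))
        if (!all(dim(m) == c(2, 3)))
            stop(sprintf("affine matrix in %s is not 2x3", path))
        det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
        if (abs(det) < 1e-12)
            stop(sprintf("non-invertible rotation block in %s (det = %g)",
                         path, det))
        m
    })
    if (!is.null(areas)) {
        missing <- setdiff(areas, names(out))
        if (length(missing) && !allowMissing)
            stop(sprintf("no transform for capture area(s): %s",
                         paste(missing, collapse = ", ")))
        for (a in missing)
            out[[a]] <- cbind(diag(2), c(0, 0))
        out <- out[areas]
    }
    out
}

#' Apply a 2x3 affine matrix to (x, y) points
#'
#' @param affine 2x3 matrix.
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyAffine <- function(affine, points) {
    points <- rbind2cols(points)
    t(affine[, 1:2] %*% t(points) + affine[, 3])
}

rbind2cols <- function(points) {
    points <- as.matrix(points)
    if (ncol(points) != 2)
        stop("points must be an n x 2 matrix")
    storage.mode(points) <- "double"
    points
}

#' Read a homology table and extract one-to-one pairs
#'
#' Parses an MGI \code{HOM_AllOrganism.rpt}-like tab-separated table with a
#' homology-group key, an organism column and a symbol column. Symbols of
#' the two requested taxa are joined within homology group, then filtered
#' to unique one-to-one matches: any source or target symbol appearing in
#' more than one pair removes all pairs it touches.
#'
#' @param path TSV path.
#' @param sourceTaxon,targetTaxon values of the organism column to join.
#' @param keyColumn,taxonColumn,symbolColumn column names in the file.
#' @return data.frame with columns \code{source_symbol},
#'   \code{target_symbol}, \code{source_taxon}, \code{target_taxon}.
#' @export
readHomologTable <- function(path, sourceTaxon, targetTaxon,
                             keyColumn = "DB Class Key",
                             taxonColumn = "Common Organism Name",
                             symbolColumn = "Symbol") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c(keyColumn, taxonColumn, symbolColumn)
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("format error: %s lacks column(s): %s", path,
                     paste(miss, collapse = ", ")))
    src <- df[df[[taxonColumn]] == sourceTaxon, c(keyColumn, symbolColumn)]
    tgt <- df[df[[taxonColumn]] == targetTaxon, c(keyColumn, symbolColumn)]
    pairs <- merge(src, tgt, by = keyColumn, suffixes = c(".src", ".tgt"))
    names(pairs) <- c("key", "source_symbol", "target_symbol")
    keep <- !(pairs$source_symbol %in%
                  pairs$source_symbol[duplicated(pairs$source_symbol)]) &
            !(pairs$target_symbol %in%
                  pairs$target_symbol[duplicated(pairs$target_symbol)])
    pairs <- pairs[keep, , drop = FALSE]
    data.frame(source_symbol = pairs$source_symbol,
               target_symbol = pairs$target_symbol,
               source_taxon = sourceTaxon, target_taxon = targetTaxon,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Write BED intervals
#'
#' Writes 0-based half-open intervals as tab-separated
#' chrom/start/end/name, sorted by (chrom, start). Clipping negative
#' starts is the caller's responsibility; they are rejected here.
#'
#' @param intervals data.frame with columns chrom, start, end, name.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeBed <- function(intervals, path) {
    stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
    if (nrow(intervals)) {
        if (any(intervals$start < 0))
            stop("negative start coordinate; clip before writing")
        if (any(intervals$end <= intervals$start))
            stop("intervals must satisfy start < end (0-based half-open)")
        intervals <- intervals[order(intervals$chrom, intervals$start), ]
    }
    utils::write.table(intervals[, c("chrom", "start", "end", "name")], path,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read a BED file written by \code{writeBed}
#' @param path BED path.
#' @return data.frame with chrom/start/end/name, 0-based half-open.
#' @export
readBed <- function(path) {
    if (file.size(path) == 0)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character()))
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
    df
}
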