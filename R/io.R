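#' Read an abundance matrix from delimited text
#'
#' Reads a CSV/TSV file with one header row of ids and one leading id column
#' into the package's internal samples x proteins orientation. Cells matching
#' one of `naTokens` (or empty cells) become missing; any other non-numeric
#' cell is a parse error naming the offending row and column. In intensity
#' space every observed value must be strictly positive.
#'
#' @param path file path; the delimiter defaults to `","` for `.csv` and tab
#'   otherwise, overridable via `sep`.
#' @param orientation orientation of the file: `"samples_by_proteins"` (rows
#'   are samples) or `"proteins_by_samples"` (rows are proteins; the matrix is
#'   transposed on read).
#' @param naTokens character vector of missing-value tokens.
#' @param sep optional delimiter override.
#' @param space `"intensity"` (default) or `"log2"`.
#' @return an [AbundanceMatrix-class] in samples x proteins orientation.
#' @seealso [writeMatrix()], [readScores()]
#' @export
readMatrix <- function(path,
                       orientation = c("samples_by_proteins", "proteins_by_samples"),
                       naTokens = c("NA", "NaN", ""), sep = NULL,
                       space = "intensity") {
  orientation <- match.arg(orientation)
  grid <- .readGrid(path, naTokens, sep)
  if (orientation == "proteins_by_samples") grid <- t(grid)
  if (anyDuplicated(rownames(grid)))
    stop("duplicate sample ids in ", path, call. = FALSE)
  if (anyDuplicated(colnames(grid)))
    stop("duplicate protein ids in ", path, call. = FALSE)
  if (identical(space, "intensity")) {
    bad <- which(!is.na(grid) & grid <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("nonpositive intensity at row '%s', column '%s' in %s",
                   rownames(grid)[bad[1, 1]], colnames(grid)[bad[1, 2]], path),
           call. = FALSE)
  }
  AbundanceMatrix(grid, space = space)
}

# shared delimited-grid reader: header row of ids + first id column; returns a
# numeric matrix with NA where a token matched
.readGrid <- function(path, naTokens, sep = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  ids <- rownames(raw)
  cols <- colnames(raw)
  grid <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- trimws(raw[[j]])
    isNA <- cell %in% naTokens | cell == ""
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!isNA & is.na(val))
    if (length(bad))
      stop(sprintf("cannot parse cell at row '%s', column '%s' in %s: '%s'",
                   ids[bad[1]], cols[j], path, cell[bad[1]]), call. = FALSE)
    val[isNA] <- NA_real_
    grid[, j] <- val
  }
  grid
}

#' Write an abundance matrix to delimited text
#'
#' Values are printed with 17 significant digits so that
#' `readMatrix(writeMatrix(x))` reproduces `x` bit-exactly; missing entries
#' are rendered as `naToken`.
#'
#' @param x an [AbundanceMatrix-class].
#' @param path output file path (delimiter from extension, see [readMatrix()]).
#' @param orientation file orientation, as in [readMatrix()].
#' @param naToken string used for missing cells (default `"NA"`).
#' @param sep optional delimiter override.
#' @return `invisible(path)`.
#' @export
writeMatrix <- function(x, path,
                        orientation = c("samples_by_proteins", "proteins_by_samples"),
                        naToken = "NA", sep = NULL) {
  .assertAbundanceMatrix(x, "x")
  orientation <- match.arg(orientation)
  v <- x@values
  if (orientation == "proteins_by_samples") v <- t(v)
  .writeGrid(v, path, naToken, sep)
  invisible(path)
}

.writeGrid <- function(v, path, naToken = "NA", sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  chr <- matrix(sprintf("%.17g", v), nrow(v), ncol(v))
  chr[is.na(v)] <- naToken
  lines <- c(paste(c("id", colnames(v)), collapse = sep),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], chr[i, ]), collapse = sep), character(1)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  ok <- try(writeLines(lines, con), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write '", path, "'", call. = FALSE)
}

#' Read a complete per-sample score table
#'
#' Like [readMatrix()] (samples in rows, score columns) but missing entries
#' are an error: external score tables must be complete.
#'
#' @inheritParams readMatrix
#' @return an [ExternalScores-class] object.
#' @export
readScores <- function(path, naTokens = c("NA", "NaN", ""), sep = NULL) {
  grid <- .readGrid(path, naTokens, sep)
  if (anyNA(grid))
    stop("scores must be complete: missing entries in ", path, call. = FALSE)
  if (anyDuplicated(rownames(grid)))
    stop("duplicate sample ids in ", path, call. = FALSE)
  ExternalScores(grid)
}

#' Align external scores to an abundance matrix
#'
#' @param scores an [ExternalScores-class].
#' @param x the target [AbundanceMatrix-class].
#' @return the scores reordered to the sample order of `x`; an error if the
#'   id sets differ.
#' @export
alignScores <- function(scores, x) {
  idx <- match(sampleIds(x), rownames(scores@scores))
  if (anyNA(idx))
    stop("sample ids of the score table do not match the abundance matrix",
         call. = FALSE)
  ExternalScores(scores@scores[idx, , drop = FALSE])
}

#' Serialize / read a GroundTruth table
#'
#' CSV with columns `sample_id, protein_id, true_value, space`.
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @return `writeGroundTruth` returns `invisible(path)`; `readGroundTruth`
#'   returns a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  df <- data.frame(sample_id = truth@sampleIds, protein_id = truth@proteinIds,
                   true_value = sprintf("%.17g", truth@values),
                   space = truth@space)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "character", "character"))
  GroundTruth(df$sample_id, df$protein_id, as.numeric(df$true_value),
              df$space[1])
}
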