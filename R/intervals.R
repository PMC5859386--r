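#' Stranded genomic intervals
#'
#' The universal coordinate currency of the package: a data frame with
#' columns `chrom`, `start`, `end`, `name`, `score`, `strand`, using the BED
#' convention (0-based, half-open `[start, end)`).  `strand` is one of
#' `"+"`, `"-"` or `"."` (unstranded).
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param name feature labels (recycled; default `"."`).
#' @param score non-negative numeric scores (recycled; default 0).
#' @param strand `"+"`, `"-"` or `"."` (recycled; default `"."`).
#' @return A validated `data.frame` of intervals.
#' @examples
#' intervals("chr1", c(100, 400), c(200, 500), strand = c("+", "-"))
#' @export
intervals <- function(chrom, start, end, name = ".", score = 0, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(
    chrom  = rep_len(as.character(chrom), n),
    start  = rep_len(as.integer(start), n),
    end    = rep_len(as.integer(end), n),
    name   = rep_len(as.character(name), n),
    score  = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
}

#' Validate an interval data frame
#'
#' Checks the interval invariants: required columns, `0 <= start < end`,
#' non-negative scores, and `strand` restricted to `+`, `-`, `.`.
#'
#' @param x a data frame with at least `chrom`, `start`, `end` columns;
#'   missing `name`/`score`/`strand` columns are filled with defaults.
#' @return `x`, with all six columns, invisibly valid.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop("interval data frame requires columns: ", paste(need, collapse = ", "))
  if (is.null(x$name))   x$name   <- "."
  if (is.null(x$score))  x$score  <- 0
  if (is.null(x$strand)) x$strand <- "."
  x$start <- as.integer(x$start)
  x$end   <- as.integer(x$end)
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("non-integer interval coordinates")
  bad <- which(x$start < 0L | x$start >= x$end)
  if (length(bad))
    stop(sprintf("invalid interval at row %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], x$start[bad[1]], x$end[bad[1]]))
  if (any(!x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (any(x$score < 0)) stop("interval scores must be >= 0")
  x
}

#' Read intervals from a BED3-BED6 file
#'
#' Parses whitespace/tab-delimited interval records with 3-6 columns.
#' Missing strand becomes `"."`; file order is preserved.  Malformed lines
#' raise an error naming the offending line number.
#'
#' @param path path to an existing BED-like file.
#' @return interval data frame (see [intervals()]).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track\\b|browser\\b)", trimws(lines)))
  if (!length(keep)) {
    return(intervals(character(0), integer(0), integer(0))[0, ])
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3L | nf > 6L)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected 3-6 fields, found %d",
                 keep[bad[1]], nf[bad[1]]))
  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.integer(col(2, NA)))
  end   <- suppressWarnings(as.integer(col(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-integer coordinates", keep[bad[1]]))
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop(sprintf("validation error at line %d: start=%d end=%d (need 0 <= start < end)",
                 keep[bad[1]], start[bad[1]], end[bad[1]]))
  score <- suppressWarnings(as.numeric(col(5, "0")))
  score[is.na(score)] <- 0
  strand <- col(6, ".")
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad))
    stop(sprintf("validation error at line %d: strand '%s'", keep[bad[1]], strand[bad[1]]))
  intervals(col(1, NA), start, end, name = col(4, "."), score = score,
            strand = strand)
}

#' Write intervals as BED6
#'
#' Round-trips losslessly with [read_intervals()] on all six fields.
#'
#' @param x interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  x <- validate_intervals(x)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   x$chrom, x$start, x$end, x$name,
                   vapply(x$score, format, character(1), digits = 15),
                   x$strand)
  writeLines(lines, path)
  invisible(path)
}
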