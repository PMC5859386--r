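#' Reverse complement of DNA sequences
#'
#' Alphabet is restricted to `A`, `C`, `G`, `T`, `N`.  Vectorised; an
#' involution (`reverse_complement(reverse_complement(s)) == s`).
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")   # palindrome
#' reverse_complement("AAAC")   # "GTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (any(grepl("[^ACGTN]", seq)))
    stop("invalid character in DNA sequence (alphabet is A,C,G,T,N)")
  if (!length(seq)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's single sequence
#' container (`DNAStringSet`) explicit at the module boundary.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @param x named `DNAStringSet` or named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Per-base coverage track
#'
#' One vector of non-negative per-base values for one chromosome, plus its
#' normalization state (`"raw"` or `"per-1M-reads"`).
#'
#' @param chrom chromosome name.
#' @param values numeric vector, one value per base, all `>= 0`.
#' @param normalization `"raw"` or `"per-1M-reads"`.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, values, normalization = "raw") {
  stopifnot(is.character(chrom), length(chrom) == 1L, is.numeric(values))
  if (any(values < 0)) stop("coverage values must be >= 0")
  normalization <- match.arg(normalization, c("raw", "per-1M-reads"))
  structure(list(chrom = chrom, values = as.numeric(values),
                 normalization = normalization),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bp, mean %.3f (%s)\n",
              x$chrom, length(x$values), mean(x$values), x$normalization))
  invisible(x)
}

#' Rescale a raw track to signal per 1M reads
#'
#' @param track a [coverage_track()].
#' @param total_reads the library size the track was built from.
#' @return a `coverage_track` with normalization `"per-1M-reads"`.
#' @export
normalize_per_million <- function(track, total_reads) {
  stopifnot(inherits(track, "coverage_track"), total_reads > 0)
  coverage_track(track$chrom, track$values * 1e6 / total_reads,
                 normalization = "per-1M-reads")
}

#' Write / read a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed into bedGraph records (0-based,
#' half-open).  `read_bedgraph` needs the chromosome length to restore the
#' dense per-base vector (absent records are zero).
#'
#' @param track a [coverage_track()].
#' @param path file path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, starts[keep], ends[keep],
                     vapply(r$values[keep], format, character(1), digits = 10)),
             path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param chrom_length length of the chromosome in bp.
#' @param normalization normalization tag to attach to the restored track.
#' @export
read_bedgraph <- function(path, chrom_length, normalization = "raw") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty bedGraph: ", path)
  f <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(f) != 4L)) stop("malformed bedGraph record in ", path)
  chrom <- unique(vapply(f, `[`, character(1), 1))
  if (length(chrom) != 1L) stop("read_bedgraph handles one chromosome per file")
  v <- numeric(chrom_length)
  for (rec in f) {
    s <- as.integer(rec[2]); e <- as.integer(rec[3])
    if (is.na(s) || is.na(e) || s < 0 || e > chrom_length || s >= e)
      stop("bedGraph record out of bounds in ", path)
    v[(s + 1L):e] <- as.numeric(rec[4])
  }
  coverage_track(chrom, v, normalization)
}
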