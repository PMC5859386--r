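# Motif matrices, the motif-library text dialect, consensus conversion and
# log-odds scanning.  Scores are in bits against a uniform 0.25 background;
# `N` in a scanned sequence contributes 0 bits (background).

BASES <- c("A", "C", "G", "T")

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a motif matrix
#'
#' A position probability matrix with a log-odds detection threshold in bits
#' (uniform 0.25 background).  Rows must sum to 1 and be strictly positive:
#' a zero probability would give a -Inf log-odds, so zeros are rejected
#' rather than silently pseudocounted.
#'
#' @param name motif identifier.
#' @param probs L x 4 numeric matrix of base probabilities, columns A,C,G,T.
#' @param log_odds_threshold minimal detection score in bits; must not
#'   exceed the maximal achievable score of the matrix.
#' @param source provenance tag: `"database"`, `"discovered"` or
#'   `"converted-consensus"`.
#' @param tol tolerance on row sums (rows are renormalized after the check).
#' @return object of class `motif_matrix`.
#' @export
motif_matrix <- function(name, probs, log_odds_threshold,
                         source = c("database", "discovered", "converted-consensus"),
                         tol = 1e-6) {
  source <- match.arg(source)
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("motif matrix must have 4 columns (A,C,G,T)")
  colnames(probs) <- BASES
  if (any(probs <= 0))
    stop("motif '", name, "': zero (or negative) probability; apply a pseudocount upstream")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("motif '%s': row %d sums to %.6f (must be 1 within %g)",
                 name, which(abs(rs - 1) > tol)[1], rs[abs(rs - 1) > tol][1], tol))
  probs <- probs / rs
  m <- structure(list(name = as.character(name), probs = probs,
                      log_odds_threshold = as.numeric(log_odds_threshold),
                      source = source),
                 class = "motif_matrix")
  if (m$log_odds_threshold > motif_max_score(m) + 1e-9)
    stop("motif '", name, "': threshold exceeds maximal achievable score")
  m
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %s (%s): %d bp, threshold %.2f bits (max %.2f)\n",
              x$name, x$source, nrow(x$probs), x$log_odds_threshold,
              motif_max_score(x)))
  invisible(x)
}

#' Log-odds matrix (bits) of a motif
#' @param m a [motif_matrix()].
#' @return L x 4 matrix of `log2(p / 0.25)`.
#' @export
motif_log_odds <- function(m) log2(m$probs / 0.25)

#' Maximal achievable log-odds score of a motif
#' @param m a [motif_matrix()].
#' @return score in bits.
#' @export
motif_max_score <- function(m) sum(apply(motif_log_odds(m), 1, max))

#' Majority consensus string of a motif (first-max tie break)
#' @param m a [motif_matrix()].
#' @return character scalar over A,C,G,T.
#' @export
motif_consensus <- function(m) {
  paste(BASES[apply(m$probs, 1, which.max)], collapse = "")
}

#' Convert an IUPAC consensus to a motif matrix
#'
#' Allowed bases at each position share probability mass 0.997 (split
#' equally across degenerate codes); disallowed bases share 0.003.  The
#' detection threshold is placed midway between the worst score attainable
#' with `mismatches_allowed` mismatches and the best score attainable with
#' one more, so that sequences within the mismatch budget score above the
#' threshold and all others below it.
#'
#' @param consensus IUPAC string.
#' @param mismatches_allowed maximum number of mismatching positions that
#'   must still be detected (default 0).
#' @param name motif name (default: the consensus).
#' @param source provenance tag, default `"converted-consensus"`.
#' @return a [motif_matrix()].
#' @export
consensus_to_matrix <- function(consensus, mismatches_allowed = 0L,
                                name = consensus,
                                source = "converted-consensus") {
  stopifnot(is.character(consensus), length(consensus) == 1L, nchar(consensus) > 0)
  stopifnot(mismatches_allowed >= 0L)
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (any(!chars %in% names(IUPAC)))
    stop("invalid IUPAC character: ", chars[!chars %in% names(IUPAC)][1])
  L <- length(chars)
  probs <- matrix(0, L, 4, dimnames = list(NULL, BASES))
  match_s <- mismatch_s <- numeric(L)      # per-position log-odds scores
  mismatchable <- logical(L)
  for (i in seq_len(L)) {
    allowed <- IUPAC[[chars[i]]]
    k <- length(allowed)
    if (k == 4L) {
      probs[i, ] <- 0.25
      match_s[i] <- 0
      mismatchable[i] <- FALSE
    } else {
      probs[i, allowed] <- 0.997 / k
      probs[i, setdiff(BASES, allowed)] <- 0.003 / (4 - k)
      match_s[i] <- log2((0.997 / k) / 0.25)
      mismatch_s[i] <- log2((0.003 / (4 - k)) / 0.25)
      mismatchable[i] <- TRUE
    }
  }
  max_score <- sum(match_s)
  drop <- (match_s - mismatch_s)[mismatchable]      # cost of mismatching position i
  m <- min(mismatches_allowed, length(drop))
  if (m >= length(drop)) {
    # every sequence is within the mismatch budget: accept everything
    threshold <- max_score - sum(drop)
  } else {
    worst_ok  <- max_score - sum(sort(drop, decreasing = TRUE)[seq_len(m)])
    best_bad  <- max_score - sum(sort(drop)[seq_len(m + 1L)])
    if (worst_ok <= best_bad)
      stop("consensus '", consensus, "': additive scoring cannot separate ",
           m, " from ", m + 1L, " mismatches")
    threshold <- (worst_ok + best_bad) / 2
  }
  motif_matrix(name, probs, threshold, source = source)
}

#' Read a motif library
#'
#' Text dialect (HOMER-flavoured), one block per motif:
#' ```
#' >CONSENSUS<TAB>name<TAB>log_odds_threshold[<TAB>source]
#' pA<TAB>pC<TAB>pG<TAB>pT        (one row per motif position)
#' ```
#' Probabilities must be strictly positive and rows must sum to 1 within
#' 1e-6 (zero probabilities are rejected with a pseudocount suggestion).
#' Motif order is preserved.
#'
#' @param path motif library file.
#' @return list of [motif_matrix()] objects.
#' @export
read_motif_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no motif headers ('>') found in ", path)
  bounds <- c(heads, length(lines) + 1L)
  lib <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    hf <- strsplit(sub("^>", "", lines[heads[i]]), "[ \t]+")[[1]]
    if (length(hf) < 3L)
      stop("motif header needs at least consensus, name, threshold: ",
           lines[heads[i]])
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    if (!length(body)) stop("motif '", hf[2], "' has no probability rows")
    rows <- lapply(strsplit(body, "[ \t]+"), as.numeric)
    if (any(lengths(rows) != 4L) || any(vapply(rows, anyNA, logical(1))))
      stop("motif '", hf[2], "': each row must hold 4 numeric probabilities")
    probs <- do.call(rbind, rows)
    if (any(probs <= 0))
      stop("motif '", hf[2], "': zero probability not allowed ",
           "(apply a pseudocount before writing the library)")
    rs <- rowSums(probs)
    if (any(abs(rs - 1) > 1e-6))
      stop(sprintf("motif '%s': row %d sums to %.6f, not 1 (tolerance 1e-6)",
                   hf[2], which(abs(rs - 1) > 1e-6)[1], rs[abs(rs - 1) > 1e-6][1]))
    src <- if (length(hf) >= 4L) hf[4] else "database"
    lib[[i]] <- motif_matrix(hf[2], probs, as.numeric(hf[3]), source = src)
  }
  lib
}

#' Write a motif library
#' @param lib list of [motif_matrix()] objects.
#' @param path output path.
#' @export
write_motif_library <- function(lib, path) {
  stopifnot(is.list(lib), all(vapply(lib, inherits, logical(1), "motif_matrix")))
  out <- character(0)
  for (m in lib) {
    out <- c(out,
             sprintf(">%s\t%s\t%.6f\t%s", motif_consensus(m), m$name,
                     m$log_odds_threshold, m$source),
             apply(m$probs, 1, function(r) paste(sprintf("%.6f", r), collapse = "\t")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Default CTCF-like motif library (synthetic)
#'
#' A nine-entry library mirroring the field's usual design for CTCF
#' orientation calling: five consensus-derived entries (converted with a
#' 0-mismatch budget, tagged `database`) and four profile-style entries
#' (dominant base 0.85, threshold at 80% of the maximal score, tagged
#' `discovered`).  The motifs are synthetic CTCF-like 15-16-mers built
#' around the C-rich core of the canonical CTCF binding site; they are
#' non-palindromic, so a planted site is detected on one strand only.
#' The same library ships as plain text in
#' `inst/extdata/ctcf_like_library.motifs`.
#'
#' @return list of 9 [motif_matrix()] objects.
#' @export
default_ctcf_library <- function() {
  db <- c(ctcf_db1 = "CCACCAGGGGGCGCT",
          ctcf_db2 = "CCACTAGGTGGCAGA",
          ctcf_db3 = "TCCACCAGATGGCGC",
          ctcf_db4 = "CCGCCAGGGGGAGCT",
          ctcf_db5 = "ACCACCAGGGGGCAC")
  disc <- c(ctcf_disc1 = "CCACCTGGTGGCAGT",
            ctcf_disc2 = "GCCACCAGGGGGAGCA",
            ctcf_disc3 = "CCAGCAGGGGGCACTT",
            ctcf_disc4 = "TCCGCCAGCTGGCGCA")
  lib <- lapply(names(db), function(nm)
    consensus_to_matrix(db[[nm]], 0L, name = nm, source = "database"))
  lib2 <- lapply(names(disc), function(nm) {
    chars <- strsplit(disc[[nm]], "")[[1]]
    probs <- matrix(0.05, length(chars), 4, dimnames = list(NULL, BASES))
    probs[cbind(seq_along(chars), match(chars, BASES))] <- 0.85
    motif_matrix(nm, probs, 0.8 * nrow(probs) * log2(0.85 / 0.25),
                 source = "discovered")
  })
  c(lib, lib2)
}

# integer codes 1..4 for A,C,G,T; NA for N
.seq_codes <- function(seq) match(strsplit(seq, "")[[1]], BASES)

# log-odds score of `motif` at every offset of a coded sequence
.scan_codes <- function(codes, lo) {
  L <- nrow(lo)
  n <- length(codes) - L + 1L
  if (n <= 0L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    v <- lo[j, ][codes[j:(j + n - 1L)]]
    v[is.na(v)] <- 0            # N scores as background
    s <- s + v
  }
  s
}

#' Scan a sequence against a motif library on both strands
#'
#' Every offset x motif x strand whose log-odds score reaches the motif's
#' threshold is reported.  Minus-strand hits are scored on the reverse
#' complement and reported in the coordinates of the input sequence
#' (0-based, half-open).  A sequence shorter than every motif yields an
#' empty hit table.
#'
#' @param seq character scalar over A,C,G,T,N.
#' @param library list of [motif_matrix()] (or a single motif).
#' @return data frame with columns `motif`, `start`, `end`, `strand`,
#'   `score`.
#' @export
scan_sequence <- function(seq, library) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) stop("invalid character in sequence")
  if (inherits(library, "motif_matrix")) library <- list(library)
  fwd <- .seq_codes(seq)
  rcc <- .seq_codes(reverse_complement(seq))
  n <- length(fwd)
  out <- list()
  for (m in library) {
    lo <- motif_log_odds(m)
    L <- nrow(lo)
    sf <- .scan_codes(fwd, lo)
    hit <- which(sf >= m$log_odds_threshold)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        motif = m$name, start = hit - 1L, end = hit - 1L + L,
        strand = "+", score = sf[hit], stringsAsFactors = FALSE)
    sr <- .scan_codes(rcc, lo)
    hit <- which(sr >= m$log_odds_threshold)
    if (length(hit)) {
      # offset i (1-based) on the reverse complement covers forward
      # positions [n - i + 1 - L, n - i + 1) in 0-based half-open terms
      start0 <- n - (hit - 1L) - L
      out[[length(out) + 1L]] <- data.frame(
        motif = m$name, start = start0, end = start0 + L,
        strand = "-", score = sr[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$motif, res$strand), , drop = FALSE]
}
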