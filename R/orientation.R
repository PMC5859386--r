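# The four-step CTCF orientation procedure: scan each confident peak
# against the motif library on both strands, give every (collapsed) motif
# instance one vote by its strand, take the consensus sign, discard
# ambiguous peaks from the stranded output.

#' Scan peaks against a motif library
#'
#' Extracts each peak's sequence from the genome and reports every motif
#' hit (both strands) in genome coordinates.  Peaks shorter than every
#' motif simply yield no hits.
#'
#' @param peaks peak (or any interval) data frame.
#' @param genome named `DNAStringSet`.
#' @param library motif library (list of [motif_matrix()]).
#' @return data frame of hits: `peak`, `motif`, `start`, `end`, `strand`,
#'   `score` (genome coordinates).
#' @export
scan_peaks <- function(peaks, genome, library) {
  peaks <- validate_intervals(peaks)
  out <- list()
  glen <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(nrow(peaks))) {
    ch <- peaks$chrom[i]
    if (!ch %in% names(genome)) stop("peak on unknown chromosome: ", ch)
    if (peaks$end[i] > glen[[ch]]) stop("peak outside genome bounds")
    seq <- as.character(Biostrings::subseq(genome[[ch]], peaks$start[i] + 1L,
                                           peaks$end[i]))
    h <- scan_sequence(seq, library)
    if (nrow(h)) {
      h$start <- h$start + peaks$start[i]
      h$end <- h$end + peaks$start[i]
      h <- cbind(peak = peaks$name[i], h, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(peak = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# collapse overlapping hits of the same motif on the same strand to the
# best-scoring instance: one physical site, one vote
.collapse_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  out <- list()
  for (key in unique(paste(hits$motif, hits$strand))) {
    h <- hits[paste(hits$motif, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- integer(nrow(h)); g <- 1L; grp[1] <- 1L
    if (nrow(h) > 1L) {
      cur_end <- h$end[1]
      for (i in 2:nrow(h)) {
        if (h$start[i] < cur_end) {
          grp[i] <- g
          cur_end <- max(cur_end, h$end[i])
        } else {
          g <- g + 1L; grp[i] <- g; cur_end <- h$end[i]
        }
      }
    }
    for (gg in unique(grp)) {
      sub <- h[grp == gg, , drop = FALSE]
      out[[length(out) + 1L]] <- sub[which.max(sub$score), , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif), , drop = FALSE]
}

#' Consensus-sign orientation from motif hits
#'
#' Each (collapsed) hit votes with its strand.  A strict majority of
#' signs gives `forward` (+) or `reverse` (-); a tie with at least one
#' hit is `ambiguous`; no hits is `no_motif`.
#'
#' With `mode = "per_motif_best"` each motif model contributes one vote —
#' the strand of its best-scoring hit (a motif whose best forward and
#' reverse scores tie abstains) — instead of one vote per instance.
#'
#' @param hits hit data frame for one peak (from [scan_peaks()]).
#' @param mode `"per_instance"` (default) or `"per_motif_best"`.
#' @return list with `call` (one of `forward`, `reverse`, `ambiguous`,
#'   `no_motif`), `votes` (named counts `plus`, `minus`) and `hits` (the
#'   collapsed hits that voted).
#' @export
assign_orientation <- function(hits, mode = c("per_instance", "per_motif_best")) {
  mode <- match.arg(mode)
  h <- .collapse_hits(hits)
  if (!nrow(h))
    return(list(call = "no_motif", votes = c(plus = 0L, minus = 0L), hits = h))
  if (mode == "per_instance") {
    plus <- sum(h$strand == "+")
    minus <- sum(h$strand == "-")
  } else {
    plus <- minus <- 0L
    for (m in unique(h$motif)) {
      hm <- h[h$motif == m, , drop = FALSE]
      bp <- suppressWarnings(max(hm$score[hm$strand == "+"], -Inf))
      bm <- suppressWarnings(max(hm$score[hm$strand == "-"], -Inf))
      if (bp > bm) plus <- plus + 1L
      else if (bm > bp) minus <- minus + 1L
      # equal best scores on both strands: the motif abstains
    }
    if (plus + minus == 0L)
      return(list(call = "ambiguous", votes = c(plus = 0L, minus = 0L), hits = h))
  }
  call <- if (plus > minus) "forward"
          else if (minus > plus) "reverse"
          else "ambiguous"
  list(call = call, votes = c(plus = as.integer(plus), minus = as.integer(minus)),
       hits = h)
}

#' Orient a peak set
#'
#' Runs [scan_peaks()] and [assign_orientation()] over every peak and
#' assembles (i) the full report with calls and vote counts for all
#' peaks and (ii) the stranded interval set holding only the
#' unambiguous calls (`forward` -> `+`, `reverse` -> `-`); ambiguous and
#' motif-less peaks are discarded from the stranded set but retained in
#' the report.
#'
#' @param peaks peak data frame.
#' @param genome named `DNAStringSet`.
#' @param library motif library.
#' @param mode voting mode (see [assign_orientation()]).
#' @return list with `peaks` (report: peaks + `call`, `votes_plus`,
#'   `votes_minus`, `strand` updated for oriented calls), `stranded`
#'   (interval data frame, never strand `"."`), `hits` (all collapsed
#'   hits) and `counts` (named vector over the four call classes).
#' @export
orient_peak_set <- function(peaks, genome, library,
                            mode = c("per_instance", "per_motif_best")) {
  mode <- match.arg(mode)
  peaks <- validate_intervals(peaks)
  hits_all <- scan_peaks(peaks, genome, library)
  calls <- character(nrow(peaks))
  vp <- vm <- integer(nrow(peaks))
  kept_hits <- list()
  for (i in seq_len(nrow(peaks))) {
    h <- hits_all[hits_all$peak == peaks$name[i], , drop = FALSE]
    a <- assign_orientation(h, mode = mode)
    calls[i] <- a$call
    vp[i] <- a$votes[["plus"]]; vm[i] <- a$votes[["minus"]]
    if (nrow(a$hits)) kept_hits[[length(kept_hits) + 1L]] <- a$hits
  }
  report <- peaks
  report$call <- calls
  report$votes_plus <- vp
  report$votes_minus <- vm
  report$strand <- ifelse(calls == "forward", "+",
                          ifelse(calls == "reverse", "-", "."))
  oriented <- report[report$call %in% c("forward", "reverse"), , drop = FALSE]
  stranded <- intervals(oriented$chrom, oriented$start, oriented$end,
                        name = oriented$name, score = oriented$score,
                        strand = oriented$strand)
  counts <- c(forward = sum(calls == "forward"),
              reverse = sum(calls == "reverse"),
              ambiguous = sum(calls == "ambiguous"),
              no_motif = sum(calls == "no_motif"))
  list(peaks = report, stranded = stranded,
       hits = if (length(kept_hits)) do.call(rbind, kept_hits) else hits_all,
       counts = counts)
}

#' Orientation of peaks relative to a locus's D-J-C end
#'
#' A site points `toward_DJC` when its motif faces the locus end holding
#' the D-J-C cluster: strand `+` with polarity `right`, or strand `-`
#' with polarity `left`.  Peaks without an unambiguous orientation call
#' are excluded.
#'
#' @param oriented oriented-peak report (needs `call` and `strand`).
#' @param locus a [locus_definition()] (or [locus_spec()]).
#' @return list with `per_peak` (the oriented subset plus a `direction`
#'   column) and `tally` (named counts `toward`, `away`).
#' @export
orientation_relative_to_locus <- function(oriented, locus) {
  if (inherits(locus, "locus_spec")) locus <- locus_definition(locus)
  ok <- oriented$call %in% c("forward", "reverse")
  x <- oriented[ok, , drop = FALSE]
  toward <- (x$strand == "+" & locus$polarity == "right") |
            (x$strand == "-" & locus$polarity == "left")
  x$direction <- ifelse(toward, "toward_DJC", "away_from_DJC")
  list(per_peak = x,
       tally = c(toward = sum(toward), away = sum(!toward)))
}
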