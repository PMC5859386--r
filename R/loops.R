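# Anchor-pair geometry and loop prediction under the convergent-stop
# extrusion rule.  Geometry of an ordered pair (left, right):
# (+,-) convergent (facing), equal signs tandem, (-,+) divergent.

.check_anchors <- function(anchors) {
  anchors <- validate_intervals(anchors)
  if (any(anchors$strand == "."))
    stop("anchors must be stranded ('+' or '-')")
  anchors[order(anchors$chrom, anchors$start), , drop = FALSE]
}

# merge overlapping anchors, keeping the best-scoring representative:
# one physical site, one anchor
.merge_anchors <- function(anchors) {
  anchors <- .check_anchors(anchors)
  if (nrow(anchors) < 2L) return(anchors)
  keep <- list()
  i <- 1L
  while (i <= nrow(anchors)) {
    j <- i
    cur_end <- anchors$end[i]
    while (j < nrow(anchors) && anchors$chrom[j + 1L] == anchors$chrom[i] &&
           anchors$start[j + 1L] < cur_end) {
      j <- j + 1L
      cur_end <- max(cur_end, anchors$end[j])
    }
    blk <- anchors[i:j, , drop = FALSE]
    keep[[length(keep) + 1L]] <- blk[which.max(blk$score), , drop = FALSE]
    i <- j + 1L
  }
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

#' Classify the geometry of an anchor pair
#'
#' @param a,b one-row stranded interval data frames on the same
#'   chromosome, non-overlapping, strands `+`/`-` only.
#' @return object of class `anchor_pair`: list with `left`, `right`
#'   (ordered by coordinate), `geometry` (`convergent`, `tandem` or
#'   `divergent`) and `span` (outer span in bp).
#' @export
classify_pair <- function(a, b) {
  a <- validate_intervals(a); b <- validate_intervals(b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$strand == "." || b$strand == ".")
    stop("anchors must be stranded ('+' or '-')")
  if (a$chrom != b$chrom) stop("anchors on different chromosomes")
  if (a$start < b$end && b$start < a$end) stop("overlapping anchors")
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  geometry <- if (a$strand == "+" && b$strand == "-") "convergent"
              else if (a$strand == "-" && b$strand == "+") "divergent"
              else "tandem"
  structure(list(left = a, right = b, geometry = geometry,
                 span = b$end - a$start),
            class = "anchor_pair")
}

#' Predict loops under the convergent-stop extrusion rule
#'
#' For every forward (`+`) anchor the predicted partner is the nearest
#' downstream reverse (`-`) anchor, if any; the pair is annotated with
#' the number of intervening anchors.  Anchors with no valid partner
#' yield no loop, so an all-same-strand array predicts no internal
#' loops.  Overlapping anchors are merged (best score kept) before
#' pairing.  Every predicted loop is convergent by construction; the
#' intervening-anchor count lets users relax the fully-blocking
#' assumption downstream.
#'
#' @param anchors stranded interval data frame (strands `+`/`-` only).
#' @return data frame of loops: `chrom`, `left_start`, `left_end`,
#'   `left_name`, `right_start`, `right_end`, `right_name`, `span`,
#'   `n_between`.
#' @export
predict_extrusion_loops <- function(anchors) {
  anchors <- .merge_anchors(anchors)
  out <- list()
  for (ch in unique(anchors$chrom)) {
    x <- anchors[anchors$chrom == ch, , drop = FALSE]
    n <- nrow(x)
    for (i in seq_len(n)) {
      if (x$strand[i] != "+") next
      down <- which(x$strand == "-" & seq_len(n) > i & x$start >= x$end[i])
      if (!length(down)) next
      j <- down[1]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, left_start = x$start[i], left_end = x$end[i],
        left_name = x$name[i], right_start = x$start[j],
        right_end = x$end[j], right_name = x$name[j],
        span = x$end[j] - x$start[i], n_between = j - i - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), left_start = integer(0),
                      left_end = integer(0), left_name = character(0),
                      right_start = integer(0), right_end = integer(0),
                      right_name = character(0), span = integer(0),
                      n_between = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect gene clusters flanked by convergent anchors
#'
#' For each cluster the nearest anchor strictly upstream and strictly
#' downstream are located; the call is `supported` when that pair is
#' convergent (`+` upstream, `-` downstream).  When several consecutive
#' forward anchors sit immediately upstream, each one is reported as a
#' candidate paired with the same downstream anchor.  Clusters lacking a
#' flanking anchor on either side yield no call.
#'
#' @param clusters interval data frame of gene clusters.
#' @param anchors stranded interval data frame.
#' @return data frame: `cluster`, `up_name`, `up_start`, `up_strand`,
#'   `down_name`, `down_start`, `down_strand`, `supported`.
#' @export
detect_flanked_domains <- function(clusters, anchors) {
  clusters <- validate_intervals(clusters)
  anchors <- .merge_anchors(anchors)
  out <- list()
  for (i in seq_len(nrow(clusters))) {
    ch <- clusters$chrom[i]
    x <- anchors[anchors$chrom == ch, , drop = FALSE]
    up_idx <- which(x$end <= clusters$start[i])
    down_idx <- which(x$start >= clusters$end[i])
    if (!length(up_idx) || !length(down_idx)) next
    d <- down_idx[1]
    nearest_up <- up_idx[length(up_idx)]
    cands <- nearest_up
    if (x$strand[nearest_up] == "+") {
      k <- nearest_up
      while (k - 1L >= 1L && (k - 1L) %in% up_idx && x$strand[k - 1L] == "+")
        k <- k - 1L
      cands <- seq.int(k, nearest_up)
    }
    for (u in cands) {
      out[[length(out) + 1L]] <- data.frame(
        cluster = clusters$name[i], up_name = x$name[u], up_start = x$start[u],
        up_strand = x$strand[u], down_name = x$name[d],
        down_start = x$start[d], down_strand = x$strand[d],
        supported = x$strand[u] == "+" && x$strand[d] == "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cluster = character(0), up_name = character(0),
                      up_start = integer(0), up_strand = character(0),
                      down_name = character(0), down_start = integer(0),
                      down_strand = character(0), supported = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Geometry census of an anchor set
#'
#' Counts convergent / tandem / divergent geometry over all ordered
#' anchor pairs and over the predicted extrusion loops (which are
#' convergent by construction).
#'
#' @param anchors stranded interval data frame with at least 2 anchors.
#' @return list with `pairs` (named counts), `pair_fractions`, `loops`
#'   (named counts over predicted loops), `n_anchors`, `n_pairs`.
#' @export
geometry_census <- function(anchors) {
  anchors <- .merge_anchors(anchors)
  if (nrow(anchors) < 2L) stop("geometry census needs at least 2 anchors")
  counts <- c(convergent = 0, tandem = 0, divergent = 0)
  for (ch in unique(anchors$chrom)) {
    s <- anchors$strand[anchors$chrom == ch]
    n <- length(s)
    if (n < 2L) next
    is_plus <- s == "+"
    # pairs ordered by coordinate: (+,-) convergent, (-,+) divergent
    n_plus_before <- cumsum(is_plus) - is_plus
    n_minus_before <- cumsum(!is_plus) - !is_plus
    counts[["convergent"]] <- counts[["convergent"]] +
      sum(n_plus_before[!is_plus])
    counts[["divergent"]] <- counts[["divergent"]] +
      sum(n_minus_before[is_plus])
    np <- sum(is_plus); nm <- n - np
    counts[["tandem"]] <- counts[["tandem"]] +
      choose(np, 2) + choose(nm, 2)
  }
  n_pairs <- sum(counts)
  loops <- predict_extrusion_loops(anchors)
  list(pairs = counts,
       pair_fractions = if (n_pairs > 0) counts / n_pairs else counts,
       loops = c(convergent = nrow(loops), tandem = 0L, divergent = 0L),
       n_anchors = nrow(anchors), n_pairs = n_pairs)
}
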