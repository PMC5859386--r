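# Confident-peak calling against a local Poisson background, cross-cell-type
# merging into a presence matrix, specificity classification, per-region
# counting, hypergeometric locus enrichment, and the motif-match fraction
# summary.

#' Call confident peaks from a coverage track
#'
#' Sliding windows are converted to fragment-count equivalents
#' (window coverage sum / `frag_len`) and scored against a Poisson null
#' whose rate is the most conservative of the global track mean, a local
#' mean (default 10 kb window) and, if a control track is given, the
#' control's global, local and window-scale means.  Windows with
#' upper-tail `p <= p_max` are retained,
#' Benjamini-Hochberg q-values are computed over all tested windows,
#' overlapping retained windows are merged, and merged peaks with
#' `q <= fdr_max` are returned sorted by coordinate.  The summit is the
#' position of maximal coverage within the peak.
#'
#' @param track sample [coverage_track()].
#' @param control optional control [coverage_track()] of the same length.
#' @param window window width in bp.
#' @param step window step (default `window / 2`).
#' @param fdr_max maximal BH q-value (confident-peak FDR), default 0.01.
#' @param p_max maximal Poisson p-value, default 1e-5.
#' @param frag_len fragment length used to convert coverage to counts.
#' @param local_window width of the local background window (bp).
#' @return data frame of peaks: `chrom`, `start`, `end`, `name`, `score`
#'   (peak height = max coverage), `strand` (`"."`), `summit`, `p_value`,
#'   `q_value`.
#' @export
call_peaks <- function(track, control = NULL, window = 200L,
                       step = max(1L, window %/% 2L), fdr_max = 0.01,
                       p_max = 1e-5, frag_len = 147L, local_window = 10000L) {
  stopifnot(inherits(track, "coverage_track"), window >= 1L)
  v <- track$values
  L <- length(v)
  if (!is.null(control)) {
    stopifnot(inherits(control, "coverage_track"))
    if (length(control$values) != L) stop("mismatched track lengths")
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      summit = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE)
  if (L < window) return(empty)
  starts <- seq.int(0L, L - window, by = step)
  cs <- c(0, cumsum(v))
  wsum <- cs[starts + window + 1L] - cs[starts + 1L]
  k <- wsum / frag_len
  half <- local_window %/% 2L
  ls <- pmax(starts + window %/% 2L - half, 0L)
  le <- pmin(starts + window %/% 2L + half, L)
  local_mean <- (cs[le + 1L] - cs[ls + 1L]) / (le - ls)
  lambda <- pmax(mean(v), local_mean)
  if (!is.null(control)) {
    cc <- c(0, cumsum(control$values))
    ctrl_local <- (cc[le + 1L] - cc[ls + 1L]) / (le - ls)
    ctrl_win <- (cc[starts + window + 1L] - cc[starts + 1L]) / window
    lambda <- pmax(lambda, ctrl_local, ctrl_win, mean(control$values))
  }
  mu <- lambda * window / frag_len
  p <- ppois(ceiling(k) - 1, mu, lower.tail = FALSE)
  p[k <= 0] <- 1
  q <- p.adjust(p, method = "BH")
  keep <- which(p <= p_max & q <= fdr_max)
  if (!length(keep)) return(empty)
  # merge overlapping retained windows
  ks <- starts[keep]; ke <- starts[keep] + window
  o <- order(ks)
  ks <- ks[o]; ke <- ke[o]; kp <- p[keep][o]; kq <- q[keep][o]
  ms <- ks[1]; me <- ke[1]; mp <- kp[1]; mq <- kq[1]
  peaks <- list()
  flush <- function() {
    seg <- v[(ms + 1L):me]
    summit <- ms + which.max(seg) - 1L
    peaks[[length(peaks) + 1L]] <<- data.frame(
      chrom = track$chrom, start = ms, end = me, name = NA_character_,
      score = max(seg), strand = ".", summit = summit,
      p_value = mp, q_value = mq, stringsAsFactors = FALSE)
  }
  for (i in seq_along(ks)[-1]) {
    if (ks[i] < me) {           # >= 1 bp overlap
      me <- max(me, ke[i]); mp <- min(mp, kp[i]); mq <- min(mq, kq[i])
    } else {
      flush()
      ms <- ks[i]; me <- ke[i]; mp <- kp[i]; mq <- kq[i]
    }
  }
  flush()
  res <- do.call(rbind, peaks)
  res$name <- sprintf("%s_peak_%d", track$chrom, seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

# -- merging and specificity --------------------------------------------------

# minimal union-find for transitive overlap closure
.uf_components <- function(n, edges_from, edges_to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(edges_from)) {
    a <- find(edges_from[e]); b <- find(edges_to[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge peak sets across cell types into a presence matrix
#'
#' The transitive closure of pairwise overlaps of at least `min_overlap`
#' bp defines merged reference intervals; a cell type is "present" at a
#' merged interval when it contributed at least one peak to the cluster.
#' The default `min_overlap = 1` is literal overlap (abutting peaks are
#' not merged).
#'
#' @param peak_sets named list of peak data frames (one per cell type).
#' @param min_overlap minimal overlap in bp (default 1).
#' @return list with `intervals` (merged reference intervals), `presence`
#'   (logical matrix: merged interval x cell type) and `members`
#'   (peak-to-cluster assignment).
#' @export
merge_peak_sets <- function(peak_sets, min_overlap = 1L) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)), min_overlap >= 1L)
  cts <- names(peak_sets)
  all <- do.call(rbind, lapply(cts, function(ct) {
    p <- peak_sets[[ct]]
    if (is.null(p) || !nrow(p)) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end,
               cell_type = ct, stringsAsFactors = FALSE)
  }))
  if (is.null(all) || !nrow(all)) {
    return(list(intervals = intervals(character(0), integer(0), integer(0))[0, ],
                presence = matrix(logical(0), 0, length(cts),
                                  dimnames = list(NULL, cts)),
                members = data.frame()))
  }
  all$cluster <- NA_integer_
  next_id <- 0L
  for (ch in unique(all$chrom)) {
    idx <- which(all$chrom == ch)
    ir <- IRanges::IRanges(start = all$start[idx] + 1L, end = all$end[idx])
    hits <- IRanges::findOverlaps(ir, ir, minoverlap = min_overlap)
    comp <- .uf_components(length(idx),
                           S4Vectors::queryHits(hits),
                           S4Vectors::subjectHits(hits))
    all$cluster[idx] <- next_id + match(comp, unique(comp))
    next_id <- next_id + length(unique(comp))
  }
  ids <- sort(unique(all$cluster))
  m_chrom <- vapply(ids, function(id) all$chrom[all$cluster == id][1], character(1))
  m_start <- vapply(ids, function(id) min(all$start[all$cluster == id]), numeric(1))
  m_end   <- vapply(ids, function(id) max(all$end[all$cluster == id]), numeric(1))
  ord <- order(m_chrom, m_start, m_end)
  merged <- intervals(m_chrom[ord], m_start[ord], m_end[ord],
                      name = sprintf("merged_%d", seq_along(ids)))
  presence <- matrix(FALSE, length(ids), length(cts),
                     dimnames = list(merged$name, cts))
  row_of <- match(all$cluster, ids[ord])
  presence[cbind(row_of, match(all$cell_type, cts))] <- TRUE
  list(intervals = merged, presence = presence,
       members = all[, c("chrom", "start", "end", "cell_type", "cluster")])
}

#' Classify cross-cell-type binding specificity
#'
#' Applies the category rules in precedence order:
#' \enumerate{
#'   \item `ubiquitous` — present in every panel label, including the
#'     non-lymphoid ones;
#'   \item `lymphocyte_specific` — no non-lymphoid label present, and at
#'     least one B-lineage and one T-lineage label present;
#'   \item `B_lineage` / `T_lineage` — no non-lymphoid label, all present
#'     labels of one lineage, and at least two of them;
#'   \item `stage_specific` — exactly one lymphoid label present;
#'   \item `mixed` — any other pattern.
#' }
#' Every presence pattern maps to exactly one class.
#'
#' @param presence logical matrix from [merge_peak_sets()].
#' @param panel a [cell_type_panel()].
#' @param groupings named map label -> `"B"`, `"T"` or `"non_lymphoid"`
#'   covering the panel.
#' @return character vector of classes, named by merged interval.
#' @export
classify_specificity <- function(presence, panel, groupings) {
  stopifnot(is.matrix(presence))
  labs <- colnames(presence)
  if (!all(labs %in% names(groupings)))
    stop("label missing from groupings: ",
         paste(setdiff(labs, names(groupings)), collapse = ", "))
  if (!all(as.character(panel) %in% labs))
    stop("presence matrix lacks panel label(s)")
  grp <- groupings[labs]
  apply(presence, 1, function(pr) {
    g <- grp[pr]
    n_b <- sum(g == "B"); n_t <- sum(g == "T"); n_nl <- sum(g == "non_lymphoid")
    if (all(pr)) "ubiquitous"
    else if (n_nl == 0 && n_b >= 1 && n_t >= 1) "lymphocyte_specific"
    else if (n_nl == 0 && n_t == 0 && n_b >= 2) "B_lineage"
    else if (n_nl == 0 && n_b == 0 && n_t >= 2) "T_lineage"
    else if (n_nl == 0 && n_b + n_t == 1) "stage_specific"
    else "mixed"
  })
}

#' Count peaks whose summit lies in a region
#'
#' Summit-in-region (half-open) membership: a peak belongs to exactly one
#' region.
#'
#' @param peaks peak data frame (needs `chrom`, `summit`).
#' @param region one-row interval data frame.
#' @return integer count.
#' @export
count_peaks_in_region <- function(peaks, region) {
  region <- validate_intervals(region)
  stopifnot(nrow(region) == 1L)
  if (!nrow(peaks)) return(0L)
  sum(peaks$chrom == region$chrom &
        peaks$summit >= region$start & peaks$summit < region$end)
}

# vectorised exact upper tail P(X >= k) of Hypergeometric(N, K, n)
.hyper_tail <- function(k, N, K, n) {
  p <- ifelse(k <= 0, 1, phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Hypergeometric enrichment of peaks in a locus
#'
#' Exact upper-tail probability `P(X >= k)` for drawing `k` locus bins
#' among `n` peak-bearing bins from a genome of `N` bins of which `K`
#' fall in the locus.
#'
#' @param N total genome bins.
#' @param K locus bins.
#' @param n total peak-bearing bins.
#' @param k locus peak-bearing bins.
#' @return object of class `enrichment_result` with fields
#'   `population_bins`, `locus_bins`, `total_peaks`, `locus_peaks`,
#'   `p_value`.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("impossible counts: need 0 <= k <= min(K, n), K <= N, n <= N")
  structure(list(population_bins = N, locus_bins = K, total_peaks = n,
                 locus_peaks = k, p_value = .hyper_tail(k, N, K, n)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> k=%d of n=%d peak bins in K=%d of N=%d locus bins: P(X>=k) = %.3g\n",
              x$locus_peaks, x$total_peaks, x$locus_bins, x$population_bins,
              x$p_value))
  invisible(x)
}

#' Bin-based locus enrichment from a peak set
#'
#' Bins the genome into fixed windows (`bin_size`), counts bins
#' containing at least one peak summit genome-wide (`n`) and within the
#' locus span (`k`), and tests enrichment with
#' [hypergeometric_enrichment()].
#'
#' @param peaks peak data frame across the whole genome (one cell type).
#' @param chrom_lengths named chromosome lengths.
#' @param locus one-row interval data frame (the locus span).
#' @param bin_size bin width in bp (default 1000).
#' @return an `enrichment_result`.
#' @export
locus_enrichment <- function(peaks, chrom_lengths, locus, bin_size = 1000L) {
  locus <- validate_intervals(locus)
  stopifnot(nrow(locus) == 1L, bin_size >= 1L,
            locus$chrom %in% names(chrom_lengths))
  nbins <- ceiling(as.numeric(chrom_lengths) / bin_size)
  N <- sum(nbins)
  K <- length(seq.int(locus$start %/% bin_size, (locus$end - 1L) %/% bin_size))
  bin_id <- function(chrom, pos) paste0(chrom, ":", pos %/% bin_size)
  if (nrow(peaks)) {
    ids <- unique(bin_id(peaks$chrom, peaks$summit))
    n <- length(ids)
    in_locus <- peaks$chrom == locus$chrom &
      peaks$summit >= locus$start & peaks$summit < locus$end
    k <- length(unique(bin_id(peaks$chrom[in_locus], peaks$summit[in_locus])))
  } else {
    n <- 0L; k <- 0L
  }
  hypergeometric_enrichment(N, K, n, k)
}

#' Motif-match fraction of a peak set
#'
#' Percentage of peaks whose orientation call is anything other than
#' `no_motif` (ambiguous peaks had motifs, so they count as matched),
#' rounded to one decimal.
#'
#' @param oriented oriented-peak data frame from [orient_peak_set()]
#'   (needs a `call` column).
#' @return list with `total`, `with_motif`, `percent`.
#' @export
motif_match_fraction <- function(oriented) {
  stopifnot(is.data.frame(oriented), "call" %in% names(oriented))
  total <- nrow(oriented)
  if (total == 0L) stop("empty peak set: motif fraction undefined")
  with_motif <- sum(oriented$call != "no_motif")
  list(total = total, with_motif = with_motif,
       percent = motif_match_percent(total, with_motif))
}

#' @rdname motif_match_fraction
#' @param total total number of peaks (> 0).
#' @param with_motif number of peaks with at least one motif hit.
#' @return `motif_match_percent`: the percentage rounded to one decimal.
#' @export
motif_match_percent <- function(total, with_motif) {
  stopifnot(total > 0, with_motif >= 0, with_motif <= total)
  round(100 * with_motif / total, 1)
}
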