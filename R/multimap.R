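# Multi-placement read retention: the "report all alignments with at most
# v mismatches, keep only the best stratum, discard reads with more than m
# best-stratum placements" contract, plus fragment-extension coverage and
# the duplicated-copy coverage comparison across placement caps.

# restrict candidates to each read's best (minimal-mismatch) stratum
.best_stratum <- function(cand) {
  if (!nrow(cand)) return(cand)
  best <- tapply(cand$mismatches, cand$read_index, min)
  cand[cand$mismatches == best[as.character(cand$read_index)], , drop = FALSE]
}

# apply the placement cap: reads with more than m_max best-stratum
# placements are discarded
.apply_cap <- function(cand, m_max) {
  if (!nrow(cand)) return(list(kept = cand, over = integer(0)))
  cnt <- table(cand$read_index)
  over <- as.integer(names(cnt)[cnt > m_max])
  list(kept = cand[!cand$read_index %in% over, , drop = FALSE], over = over)
}

#' Place reads with the best-stratum / placement-cap retention policy
#'
#' Candidate placements are all positions on both strands of every
#' chromosome with at most `v_max` mismatches (exact counting over every
#' offset — no heuristic index).  Only the best stratum (minimal mismatch
#' count) of each read is kept; if it holds at most `m_max` placements
#' they are all reported with full weight, otherwise the read is
#' discarded.  Ties within the best stratum are all reported, so results
#' are deterministic.
#'
#' Identical read sequences are de-duplicated before placement (the
#' conventional duplicate-removal step); each distinct sequence then
#' contributes once, under the id of its first occurrence.
#'
#' @param reads character vector of read sequences, or a data frame with
#'   `seq` and `id` columns (as produced by [simulate_reads()]).
#' @param genome named `DNAStringSet` (or named character vector).
#' @param v_max maximum mismatches per placement (>= 0).
#' @param m_max maximum number of best-stratum placements retained (>= 1).
#' @param dedup de-duplicate identical sequences first (default TRUE).
#' @return list with `placements` (data frame: `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `mismatches`), `discarded` (ids of reads
#'   exceeding `m_max`), `unplaced` (ids with no candidate at all),
#'   `n_input`, `n_unique`.
#' @export
place_reads <- function(reads, genome, v_max = 2L, m_max = 3L, dedup = TRUE) {
  stopifnot(v_max >= 0L, m_max >= 1L)
  if (is.data.frame(reads)) {
    ids <- reads$id %||% sprintf("read_%06d", seq_len(nrow(reads)))
    seqs <- reads$seq
  } else {
    seqs <- as.character(reads)
    ids <- names(seqs) %||% sprintf("read_%06d", seq_along(seqs))
  }
  chroms <- names(genome)
  gseq <- as.character(genome)   # DNAStringSet or plain character vector
  if (is.null(chroms) || !length(gseq)) stop("empty genome (or unnamed chromosomes)")
  if (any(nchar(seqs) > max(nchar(gseq))))
    stop("read longer than every chromosome")
  empty <- data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(seqs))
    return(list(placements = empty, discarded = character(0),
                unplaced = character(0), n_input = 0L, n_unique = 0L))
  if (dedup) {
    first <- !duplicated(seqs)
    useqs <- seqs[first]
    uids <- ids[first]
  } else {
    useqs <- seqs
    uids <- ids
  }
  cand <- .best_stratum(.cpp_place_candidates(useqs, gseq, as.integer(v_max)))
  ret <- .apply_cap(cand, m_max)
  cand <- ret$kept
  over <- ret$over
  placed_idx <- unique(cand$read_index)
  unplaced <- uids[setdiff(seq_along(useqs), c(placed_idx, over))]
  rl <- nchar(useqs)[cand$read_index]
  placements <- data.frame(
    read_id = uids[cand$read_index],
    chrom = chroms[cand$chrom_index],
    start = as.integer(cand$start),
    end = as.integer(cand$start + rl),
    strand = ifelse(cand$forward == 1L, "+", "-"),
    mismatches = as.integer(cand$mismatches),
    stringsAsFactors = FALSE)
  placements <- placements[order(placements$chrom, placements$start,
                                 placements$read_id), , drop = FALSE]
  rownames(placements) <- NULL
  list(placements = placements, discarded = uids[over], unplaced = unplaced,
       n_input = length(seqs), n_unique = length(useqs))
}

#' Fragment-extension coverage from placements
#'
#' Each placement contributes `weight` over `extend_to` bases from its 5'
#' end in the placement's strand direction, clipped at chromosome
#' boundaries.
#'
#' @param placements data frame from [place_reads()] (needs `read_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param extend_to extension length in bp (>= read length).
#' @param weight `"full"` (each placement counts 1, mirroring
#'   report-all-up-to-m aligner semantics) or `"fractional"` (each
#'   placement of a read counts 1/k where k is the read's number of
#'   retained placements).
#' @return named list of [coverage_track()], one per chromosome in
#'   `chrom_lengths`.
#' @export
coverage_from_placements <- function(placements, chrom_lengths,
                                     extend_to = 147L,
                                     weight = c("full", "fractional")) {
  weight <- match.arg(weight)
  stopifnot(!is.null(names(chrom_lengths)))
  if (nrow(placements) &&
      extend_to < max(placements$end - placements$start))
    stop("extend_to must be >= read length")
  w <- rep(1, nrow(placements))
  if (weight == "fractional" && nrow(placements)) {
    k <- table(placements$read_id)
    w <- 1 / as.numeric(k[placements$read_id])
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[ch]])
    sel <- which(placements$chrom == ch)
    d <- numeric(L + 1L)
    if (length(sel)) {
      p <- placements[sel, , drop = FALSE]
      s <- ifelse(p$strand == "+", p$start, p$end - extend_to)
      e <- ifelse(p$strand == "+", p$start + extend_to, p$end)
      s <- pmax(s, 0L); e <- pmin(e, L)
      ok <- which(e > s)
      for (i in ok) {
        d[s[i] + 1L] <- d[s[i] + 1L] + w[sel][i]
        d[e[i] + 1L] <- d[e[i] + 1L] - w[sel][i]
      }
    }
    vals <- cumsum(d[seq_len(L)])
    vals[abs(vals) < 1e-9] <- 0     # fractional weights leave FP dust
    out[[ch]] <- coverage_track(ch, vals)
  }
  out
}

#' Coverage over duplication copies as the placement cap varies
#'
#' Applies each placement cap in `m_list` to one shared candidate set
#' and reports mean fragment-extension coverage over every duplication
#' copy, over a non-duplicated control region (a window of template
#' width centred on the first planted site outside the duplication), and
#' over a site-free, duplication-free background window.  This
#' quantifies the coverage loss over near-identical repeats when
#' multi-mapping reads are discarded (cap 1) versus retained (cap >=
#' number of copies).
#'
#' Coverage here defaults to `"fractional"` weighting (each of a read's
#' k retained placements contributes 1/k): only under that weighting is
#' coverage over a perfect repeat commensurable with a unique control
#' region — full weighting replicates every ambiguous read into all
#' copies and inflates repeat coverage by the copy number.
#'
#' @param truth a [build_genome()] result whose spec has a duplication.
#' @param reads read set (see [place_reads()]).
#' @param v_max mismatch budget.
#' @param m_list integer vector of placement caps to compare.
#' Duplicate-sequence removal is disabled here by default: over a perfect
#' repeat, reads from different copies collide in sequence space, so
#' dedup removes several-fold more background reads inside the repeat
#' than outside it and would confound the placement-policy effect this
#' diagnostic isolates (how dedup should interact with multi-placement
#' retention is genuinely underdetermined; see the vignette).
#'
#' @param extend_to fragment extension for coverage.
#' @param weight placement weighting (see [coverage_from_placements()]).
#' @param dedup de-duplicate identical read sequences before placement
#'   (default FALSE here; see Details).
#' @return data frame with columns `m`, `region`, `start`, `end`,
#'   `mean_coverage`.
#' @export
compare_mapping_policies <- function(truth, reads, v_max = 2L,
                                     m_list = c(1L, 2L, 3L),
                                     extend_to = 147L,
                                     weight = "fractional",
                                     dedup = FALSE) {
  stopifnot(inherits(truth, "sim_truth"))
  dm <- truth$duplication_map
  if (!nrow(dm)) stop("truth has no duplication map")
  chrom <- names(truth$genome)[1]
  L <- Biostrings::width(truth$genome)[1]
  wtpl <- dm$end[1] - dm$start[1]
  in_dup <- function(s, e) any(s < dm$end & e > dm$start)
  sites <- truth$sites
  ctrl_sites <- sites[!vapply(seq_len(nrow(sites)), function(i)
    in_dup(sites$start[i], sites$end[i]), logical(1)), , drop = FALSE]
  if (!nrow(ctrl_sites)) stop("no non-duplicated control site in the truth")
  cc <- (ctrl_sites$start[1] + ctrl_sites$end[1]) %/% 2L
  ctrl <- c(max(0L, cc - wtpl %/% 2L), min(L, cc + wtpl %/% 2L))
  # the control must stay clear of the duplication: clip at the nearest
  # duplication boundary on either side of the control site
  left_dup <- dm$end[dm$end <= cc]
  right_dup <- dm$start[dm$start >= cc]
  if (length(left_dup)) ctrl[1] <- max(ctrl[1], max(left_dup))
  if (length(right_dup)) ctrl[2] <- min(ctrl[2], min(right_dup))
  if (ctrl[2] - ctrl[1] < 100L)
    stop("control site too close to the duplication for a control window")
  # background: widest window clear of duplication copies and of site
  # neighbourhoods (site +/- 2 kb)
  blocked <- rbind(cbind(dm$start, dm$end),
                   cbind(pmax(sites$start - 2000L, 0L),
                         pmin(sites$end + 2000L, L)))
  blocked <- blocked[order(blocked[, 1]), , drop = FALSE]
  gaps <- list(); cur <- 0L
  for (i in seq_len(nrow(blocked))) {
    if (blocked[i, 1] > cur) gaps[[length(gaps) + 1L]] <- c(cur, blocked[i, 1])
    cur <- max(cur, blocked[i, 2])
  }
  if (cur < L) gaps[[length(gaps) + 1L]] <- c(cur, L)
  gw <- vapply(gaps, diff, numeric(1))
  if (!length(gaps)) stop("no background window available")
  bg <- gaps[[which.max(gw)]]
  regions <- rbind(
    data.frame(region = sprintf("copy_%d", dm$copy), start = dm$start,
               end = dm$end, stringsAsFactors = FALSE),
    data.frame(region = "control", start = ctrl[1], end = ctrl[2],
               stringsAsFactors = FALSE),
    data.frame(region = "background", start = bg[1], end = bg[2],
               stringsAsFactors = FALSE))
  base <- place_reads(reads, truth$genome, v_max = v_max,
                      m_max = .Machine$integer.max, dedup = dedup)
  out <- list()
  for (m in m_list) {
    idx <- stats::setNames(seq_along(unique(base$placements$read_id)),
                           unique(base$placements$read_id))
    cand <- data.frame(read_index = idx[base$placements$read_id],
                       base$placements, stringsAsFactors = FALSE)
    ret <- .apply_cap(cand, m)
    pl <- list(placements = ret$kept[, names(base$placements), drop = FALSE])
    cov <- coverage_from_placements(pl$placements,
                                    stats::setNames(L, chrom),
                                    extend_to = extend_to, weight = weight)
    v <- cov[[chrom]]$values
    mc <- vapply(seq_len(nrow(regions)), function(i)
      mean(v[(regions$start[i] + 1L):regions$end[i]]), numeric(1))
    out[[length(out) + 1L]] <- data.frame(m = m, regions,
                                          mean_coverage = mc,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
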