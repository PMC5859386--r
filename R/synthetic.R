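# Synthetic antigen-receptor loci: planted, oriented CTCF sites with
# per-cell-type occupancy, an optional near-identical segmental
# triplication, and simulated ChIP-seq reads.  The generator is the
# statistical stand-in for real ChIP-seq data: peak height is proportional
# to the fraction of cells bound (occupancy), V-region sites are
# lymphocyte-restricted while D-J-C-end sites are ubiquitous, and the
# TCRa/d-like locus carries a triplicated segment.

#' Ordered cell-type panel
#'
#' The nine cell states compared throughout: B-lineage progenitors
#' (pre-pro-B, pro-B, pre-B), thymocyte stages (DN, DP), mature B and T
#' cells, and the two non-lymphoid references (MEF, ES).
#'
#' @param labels unique character labels (default: the nine-state panel).
#' @return character vector of class `cell_type_panel`.
#' @export
cell_type_panel <- function(labels = c("pre_pro_B", "pro_B", "pre_B", "DN",
                                       "DP", "mature_B", "mature_T",
                                       "MEF", "ES")) {
  stopifnot(is.character(labels), !anyDuplicated(labels))
  structure(labels, class = "cell_type_panel")
}

#' Default lineage groupings for a panel
#'
#' Maps each panel label to `"B"`, `"T"` or `"non_lymphoid"`, as used by
#' [classify_specificity()].
#'
#' @param panel a [cell_type_panel()].
#' @return named character vector over the panel labels.
#' @export
default_groupings <- function(panel = cell_type_panel()) {
  g <- c(pre_pro_B = "B", pro_B = "B", pre_B = "B", mature_B = "B",
         DN = "T", DP = "T", mature_T = "T",
         MEF = "non_lymphoid", ES = "non_lymphoid")
  if (!all(panel %in% names(g)))
    stop("no default grouping for label(s): ",
         paste(setdiff(panel, names(g)), collapse = ", "))
  g[as.character(panel)]
}

#' Specification of a synthetic AgR-like locus
#'
#' @param name locus label (also the chromosome name of its synthetic
#'   sequence).
#' @param length locus length in bp.
#' @param v_region,djc_region integer `c(start, end)` sub-intervals
#'   (0-based, half-open); must be disjoint and inside `[0, length)`.
#' @param polarity `"right"` or `"left"`: which genomic end holds the
#'   D-J-C cluster (i.e. the direction "toward D-J-C").
#' @param sites data frame of planted CTCF sites with columns `name`,
#'   `pos` (0-based start of the motif instance), `strand` (`+`/`-`) and
#'   `motif` (a name in the motif library used by [build_genome()]).
#' @param occupancy named list: cell type -> named numeric vector of
#'   per-site binding probabilities in `[0, 1]` (sites absent from a
#'   vector have occupancy 0 in that cell type).
#' @param duplication optional list `list(template = c(start, end),
#'   n_copies, divergence)`: the template is cloned `n_copies - 1` times
#'   immediately downstream with the given per-base substitution rate.
#' @param rearranging the panel label at which this locus rearranges
#'   (used by the pipeline to pick the cell type for orientation calls).
#' @return object of class `locus_spec`.
#' @export
locus_spec <- function(name, length, v_region, djc_region,
                       polarity = c("right", "left"), sites, occupancy,
                       duplication = NULL, rearranging = NULL) {
  polarity <- match.arg(polarity)
  length <- as.integer(length)
  stopifnot(length > 0, is.data.frame(sites),
            all(c("name", "pos", "strand", "motif") %in% names(sites)))
  reg_ok <- function(r) length(r) == 2L && r[1] >= 0 && r[1] < r[2] && r[2] <= length
  if (!reg_ok(v_region) || !reg_ok(djc_region))
    stop("v_region/djc_region must be c(start, end) within [0, length)")
  if (max(v_region[1], djc_region[1]) < min(v_region[2], djc_region[2]))
    stop("v_region and djc_region must be disjoint")
  if ((polarity == "right") != (djc_region[1] >= v_region[2]))
    stop("polarity inconsistent with the order of v_region and djc_region")
  if (any(!sites$strand %in% c("+", "-")))
    stop("planted site strands must be '+' or '-'")
  if (any(sites$pos < 0 | sites$pos >= length))
    stop("planted site outside the locus")
  if (anyDuplicated(sites$name)) stop("planted site names must be unique")
  stopifnot(is.list(occupancy))
  for (ct in names(occupancy)) {
    o <- occupancy[[ct]]
    if (any(o < 0 | o > 1)) stop("binding probabilities must lie in [0, 1]")
    if (any(!names(o) %in% sites$name))
      stop("occupancy for unknown site in cell type ", ct)
  }
  if (!is.null(duplication)) {
    stopifnot(is.list(duplication),
              all(c("template", "n_copies") %in% names(duplication)))
    duplication$divergence <- duplication$divergence %||% 0
    t <- duplication$template
    if (!reg_ok(t)) stop("duplication template must lie within the locus")
    if (duplication$n_copies < 1L) stop("n_copies must be >= 1")
    if (duplication$divergence < 0 || duplication$divergence >= 1)
      stop("divergence must be in [0, 1)")
    w <- t[2] - t[1]
    last_end <- t[2] + (duplication$n_copies - 1L) * w
    if (last_end > length) stop("duplication copies extend past the locus")
  }
  structure(list(name = name, length = length,
                 v_region = as.integer(v_region),
                 djc_region = as.integer(djc_region),
                 polarity = polarity, sites = sites, occupancy = occupancy,
                 duplication = duplication, rearranging = rearranging),
            class = "locus_spec")
}

#' The locus-definition view of a spec
#'
#' @param spec a [locus_spec()].
#' @return list with `name`, `chrom`, `span`, `v_region`, `djc_region`
#'   (interval data frames) and `polarity` — the coordinate skeleton used
#'   by counting, enrichment and orientation-polarity operations.
#' @export
locus_definition <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  list(name = spec$name, chrom = spec$name,
       span = intervals(spec$name, 0L, spec$length, name = spec$name),
       v_region = intervals(spec$name, spec$v_region[1], spec$v_region[2],
                            name = paste0(spec$name, "_V")),
       djc_region = intervals(spec$name, spec$djc_region[1], spec$djc_region[2],
                              name = paste0(spec$name, "_DJC")),
       polarity = spec$polarity)
}

#' Build the synthetic genome of one locus
#'
#' Draws a uniform random background sequence, writes each planted motif
#' instance at its recorded position (minus-strand sites as the reverse
#' complement of the motif consensus), then clones the duplication
#' template into its copies with independent per-base substitutions at
#' the stated divergence.  Deterministic given `seed`.
#'
#' Planted sites must not overlap each other, must not straddle a
#' template/copy boundary, and must not fall inside a copy target: copies
#' are clones of the template, so template sites are *projected* into
#' each copy (returned as `copy_sites`, occupancy inherited from the
#' template site).  All copies of a bound site therefore emit reads, as
#' observed for near-identical locus repeats in vivo.
#'
#' @param spec a [locus_spec()].
#' @param library motif library supplying the consensus sequence written
#'   at each planted site (default [default_ctcf_library()]).
#' @param seed integer seed.
#' @return object of class `sim_truth`: list with `genome`
#'   (`DNAStringSet`, one chromosome named after the locus), `sites`
#'   (interval data frame with the true strands and a `motif` column),
#'   `duplication_map`, `occupancy`, `seed`, `spec`.
#' @export
build_genome <- function(spec, library = default_ctcf_library(), seed = 1L) {
  stopifnot(inherits(spec, "locus_spec"))
  libnames <- vapply(library, function(m) m$name, character(1))
  if (any(!spec$sites$motif %in% libnames))
    stop("planted site references motif absent from the library")
  sites <- spec$sites[order(spec$sites$pos), , drop = FALSE]
  lens <- vapply(sites$motif, function(mn) nrow(library[[match(mn, libnames)]]$probs),
                 integer(1))
  starts <- sites$pos
  ends <- starts + lens
  if (any(ends > spec$length)) stop("planted site extends past the locus")
  if (nrow(sites) > 1L && any(starts[-1] < ends[-nrow(sites)]))
    stop("overlapping planted sites")
  dup <- spec$duplication
  dup_map <- data.frame(chrom = character(0), copy = integer(0),
                        start = integer(0), end = integer(0))
  if (!is.null(dup)) {
    w <- dup$template[2] - dup$template[1]
    copy_start <- dup$template[1] + (seq_len(dup$n_copies) - 1L) * w
    dup_map <- data.frame(chrom = spec$name,
                          copy = seq_len(dup$n_copies) - 1L,
                          start = as.integer(copy_start),
                          end = as.integer(copy_start + w))
    for (i in seq_len(nrow(dup_map))) {
      cross <- (starts < dup_map$start[i] & ends > dup_map$start[i]) |
               (starts < dup_map$end[i] & ends > dup_map$end[i])
      if (any(cross))
        stop("planted site straddles a duplication boundary")
      if (dup_map$copy[i] > 0L) {
        inside <- starts >= dup_map$start[i] & ends <= dup_map$end[i]
        if (any(inside))
          stop("planted site inside a duplication copy target (plant it in the template instead)")
      }
    }
  }
  chars <- with_seed(seed, {
    g <- sample(BASES, spec$length, replace = TRUE)
    for (i in seq_len(nrow(sites))) {
      m <- library[[match(sites$motif[i], libnames)]]
      s <- motif_consensus(m)
      if (sites$strand[i] == "-") s <- reverse_complement(s)
      g[(starts[i] + 1L):ends[i]] <- strsplit(s, "")[[1]]
    }
    if (!is.null(dup) && dup$n_copies > 1L) {
      tpl <- g[(dup$template[1] + 1L):dup$template[2]]
      for (i in which(dup_map$copy > 0L)) {
        cp <- tpl
        if (dup$divergence > 0) {
          mut <- which(runif(length(cp)) < dup$divergence)
          if (length(mut))
            cp[mut] <- vapply(cp[mut], function(b)
              sample(setdiff(BASES, b), 1L), character(1))
        }
        g[(dup_map$start[i] + 1L):dup_map$end[i]] <- cp
      }
    }
    g
  })
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- spec$name
  site_iv <- if (nrow(sites)) {
    intervals(spec$name, starts, ends, name = sites$name,
              score = 0, strand = sites$strand)
  } else {
    intervals(character(0), integer(0), integer(0))[0, ]
  }
  site_iv$motif <- sites$motif
  # project template sites into the duplication copies: the copies carry the
  # same (possibly diverged) motif instances and are bound like the template,
  # so reads are emitted from every copy; the projections are kept separate
  # from `sites` because divergence may perturb their sequence
  copy_sites <- site_iv[0, ]
  copy_sites$template <- character(0)
  if (!is.null(dup) && dup$n_copies > 1L) {
    in_tpl <- which(site_iv$start >= dup$template[1] &
                      site_iv$end <= dup$template[2])
    for (i in which(dup_map$copy > 0L)) {
      off <- dup_map$start[i] - dup$template[1]
      if (length(in_tpl)) {
        cs <- site_iv[in_tpl, , drop = FALSE]
        cs$template <- cs$name
        cs$start <- cs$start + off
        cs$end <- cs$end + off
        cs$name <- sprintf("%s_copy%d", cs$template, dup_map$copy[i])
        copy_sites <- rbind(copy_sites, cs)
      }
    }
  }
  structure(list(genome = genome, sites = site_iv, copy_sites = copy_sites,
                 duplication_map = dup_map,
                 occupancy = spec$occupancy, seed = as.integer(seed),
                 spec = spec),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s: %d bp, %d planted sites, %d duplication copies\n",
              x$spec$name, x$spec$length, nrow(x$sites), nrow(x$duplication_map)))
  invisible(x)
}

#' Simulate ChIP-seq reads for one cell type
#'
#' Each planted site (and each duplication-copy projection, which
#' inherits its template's occupancy) emits
#' `Poisson(reads_per_bound_site x occupancy)` reads — occupancy acts as
#' the fraction of cell-equivalents with the site bound, so expected
#' peak height is proportional to occupancy.
#' Fragment midpoints are `Normal(site center, frag_len / 4)`, truncated
#' to the chromosome; each fragment is sequenced from a uniformly chosen
#' end for `read_len` bases.  A uniform Poisson background of
#' `background_rate` reads/bp is added.  The returned coverage track
#' extends each read to `frag_len` from its 5' end and is therefore
#' consistent with the read set by construction.
#'
#' @param truth a [build_genome()] result.
#' @param cell_type a label present in the truth's occupancy map.
#' @param reads_per_bound_site expected read count of a fully occupied
#'   site.
#' @param read_len read length (bp).
#' @param frag_len fragment/extension length (bp); the default mirrors
#'   the 147 bp nucleosome-scale extension conventionally used for signal
#'   tracks.
#' @param background_rate background reads per bp.
#' @param seed integer seed.
#' @return list with `reads` (data frame: `id`, `chrom`, `start`, `end`,
#'   `strand`, `seq`, `origin`), `coverage` (named list of
#'   [coverage_track()]), `n_site_reads` (per-site draw), `n_background`.
#' @export
simulate_reads <- function(truth, cell_type, reads_per_bound_site = 40,
                           read_len = 50L, frag_len = 147L,
                           background_rate = 0.02, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"),
            reads_per_bound_site > 0, read_len > 0, frag_len >= read_len,
            background_rate >= 0)
  if (!cell_type %in% names(truth$occupancy))
    stop("unknown cell type: ", cell_type)
  occ <- truth$occupancy[[cell_type]]
  chrom <- names(truth$genome)[1]
  L <- Biostrings::width(truth$genome)[1]
  gstr <- as.character(truth$genome[[1]])
  sites <- truth$sites[, c("name", "start", "end")]
  sites$occ_name <- sites$name
  cs <- truth$copy_sites
  if (!is.null(cs) && nrow(cs)) {
    sites <- rbind(sites,
                   data.frame(name = cs$name, start = cs$start, end = cs$end,
                              occ_name = cs$template,
                              stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    centers <- (sites$start + sites$end) %/% 2L
    mu <- reads_per_bound_site * ifelse(sites$occ_name %in% names(occ),
                                        occ[sites$occ_name], 0)
    n_site <- rpois(nrow(sites), mu)
    frag_start <- integer(0); origin <- character(0)
    for (i in seq_len(nrow(sites))) {
      if (n_site[i] == 0L) next
      mid <- round(rnorm(n_site[i], centers[i], frag_len / 4))
      fs <- pmin(pmax(mid - frag_len %/% 2L, 0L), L - frag_len)
      frag_start <- c(frag_start, as.integer(fs))
      origin <- c(origin, rep(sites$name[i], n_site[i]))
    }
    n_bg <- rpois(1L, background_rate * L)
    if (n_bg > 0L) {
      frag_start <- c(frag_start,
                      as.integer(floor(runif(n_bg, 0, L - frag_len + 1))))
      origin <- c(origin, rep("background", n_bg))
    }
    n <- length(frag_start)
    strand <- if (n) sample(c("+", "-"), n, replace = TRUE) else character(0)
    rstart <- ifelse(strand == "+", frag_start,
                     frag_start + frag_len - read_len)
    rend <- rstart + read_len
    seqs <- if (n) substring(gstr, rstart + 1L, rend) else character(0)
    neg <- which(strand == "-")
    if (length(neg)) seqs[neg] <- reverse_complement(seqs[neg])
    reads <- data.frame(
      id = if (n) sprintf("%s_%s_r%06d", chrom, cell_type, seq_len(n)) else character(0),
      chrom = rep(chrom, n), start = as.integer(rstart), end = as.integer(rend),
      strand = strand, seq = seqs, origin = origin, stringsAsFactors = FALSE)
    cov <- coverage_from_placements(
      data.frame(read_id = reads$id, chrom = reads$chrom, start = reads$start,
                 end = reads$end, strand = reads$strand,
                 mismatches = 0L, stringsAsFactors = FALSE),
      stats::setNames(L, chrom), extend_to = frag_len)
    list(reads = reads, coverage = cov,
         n_site_reads = stats::setNames(n_site, sites$name), n_background = n_bg)
  })
}

# -- default AgR-like panel ---------------------------------------------------

.site_df <- function(name, pos, strand, motif) {
  data.frame(name = name, pos = as.integer(pos), strand = strand,
             motif = motif, stringsAsFactors = FALSE)
}

# occupancy list: every cell type in `panel` gets `v` for V-region sites and
# `d` for D-J-C-end sites, from named per-cell-type numeric vectors.
.occupancy <- function(panel, v_sites, d_sites, v, d) {
  out <- list()
  for (ct in panel) {
    o <- c(stats::setNames(rep(v[[ct]] %||% 0, length(v_sites)), v_sites),
           stats::setNames(rep(d[[ct]] %||% 0, length(d_sites)), d_sites))
    out[[ct]] <- o[o > 0]
  }
  out
}

#' Default synthetic AgR locus panel
#'
#' Four scaled-down locus designs encoding the qualitative architecture
#' the pipeline is built to recover:
#' \describe{
#'   \item{igh_like}{all V-region sites on the forward strand, pointing
#'     toward the D-J-C end; a 3'RR-like cluster of reverse-oriented
#'     sites at the far end (superanchor configuration); V occupancy in
#'     all lymphoid labels only, D-J-C occupancy everywhere.}
#'   \item{igk_like}{mixed V-region orientations (distal half toward the
#'     J end, proximal half away); V occupancy high only in pre-B, low in
#'     pro-B, absent elsewhere — the stage-specific locus; intervening
#'     Cer/Sis-like sites ubiquitous.}
#'   \item{tcrb_like}{small locus, all V sites forward, D-J-C sites
#'     T-restricted.}
#'   \item{tcrad_like}{a triplicated segment (template plus two
#'     near-identical copies, 0.5% divergence) and 85% of V-region sites
#'     pointing toward the J-C end.}
#' }
#'
#' Occupancies are illustrative design values, not estimates: 0.9 for
#' "bound", 0.05 for "marginal", 0 for "unbound"; see the vignette for
#' the rationale.
#'
#' @param seed recorded in the returned object for provenance; the panel
#'   design itself is fixed and deterministic (randomness enters only in
#'   [build_genome()] / [simulate_reads()]).
#' @return list with `specs` (named list of [locus_spec()]), `panel`
#'   (a [cell_type_panel()]), `groupings`, `seed`.
#' @export
default_agr_panel <- function(seed = 0L) {
  panel <- cell_type_panel()
  lymphoid <- c("pre_pro_B", "pro_B", "pre_B", "DN", "DP", "mature_B", "mature_T")
  all_ct <- as.character(panel)
  lib <- default_ctcf_library()
  motif_names <- vapply(lib, function(m) m$name, character(1))
  cyc <- function(n) motif_names[(seq_len(n) - 1L) %% length(motif_names) + 1L]
  occ_all <- stats::setNames(as.list(rep(0.9, length(all_ct))), all_ct)
  occ_lymph <- stats::setNames(as.list(ifelse(all_ct %in% lymphoid, 0.9, 0)), all_ct)
  occ_lymph$pre_pro_B <- 0.5          # early progenitors bind fewer/lower sites

  # Igh-like: 12 forward V sites, IGCR1-like pair, 3'RR-like triple
  v_pos <- round(seq(3000, 41000, length.out = 12))
  igh_sites <- rbind(
    .site_df(sprintf("igh_v%02d", 1:12), v_pos, "+", cyc(12)),
    .site_df(c("igh_igcr1_a", "igh_igcr1_b"), c(45000, 46500), c("-", "+"),
             motif_names[c(1, 2)]),
    .site_df(sprintf("igh_3rr%d", 1:3), c(53000, 54500, 56000), "-",
             motif_names[c(3, 4, 5)]))
  igh <- locus_spec(
    name = "igh_like", length = 60000L,
    v_region = c(2000L, 42000L), djc_region = c(44000L, 58000L),
    polarity = "right", sites = igh_sites,
    occupancy = .occupancy(all_ct,
                           grep("^igh_v", igh_sites$name, value = TRUE),
                           grep("^igh_(igcr1|3rr)", igh_sites$name, value = TRUE),
                           occ_lymph, occ_all),
    rearranging = "pro_B")

  # Igk-like: distal V half forward (toward J), proximal half reverse
  v_pos <- round(seq(3000, 41000, length.out = 10))
  igk_sites <- rbind(
    .site_df(sprintf("igk_v%02d", 1:10), v_pos,
             c(rep("+", 5), rep("-", 5)), cyc(10)),
    .site_df(c("igk_cer1", "igk_cer2", "igk_sis1", "igk_sis2"),
             c(44000, 45500, 47000, 48500), c("-", "-", "-", "+"),
             motif_names[c(6, 7, 8, 9)]))
  igk_v_occ <- stats::setNames(as.list(rep(0, length(all_ct))), all_ct)
  igk_v_occ$pre_B <- 0.9
  igk_v_occ$pro_B <- 0.05
  igk <- locus_spec(
    name = "igk_like", length = 60000L,
    v_region = c(2000L, 42000L), djc_region = c(43000L, 56000L),
    polarity = "right", sites = igk_sites,
    occupancy = .occupancy(all_ct,
                           grep("^igk_v", igk_sites$name, value = TRUE),
                           grep("^igk_(cer|sis)", igk_sites$name, value = TRUE),
                           igk_v_occ, occ_all),
    rearranging = "pre_B")

  # TCRb-like: small, all V sites forward, D-J-C sites facing them
  v_pos <- round(seq(3000, 25000, length.out = 8))
  tcrb_sites <- rbind(
    .site_df(sprintf("tcrb_v%02d", 1:8), v_pos, "+", cyc(8)),
    .site_df(c("tcrb_5pc", "tcrb_db1", "tcrb_eb"), c(30000, 33000, 36000),
             "-", motif_names[c(1, 5, 9)]))
  t_occ <- stats::setNames(as.list(rep(0, length(all_ct))), all_ct)
  t_occ[c("DN", "DP", "mature_T")] <- 0.9
  tcrb <- locus_spec(
    name = "tcrb_like", length = 40000L,
    v_region = c(2000L, 26000L), djc_region = c(28000L, 38000L),
    polarity = "right", sites = tcrb_sites,
    occupancy = .occupancy(all_ct,
                           grep("^tcrb_v", tcrb_sites$name, value = TRUE),
                           c("tcrb_5pc", "tcrb_db1", "tcrb_eb"),
                           occ_lymph, t_occ),
    rearranging = "DN")

  # TCRa/d-like: triplicated segment, 85% of V sites toward the J-C end
  v_pos <- round(seq(3000, 38500, length.out = 16))
  v_strand <- rep("+", 16); v_strand[c(4, 9, 14)] <- "-"   # 3 of 20 V sites reverse
  tcrad_sites <- rbind(
    .site_df(sprintf("tcrad_v%02d", 1:16), v_pos, v_strand, cyc(16)),
    .site_df(c("tcrad_d1", "tcrad_d2"), c(42000, 45500), "+",
             motif_names[c(2, 6)]),                        # inside the template
    .site_df(c("tcrad_v17", "tcrad_v18"), c(64500, 65600), "+",
             motif_names[c(3, 7)]),
    .site_df(c("tcrad_tea", "tcrad_ea1", "tcrad_ea2"),
             c(76000, 83000, 84500), c("-", "-", "+"),
             motif_names[c(4, 8, 1)]))
  tcrad_v <- grep("^tcrad_(v|d)", tcrad_sites$name, value = TRUE)
  occ_t_lymph <- occ_lymph
  occ_t_lymph$pre_pro_B <- 0.3
  occ_t_lymph$ES <- 0.5               # ES cells retain many TCRa/d sites
  tcrad <- locus_spec(
    name = "tcrad_like", length = 90000L,
    v_region = c(2000L, 66000L), djc_region = c(74000L, 86000L),
    polarity = "right", sites = tcrad_sites,
    occupancy = .occupancy(all_ct, tcrad_v,
                           c("tcrad_tea", "tcrad_ea1", "tcrad_ea2"),
                           occ_t_lymph, occ_all),
    duplication = list(template = c(40000L, 48000L), n_copies = 3L,
                       divergence = 0.005),
    rearranging = "DP")

  # site-free background chromosome: the "rest of the genome" against which
  # locus enrichment is measured
  bg <- locus_spec(
    name = "bg_like", length = 500000L,
    v_region = c(1000L, 2000L), djc_region = c(3000L, 4000L),
    polarity = "right",
    sites = data.frame(name = character(0), pos = integer(0),
                       strand = character(0), motif = character(0),
                       stringsAsFactors = FALSE),
    occupancy = stats::setNames(lapply(all_ct, function(x) numeric(0)), all_ct),
    rearranging = NULL)

  list(specs = list(igh_like = igh, igk_like = igk, tcrb_like = tcrb,
                    tcrad_like = tcrad, bg_like = bg),
       panel = panel, groupings = default_groupings(panel),
       seed = as.integer(seed))
}
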