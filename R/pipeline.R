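# End-to-end orchestration: simulate -> place -> call -> merge/classify ->
# orient -> enrich -> loops, with deterministic per-stage seeds derived
# from one master seed.

#' Pipeline configuration
#'
#' Bundles the locus panel and every stage parameter.  Defaults are the
#' package's standard study conditions (see the vignette).
#'
#' @param panel_design list with `specs`, `panel`, `groupings` as
#'   returned by [default_agr_panel()] (the default).
#' @param seed master seed; all per-stage seeds are derived from it.
#' @param library motif library used for planting and scanning.
#' @param v_max,m_max placement mismatch budget and cap.
#' @param window,fdr_max,p_max,frag_len peak-caller parameters.
#' @param min_overlap literal-overlap threshold for peak merging.
#' @param bin_size bin width for locus enrichment.
#' @param reads_per_bound_site,read_len,background_rate read-simulation
#'   parameters.
#' @param weight placement weighting for coverage (`"full"` or
#'   `"fractional"`).
#' @param mode orientation voting mode.
#' @return object of class `agr_config`.
#' @export
pipeline_config <- function(panel_design = default_agr_panel(), seed = 1L,
                            library = default_ctcf_library(),
                            v_max = 2L, m_max = 3L, window = 200L,
                            fdr_max = 0.01, p_max = 1e-5, frag_len = 147L,
                            min_overlap = 1L, bin_size = 1000L,
                            reads_per_bound_site = 40, read_len = 50L,
                            background_rate = 0.02, weight = "full",
                            mode = "per_instance") {
  stopifnot(is.list(panel_design),
            all(c("specs", "panel", "groupings") %in% names(panel_design)),
            v_max >= 0L, m_max >= 1L, window >= 1L,
            fdr_max > 0, fdr_max <= 1, p_max > 0, p_max <= 1,
            min_overlap >= 1L, bin_size >= 1L,
            reads_per_bound_site > 0, read_len > 0, frag_len >= read_len,
            background_rate >= 0)
  structure(list(specs = panel_design$specs, panel = panel_design$panel,
                 groupings = panel_design$groupings, seed = as.integer(seed),
                 library = library, v_max = as.integer(v_max),
                 m_max = as.integer(m_max), window = as.integer(window),
                 fdr_max = fdr_max, p_max = p_max,
                 frag_len = as.integer(frag_len),
                 min_overlap = as.integer(min_overlap),
                 bin_size = as.integer(bin_size),
                 reads_per_bound_site = reads_per_bound_site,
                 read_len = as.integer(read_len),
                 background_rate = background_rate, weight = weight,
                 mode = mode),
            class = "agr_config")
}

#' Run the full pipeline
#'
#' For every locus: build the synthetic genome, then for every cell type
#' simulate reads, place them under the retention policy, build
#' fragment-extension coverage and call confident peaks.  Per locus the
#' peak sets are merged across cell types into a presence matrix and
#' classified; peaks of every cell type are oriented against the motif
#' library; V-region peak counts, motif-match fractions, toward/away
#' tallies, bin-based locus enrichment and predicted extrusion loops
#' (for the locus's rearranging cell type) are collected.  Identical
#' configs produce identical bundles.
#'
#' @param config an [pipeline_config()].
#' @param verbose print per-stage record counts.
#' @return a bundle: list with `config`, `truths`, `peaks`
#'   (locus -> cell type -> peak df), `merged`, `classes`, `counts`
#'   (V-region peak-count table), `orientation` (per locus x cell type),
#'   `enrichment` (long data frame), `loops`, `census`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "agr_config"))
  panel <- as.character(config$panel)
  specs <- config$specs
  bundle <- list(config = config, truths = list(), peaks = list(),
                 merged = list(), classes = list(), orientation = list(),
                 loops = list(), census = list())
  seeds <- list()
  stage <- 0L
  all_peaks_by_ct <- stats::setNames(vector("list", length(panel)), panel)
  chrom_lengths <- integer(0)
  for (li in seq_along(specs)) {
    spec <- specs[[li]]
    stage <- stage + 1L
    gseed <- derive_seed(config$seed, stage)
    seeds[[paste0("genome_", spec$name)]] <- gseed
    truth <- build_genome(spec, library = config$library, seed = gseed)
    bundle$truths[[spec$name]] <- truth
    L <- Biostrings::width(truth$genome)[1]
    chrom_lengths[spec$name] <- L
    peaks_ct <- list()
    for (ct in panel) {
      stage <- stage + 1L
      rseed <- derive_seed(config$seed, stage)
      seeds[[paste0("reads_", spec$name, "_", ct)]] <- rseed
      sim <- simulate_reads(truth, ct,
                            reads_per_bound_site = config$reads_per_bound_site,
                            read_len = config$read_len,
                            frag_len = config$frag_len,
                            background_rate = config$background_rate,
                            seed = rseed)
      if (nrow(truth$sites) == 0L && !nrow(truth$duplication_map)) {
        # site-free, repeat-free chromosome: every background read places
        # uniquely at its origin, so the simulated coverage already equals
        # the placed coverage (up to vanishing chance cross-mapping)
        cov <- sim$coverage
        pl <- list(placements = data.frame())
      } else {
        pl <- place_reads(sim$reads, truth$genome, v_max = config$v_max,
                          m_max = config$m_max)
        cov <- coverage_from_placements(pl$placements,
                                        stats::setNames(L, spec$name),
                                        extend_to = config$frag_len,
                                        weight = config$weight)
      }
      pk <- call_peaks(cov[[spec$name]], window = config$window,
                       fdr_max = config$fdr_max, p_max = config$p_max,
                       frag_len = config$frag_len)
      pk$cell_type <- if (nrow(pk)) ct else character(0)
      peaks_ct[[ct]] <- pk
      all_peaks_by_ct[[ct]] <- rbind(all_peaks_by_ct[[ct]], pk)
      if (verbose)
        message(sprintf("%s / %s: %d reads, %d placed, %d peaks",
                        spec$name, ct, nrow(sim$reads), nrow(pl$placements),
                        nrow(pk)))
    }
    bundle$peaks[[spec$name]] <- peaks_ct
    merged <- merge_peak_sets(peaks_ct, min_overlap = config$min_overlap)
    bundle$merged[[spec$name]] <- merged
    bundle$classes[[spec$name]] <-
      if (nrow(merged$intervals))
        classify_specificity(merged$presence, config$panel, config$groupings)
      else character(0)
    ldef <- locus_definition(spec)
    orient_ct <- list()
    for (ct in panel) {
      pk <- peaks_ct[[ct]]
      if (!nrow(pk)) {
        orient_ct[[ct]] <- NULL
        next
      }
      orc <- orient_peak_set(pk, truth$genome, config$library,
                             mode = config$mode)
      rel <- orientation_relative_to_locus(orc$peaks, ldef)
      orient_ct[[ct]] <- list(result = orc, relative = rel)
    }
    bundle$orientation[[spec$name]] <- orient_ct
    rct <- spec$rearranging %||% panel[1]
    anch <- orient_ct[[rct]]$result$stranded
    if (!is.null(anch) && nrow(anch) >= 2L) {
      bundle$loops[[spec$name]] <- predict_extrusion_loops(anch)
      bundle$census[[spec$name]] <- geometry_census(anch)
    }
  }
  # V-region peak counts per locus x cell type
  counts <- do.call(rbind, lapply(names(specs), function(nm) {
    v <- locus_definition(specs[[nm]])$v_region
    data.frame(locus = nm, cell_type = panel,
               v_peaks = vapply(panel, function(ct)
                 count_peaks_in_region(bundle$peaks[[nm]][[ct]], v),
                 integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  bundle$counts <- counts
  # bin-based enrichment of every locus against genome-wide peaks
  enr <- list()
  for (nm in names(specs)) {
    span <- locus_definition(specs[[nm]])$span
    for (ct in panel) {
      e <- locus_enrichment(all_peaks_by_ct[[ct]] %||%
                              bundle$peaks[[nm]][[ct]][0, ],
                            chrom_lengths, span, bin_size = config$bin_size)
      enr[[length(enr) + 1L]] <- data.frame(
        locus = nm, cell_type = ct, N = e$population_bins, K = e$locus_bins,
        n = e$total_peaks, k = e$locus_peaks, p_value = e$p_value,
        stringsAsFactors = FALSE)
    }
  }
  bundle$enrichment <- do.call(rbind, enr)
  bundle$manifest <- list(
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("specs", "panel", "groupings",
                                           "library"))],
    loci = names(specs), panel = panel, seeds = seeds)
  bundle
}

#' Summary report of a pipeline bundle
#'
#' One row per (locus, cell type): peak count, orientation-call counts,
#' motif-match percentage (NA when the cell type called no peaks),
#' toward/away tally relative to the locus's D-J-C end, and the locus
#' enrichment p-value.  Column order is fixed across runs.
#'
#' @param bundle a [run_pipeline()] result.
#' @return data frame.
#' @export
make_report <- function(bundle) {
  stopifnot(is.list(bundle), !is.null(bundle$peaks))
  panel <- as.character(bundle$config$panel)
  rows <- list()
  for (nm in names(bundle$peaks)) {
    for (ct in panel) {
      pk <- bundle$peaks[[nm]][[ct]]
      o <- bundle$orientation[[nm]][[ct]]
      if (!is.null(o)) {
        cnt <- o$result$counts
        mm <- motif_match_fraction(o$result$peaks)
        tal <- o$relative$tally
      } else {
        cnt <- c(forward = 0L, reverse = 0L, ambiguous = 0L, no_motif = 0L)
        mm <- list(percent = NA_real_)
        tal <- c(toward = 0L, away = 0L)
      }
      ep <- bundle$enrichment$p_value[bundle$enrichment$locus == nm &
                                        bundle$enrichment$cell_type == ct]
      rows[[length(rows) + 1L]] <- data.frame(
        locus = nm, cell_type = ct, n_peaks = nrow(pk),
        forward = cnt[["forward"]], reverse = cnt[["reverse"]],
        ambiguous = cnt[["ambiguous"]], no_motif = cnt[["no_motif"]],
        pct_with_motif = mm$percent, toward_djc = tal[["toward"]],
        away_from_djc = tal[["away"]],
        enrichment_p = if (length(ep)) ep else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
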