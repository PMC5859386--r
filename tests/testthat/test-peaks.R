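# Peak caller, merging, specificity rules, counting, enrichment, fractions.

test_that("null and degenerate tracks yield no peaks; a strong spike yields one", {
  flat <- coverage_track("c", rep(2.5, 20000))
  expect_equal(nrow(call_peaks(flat)), 0L)
  zero <- coverage_track("c", rep(0, 20000))
  expect_equal(nrow(call_peaks(zero)), 0L)
  v <- rep(0.1 * 147, 20000)       # background 0.1 fragments/bp
  v[9000:9300] <- 50 * 0.1 * 147   # 50x rectangular spike
  pk <- call_peaks(coverage_track("c", v))
  expect_equal(nrow(pk), 1L)
  expect_lte(pk$start, 9000 - 1)
  expect_gte(pk$end, 9300)
  expect_true(pk$summit >= 8999 & pk$summit < 9300)
  expect_lt(pk$p_value, 1e-5)
  expect_error(call_peaks(flat, control = coverage_track("c", rep(1, 10))),
               "mismatched")
})

test_that("a matched control lifts the local rate and suppresses shared signal", {
  v <- rep(1, 20000)
  v[5000:5200] <- 30
  sample_t <- coverage_track("c", v)
  expect_equal(nrow(call_peaks(sample_t)), 1L)
  expect_equal(nrow(call_peaks(sample_t, control = sample_t)), 0L)
})

test_that("merging equals the transitive-closure oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:6) {
    n <- 20L
    starts <- sample.int(2000, n)
    ends <- starts + sample(20:200, n, replace = TRUE)
    sets <- split(seq_len(n), sample(c("ct1", "ct2", "ct3"), n, replace = TRUE))
    peak_sets <- lapply(sets, function(i)
      data.frame(chrom = "c", start = starts[i], end = ends[i],
                 name = sprintf("p%d", i), score = 1, strand = ".",
                 summit = starts[i], p_value = 0, q_value = 0,
                 stringsAsFactors = FALSE))
    res <- merge_peak_sets(peak_sets, min_overlap = 1L)
    comp <- oracle_merge_clusters(starts, ends, 1L)
    expect_equal(nrow(res$intervals), length(unique(comp)))
    # cluster spans agree
    oracle_spans <- sort(vapply(unique(comp), function(cc)
      paste(min(starts[comp == cc]), max(ends[comp == cc])), character(1)))
    got_spans <- sort(paste(res$intervals$start, res$intervals$end))
    expect_equal(got_spans, oracle_spans)
  }
})

test_that("a chained overlap A-B-C merges into one interval present in all", {
  ps <- list(A = data.frame(chrom = "c", start = 0L, end = 100L, name = "a",
                            summit = 50L, stringsAsFactors = FALSE),
             B = data.frame(chrom = "c", start = 90L, end = 200L, name = "b",
                            summit = 150L, stringsAsFactors = FALSE),
             C = data.frame(chrom = "c", start = 190L, end = 300L, name = "c",
                            summit = 250L, stringsAsFactors = FALSE))
  res <- merge_peak_sets(ps)
  expect_equal(nrow(res$intervals), 1L)
  expect_true(all(res$presence[1, ]))
  expect_equal(res$intervals$start, 0L)
  expect_equal(res$intervals$end, 300L)
  # disjoint peaks stay separate
  ps2 <- list(A = data.frame(chrom = "c", start = 0L, end = 50L, name = "a",
                             summit = 10L, stringsAsFactors = FALSE),
              B = data.frame(chrom = "c", start = 60L, end = 100L, name = "b",
                             summit = 70L, stringsAsFactors = FALSE))
  res2 <- merge_peak_sets(ps2)
  expect_equal(nrow(res2$intervals), 2L)
  expect_equal(unname(colSums(res2$presence)), c(1L, 1L))
})

test_that("abutting peaks are not merged under literal overlap", {
  ps <- list(A = data.frame(chrom = "c", start = 0L, end = 100L, name = "a",
                            summit = 50L, stringsAsFactors = FALSE),
             B = data.frame(chrom = "c", start = 100L, end = 200L, name = "b",
                            summit = 150L, stringsAsFactors = FALSE))
  expect_equal(nrow(merge_peak_sets(ps, min_overlap = 1L)$intervals), 2L)
})

test_that("specificity rules follow the documented precedence and are total", {
  panel <- cell_type_panel()
  grp <- default_groupings(panel)
  mk <- function(present) {
    m <- matrix(as.character(panel) %in% present, nrow = 1,
                dimnames = list("iv", as.character(panel)))
    unname(classify_specificity(m, panel, grp))
  }
  expect_equal(mk(as.character(panel)), "ubiquitous")
  expect_equal(mk(c("pro_B", "pre_B", "DN", "DP", "mature_B", "mature_T")),
               "lymphocyte_specific")
  expect_equal(mk("pre_B"), "stage_specific")
  expect_equal(mk(c("pro_B", "pre_B")), "B_lineage")
  expect_equal(mk(c("DN", "DP", "mature_T")), "T_lineage")
  expect_equal(mk(c("pre_B", "ES")), "mixed")
  # totality: every nonempty presence pattern maps to exactly one class
  set.seed(5)
  classes <- c("ubiquitous", "lymphocyte_specific", "B_lineage", "T_lineage",
               "stage_specific", "mixed")
  for (i in 1:100) {
    pr <- sample(as.character(panel), sample(1:9, 1))
    expect_true(mk(pr) %in% classes)
  }
  expect_error(classify_specificity(
    matrix(TRUE, 1, 1, dimnames = list("iv", "other")), panel, grp),
    "missing")
})

test_that("peak counting uses summit membership with half-open bounds", {
  region <- intervals("c", 100L, 200L)
  pk <- data.frame(chrom = "c", summit = c(100L, 150L, 200L, 99L),
                   stringsAsFactors = FALSE)
  expect_equal(count_peaks_in_region(pk, region), 2L)
  expect_equal(count_peaks_in_region(pk[0, ], region), 0L)
})

test_that("hypergeometric tail matches combinatorial enumeration", {
  # the spec's worked example: C(5,4) C(5,0) / C(10,4) = 5/210
  r <- hypergeometric_enrichment(10, 5, 4, 4)
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeometric_enrichment(10, 5, 4, 0)$p_value, 1)
  expect_error(hypergeometric_enrichment(10, 5, 4, 5), "impossible")
  # random spot checks against the enumeration oracle
  set.seed(8)
  for (i in 1:50) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeometric_enrichment(N, K, n, k)$p_value,
                 max(oracle_hyper_tail(k, N, K, n), .Machine$double.xmin),
                 tolerance = 1e-12)
  }
})

test_that("enrichment tail is monotone decreasing in k", {
  p <- vapply(0:15, function(k)
    hypergeometric_enrichment(100, 20, 15, k)$p_value, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("binned locus enrichment counts bins, not peaks", {
  # two summits in one bin count once
  pk <- data.frame(chrom = "c", summit = c(100L, 900L, 5100L),
                   stringsAsFactors = FALSE)
  e <- locus_enrichment(pk, c(c = 20000L), intervals("c", 0L, 1000L),
                        bin_size = 1000L)
  expect_equal(e$total_peaks, 2L)     # bins 0 and 5
  expect_equal(e$locus_peaks, 1L)
  expect_equal(e$locus_bins, 1L)
  expect_equal(e$population_bins, 20L)
})

test_that("motif-match percentages reproduce one-decimal rounding", {
  expect_equal(motif_match_percent(42250, 34560), 81.8)
  expect_equal(motif_match_percent(121, 115), 95.0)
  expect_equal(motif_match_percent(5, 0), 0.0)
  df <- data.frame(call = c("forward", "reverse", "ambiguous", "no_motif"))
  mf <- motif_match_fraction(df)
  expect_equal(mf$with_motif, 3L)     # ambiguous had motifs
  expect_equal(mf$percent, 75.0)
  expect_error(motif_match_fraction(df[0, , drop = FALSE]), "undefined")
})

test_that("caller respects nominal FDR on pure-null tracks", {
  # 60 null replicates at this granularity; the acceptance suite runs 200
  set.seed(123)
  spec <- tiny_spec(occ = list(null = numeric(0)), length = 20000L)
  n_false <- 0L
  n_reps <- 60L
  for (i in seq_len(n_reps)) {
    truth <- build_genome(spec, seed = 1000 + i)
    sim <- simulate_reads(truth, "null", background_rate = 0.05,
                          seed = 2000 + i)
    pk <- call_peaks(sim$coverage$tiny)
    n_false <- n_false + (nrow(pk) > 0L)
  }
  expect_lte(n_false / n_reps, 3 * 0.01)
})
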