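# Orientation calling: voting rules, strand symmetry, stranded output.

test_that("voting implements strict majority, ties, and no-motif", {
  mk_hits <- function(strands, motifs = NULL, scores = NULL) {
    n <- length(strands)
    data.frame(peak = "p", motif = motifs %||% sprintf("m%d", seq_len(n)),
               start = seq(0, by = 50, length.out = n),
               end = seq(0, by = 50, length.out = n) + 15,
               strand = strands, score = scores %||% rep(10, n),
               stringsAsFactors = FALSE)
  }
  expect_equal(assign_orientation(mk_hits("+"))$call, "forward")
  expect_equal(assign_orientation(mk_hits(c("+", "-")))$call, "ambiguous")
  expect_equal(assign_orientation(mk_hits(c("+", "+", "-")))$call, "forward")
  expect_equal(assign_orientation(mk_hits(c("-", "-", "+")))$call, "reverse")
  a <- assign_orientation(mk_hits("+")[0, ])
  expect_equal(a$call, "no_motif")
  expect_equal(unname(a$votes), c(0L, 0L))
})

test_that("overlapping same-motif same-strand hits collapse to one vote", {
  h <- data.frame(peak = "p", motif = "m1",
                  start = c(0L, 5L, 100L), end = c(15L, 20L, 115L),
                  strand = "+", score = c(8, 12, 9),
                  stringsAsFactors = FALSE)
  a <- assign_orientation(h)
  expect_equal(unname(a$votes[["plus"]]), 2L)   # two separated instances
  expect_equal(nrow(a$hits), 2L)
  expect_equal(max(a$hits$score), 12)           # best-scoring kept
})

test_that("per-motif-best voting counts models, not instances", {
  h <- data.frame(peak = "p", motif = c("m1", "m1", "m2"),
                  start = c(0L, 100L, 200L), end = c(15L, 115L, 215L),
                  strand = c("+", "+", "-"), score = c(8, 9, 20),
                  stringsAsFactors = FALSE)
  expect_equal(assign_orientation(h, mode = "per_instance")$call, "forward")
  a <- assign_orientation(h, mode = "per_motif_best")
  expect_equal(a$call, "ambiguous")   # one model each way
})

test_that("peak orientation recovers planted strands and discards ties", {
  lib <- default_ctcf_library()
  # genome with a forward site, a reverse site, a fw+rv pair, and nothing
  c1 <- motif_consensus(lib[[1]])
  c2 <- motif_consensus(lib[[2]])
  segs <- c(paste0(random_dna(120, seed = 61), c1),
            paste0(random_dna(120, seed = 62), reverse_complement(c2)),
            paste0(random_dna(120, seed = 63), c1, "ACGTAC",
                   reverse_complement(c1)),
            random_dna(150, seed = 64))
  genome <- Biostrings::DNAStringSet(paste(segs, collapse = ""))
  names(genome) <- "chr"
  ends <- cumsum(nchar(segs))
  starts <- c(0L, ends[-4])
  pk <- intervals("chr", starts, ends, name = sprintf("p%d", 1:4))
  res <- orient_peak_set(pk, genome, lib)
  expect_equal(res$peaks$call,
               c("forward", "reverse", "ambiguous", "no_motif"))
  expect_equal(res$counts,
               c(forward = 1L, reverse = 1L, ambiguous = 1L, no_motif = 1L))
  # stranded output keeps only oriented calls and never strand "."
  expect_equal(nrow(res$stranded), 2L)
  expect_true(all(res$stranded$strand %in% c("+", "-")))
  # round-trips through interval IO
  path <- withr::local_tempfile()
  write_intervals(res$stranded, path)
  expect_equal(read_intervals(path), res$stranded)
})

test_that("orienting the reverse-complemented genome flips every call", {
  lib <- default_ctcf_library()
  truth <- build_genome(tiny_spec(), seed = 14)
  g <- truth$genome
  pk <- intervals("tiny", truth$sites$start - 50L, truth$sites$end + 50L,
                  name = "pk1")
  res <- orient_peak_set(pk, g, lib)
  expect_equal(res$peaks$call, "forward")
  # mirror genome and peak
  L <- Biostrings::width(g)[1]
  grc <- Biostrings::DNAStringSet(reverse_complement(as.character(g[[1]])))
  names(grc) <- "tiny"
  pk_rc <- intervals("tiny", L - pk$end, L - pk$start, name = "pk1")
  res_rc <- orient_peak_set(pk_rc, grc, lib)
  expect_equal(res_rc$peaks$call, "reverse")
  expect_equal(unname(res$peaks$votes_plus), unname(res_rc$peaks$votes_minus))
})

test_that("direction relative to the locus follows polarity", {
  or <- data.frame(chrom = "x", start = c(10L, 60L), end = c(30L, 80L),
                   name = c("a", "b"), score = 0,
                   strand = c("+", "-"), call = c("forward", "reverse"),
                   stringsAsFactors = FALSE)
  right <- locus_spec("x", 1000L, c(0L, 500L), c(600L, 900L), "right",
                      data.frame(name = character(0), pos = integer(0),
                                 strand = character(0), motif = character(0)),
                      occupancy = list())
  rel <- orientation_relative_to_locus(or, right)
  expect_equal(rel$per_peak$direction, c("toward_DJC", "away_from_DJC"))
  expect_equal(unname(rel$tally), c(1L, 1L))
  left <- locus_spec("x", 1000L, c(600L, 900L), c(0L, 500L), "left",
                     data.frame(name = character(0), pos = integer(0),
                                strand = character(0), motif = character(0)),
                     occupancy = list())
  rel2 <- orientation_relative_to_locus(or, left)
  expect_equal(rel2$per_peak$direction, c("away_from_DJC", "toward_DJC"))
  # ambiguous / no-motif rows are excluded
  or$call <- c("ambiguous", "no_motif")
  expect_equal(nrow(orientation_relative_to_locus(or, right)$per_peak), 0L)
})
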