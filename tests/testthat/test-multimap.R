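# Placement policy: oracle equivalence, stratum/cap rules, monotonicity,
# coverage semantics.

test_that("placement agrees with the brute-force oracle on small genomes", {
  set.seed(42)
  for (rep in 1:5) {
    g <- list(cA = random_dna(400, seed = 100 + rep),
              cB = random_dna(300, seed = 200 + rep))
    # reads drawn from the genome plus one random read
    r1 <- substr(g$cA, 51, 80)
    r2 <- reverse_complement(substr(g$cB, 101, 130))
    r3 <- random_dna(30, seed = 300 + rep)
    for (read in c(r1, r2, r3)) {
      for (v in 0:2) {
        res <- place_reads(read, unlist(g), v_max = v, m_max = 1000L)
        orc <- oracle_place(read, g, v)
        if (is.null(orc)) {
          expect_equal(nrow(res$placements), 0L)
        } else {
          best <- min(orc$mismatches)
          orc <- orc[orc$mismatches == best, ]
          orc <- orc[order(orc$chrom, orc$start, orc$strand), ]
          got <- res$placements[order(res$placements$chrom,
                                      res$placements$start,
                                      res$placements$strand), ]
          expect_equal(got$chrom, orc$chrom)
          expect_equal(got$start, orc$start)
          expect_equal(got$strand, orc$strand)
          expect_equal(got$mismatches, orc$mismatches)
        }
      }
    }
  }
})

test_that("best stratum masks worse placements and the cap discards multi-reads", {
  # one exact occurrence and one 2-mismatch occurrence of the same 20-mer
  core <- random_dna(20, seed = 17)
  mut <- core
  substr(mut, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(core, 5, 5))[1]
  substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(core, 15, 15))[1]
  pad <- function(s) paste0(random_dna(50, seed = nchar(s)), s,
                            random_dna(50, seed = nchar(s) + 1))
  genome <- c(chr = paste0(pad(core), pad(mut)))
  res <- place_reads(core, genome, v_max = 2L, m_max = 10L)
  expect_equal(nrow(res$placements), 1L)       # only the 0-mismatch stratum
  expect_equal(res$placements$mismatches, 0L)
  # identical triplicate: cap 1 discards, cap 3 keeps all three
  tri <- c(chr = paste0(pad(core), pad(core), pad(core)))
  expect_equal(nrow(place_reads(core, tri, 2L, 3L)$placements), 3L)
  r1 <- place_reads(core, tri, 2L, 1L)
  expect_equal(nrow(r1$placements), 0L)
  expect_length(r1$discarded, 1L)
})

test_that("retained placements are monotone in m_max and v_max", {
  truth <- triplicate_truth(seed = 31)
  sim <- simulate_reads(truth, "DN", reads_per_bound_site = 20,
                        background_rate = 0.01, seed = 32)
  sub <- sim$reads[seq_len(min(150, nrow(sim$reads))), ]
  n_prev <- -1
  for (m in c(1L, 2L, 3L, 4L)) {
    n <- length(unique(place_reads(sub, truth$genome, 2L, m)$placements$read_id))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  n_v <- vapply(0:2, function(v)
    length(unique(place_reads(sub, truth$genome, v, 3L)$placements$read_id)),
    numeric(1))
  expect_true(all(diff(n_v) >= 0))
})

test_that("coverage extends from the 5' end, sums correctly, clips at edges", {
  pl <- data.frame(read_id = "r1", chrom = "c", start = 10L, end = 60L,
                   strand = "+", mismatches = 0L, stringsAsFactors = FALSE)
  cov <- coverage_from_placements(pl, c(c = 300L), extend_to = 147L)
  expect_equal(sum(cov$c$values), 147)
  expect_equal(which(cov$c$values == 1), 11:157)
  # minus strand: extends leftwards from the alignment's right edge
  pl$strand <- "-"
  pl$start <- 200L; pl$end <- 250L
  cov <- coverage_from_placements(pl, c(c = 300L), extend_to = 147L)
  expect_equal(which(cov$c$values == 1), (250 - 147 + 1):250)
  # additivity and conservation under clipping
  pl2 <- data.frame(read_id = c("a", "b"), chrom = "c",
                    start = c(0L, 50L), end = c(50L, 100L), strand = "+",
                    mismatches = 0L, stringsAsFactors = FALSE)
  cov <- coverage_from_placements(pl2, c(c = 120L), extend_to = 100L)
  expect_equal(max(cov$c$values), 2)
  expect_equal(sum(cov$c$values), 100 + (120 - 50))   # second read clipped
  # empty placements: all-zero track
  cov0 <- coverage_from_placements(pl2[0, ], c(c = 50L), extend_to = 100L)
  expect_true(all(cov0$c$values == 0))
})

test_that("fractional weighting splits a multi-read across its placements", {
  pl <- data.frame(read_id = "r", chrom = "c", start = c(0L, 100L),
                   end = c(20L, 120L), strand = "+", mismatches = 0L,
                   stringsAsFactors = FALSE)
  cov <- coverage_from_placements(pl, c(c = 200L), extend_to = 20L,
                                  weight = "fractional")
  expect_equal(sum(cov$c$values), 20)    # total mass one read
  expect_equal(max(cov$c$values), 0.5)
})

test_that("copy coverage collapses at cap 1 and matches control at cap 3", {
  truth <- triplicate_truth(seed = 5, divergence = 0)
  sim <- simulate_reads(truth, "DN", reads_per_bound_site = 60,
                        background_rate = 0.25, seed = 6)
  tab <- compare_mapping_policies(truth, sim$reads, v_max = 2L,
                                  m_list = c(1L, 3L))
  copy3 <- tab$mean_coverage[tab$m == 3 & grepl("^copy", tab$region)]
  ctrl3 <- tab$mean_coverage[tab$m == 3 & tab$region == "control"]
  expect_true(all(abs(copy3 / ctrl3 - 1) < 0.1))
  copy1 <- tab$mean_coverage[tab$m == 1 & grepl("^copy", tab$region)]
  bg1 <- tab$mean_coverage[tab$m == 1 & tab$region == "background"]
  expect_true(all(copy1 < 0.05 * bg1))   # all multi-reads discarded
})

test_that("mild divergence restores intermediate coverage at cap 1", {
  truth <- triplicate_truth(seed = 5, divergence = 0.02)
  sim <- simulate_reads(truth, "DN", reads_per_bound_site = 60,
                        background_rate = 0.25, seed = 6)
  tab <- compare_mapping_policies(truth, sim$reads, v_max = 2L,
                                  m_list = c(1L, 3L))
  copy1 <- mean(tab$mean_coverage[tab$m == 1 & tab$region %in%
                                    c("copy_1", "copy_2")])
  copy3 <- mean(tab$mean_coverage[tab$m == 3 & tab$region %in%
                                    c("copy_1", "copy_2")])
  # some reads regain uniqueness: strictly between the identical-copy
  # cap-1 collapse (~0) and the cap-3 level
  expect_gt(copy1, 0.05 * copy3)
  expect_lt(copy1, 0.95 * copy3)
})
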