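# Synthetic genome and read generator: determinism, planted-site recovery,
# occupancy scaling, read-count conservation.

test_that("genome construction is deterministic and plants recoverable sites", {
  spec <- tiny_spec()
  t1 <- build_genome(spec, seed = 11)
  t2 <- build_genome(spec, seed = 11)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  t3 <- build_genome(spec, seed = 12)
  expect_false(identical(as.character(t1$genome), as.character(t3$genome)))
  # the planted site, rescanned with the generating motif, exceeds the
  # detection threshold on the recorded strand
  lib <- default_ctcf_library()
  g <- as.character(t1$genome[[1]])
  st <- t1$sites
  h <- scan_sequence(substr(g, st$start + 1, st$end), lib)
  expect_true(any(h$motif == st$motif & h$strand == st$strand))
})

test_that("minus-strand sites are planted as reverse complements", {
  spec <- tiny_spec(strand = "-")
  truth <- build_genome(spec, seed = 4)
  lib <- default_ctcf_library()
  m <- lib[[1]]
  g <- as.character(truth$genome[[1]])
  planted <- substr(g, truth$sites$start + 1, truth$sites$end)
  expect_equal(planted, reverse_complement(motif_consensus(m)))
})

test_that("generator rejects overlapping or boundary-straddling sites", {
  sites <- data.frame(name = c("a", "b"), pos = c(1000L, 1005L),
                      strand = "+", motif = "ctcf_db1",
                      stringsAsFactors = FALSE)
  spec <- locus_spec("x", 6000L, c(500L, 4000L), c(4500L, 5500L), "right",
                     sites, occupancy = list())
  expect_error(build_genome(spec), "overlapping")
  sites2 <- data.frame(name = "a", pos = 1995L, strand = "+",
                       motif = "ctcf_db1", stringsAsFactors = FALSE)
  spec2 <- locus_spec("x", 9000L, c(100L, 900L), c(8000L, 8900L), "right",
                      sites2, occupancy = list(),
                      duplication = list(template = c(1000L, 2000L),
                                         n_copies = 3L, divergence = 0))
  expect_error(build_genome(spec2), "straddles")
})

test_that("zero divergence yields identical copies; copy sites are projected", {
  truth <- triplicate_truth(seed = 8, divergence = 0)
  g <- as.character(truth$genome[[1]])
  dm <- truth$duplication_map
  tpl <- substr(g, dm$start[1] + 1, dm$end[1])
  for (i in 2:3)
    expect_equal(substr(g, dm$start[i] + 1, dm$end[i]), tpl)
  expect_equal(nrow(truth$copy_sites), 2L)   # one template site x two copies
  expect_equal(truth$copy_sites$template, c("dup", "dup"))
})

test_that("site read counts scale with occupancy and conserve totals", {
  # 120 fully occupied sites: mean read count within 3 SE of the rate
  n_sites <- 120L
  pos <- seq(1000L, by = 400L, length.out = n_sites)
  sites <- data.frame(name = sprintf("s%03d", seq_len(n_sites)), pos = pos,
                      strand = "+",
                      motif = rep(c("ctcf_db1", "ctcf_db2"), length.out = n_sites),
                      stringsAsFactors = FALSE)
  L <- as.integer(max(pos) + 2000L)
  occ1 <- stats::setNames(rep(1, n_sites), sites$name)
  spec <- locus_spec("many", L, c(100L, L - 1000L), c(L - 900L, L - 100L),
                     "right", sites,
                     occupancy = list(full = occ1,
                                      quarter = occ1 * 0.25,
                                      none = occ1 * 0))
  truth <- build_genome(spec, seed = 2)
  rate <- 30
  sim <- simulate_reads(truth, "full", reads_per_bound_site = rate,
                        background_rate = 0, seed = 3)
  m <- mean(sim$n_site_reads)
  se <- sqrt(rate / n_sites)
  expect_lt(abs(m - rate), 3 * se)
  # conservation: total reads = site draws + background draws
  expect_equal(nrow(sim$reads), sum(sim$n_site_reads) + sim$n_background)
  # occupancy 0.25 vs 1.0: total site reads ratio ~ 4 within sampling error
  simq <- simulate_reads(truth, "quarter", reads_per_bound_site = rate,
                         background_rate = 0, seed = 4)
  ratio <- sum(sim$n_site_reads) / sum(simq$n_site_reads)
  expect_lt(abs(ratio - 4), 0.5)
  # occupancy 0: no site reads at all
  sim0 <- simulate_reads(truth, "none", reads_per_bound_site = rate,
                         background_rate = 0.01, seed = 5)
  expect_equal(sum(sim0$n_site_reads), 0L)
  expect_error(simulate_reads(truth, "nosuch"), "unknown cell type")
})

test_that("read simulation is deterministic and coverage matches the read set", {
  truth <- build_genome(tiny_spec(), seed = 6)
  s1 <- simulate_reads(truth, "DN", seed = 9)
  s2 <- simulate_reads(truth, "DN", seed = 9)
  expect_identical(s1$reads, s2$reads)
  # conservation of coverage mass: reads x extension, no boundary clipping here
  expect_equal(sum(s1$coverage$tiny$values), nrow(s1$reads) * 147)
})

test_that("default panel encodes the designed contrasts", {
  pd <- default_agr_panel()
  expect_length(pd$specs, 5L)
  igh <- pd$specs$igh_like
  v <- igh$sites[grepl("^igh_v", igh$sites$name), ]
  expect_true(all(v$strand == "+"))           # all V sites toward D-J-C
  tcrad <- pd$specs$tcrad_like
  v <- tcrad$sites[tcrad$sites$pos < tcrad$v_region[2], ]
  toward <- mean(v$strand == "+")
  expect_gte(toward, 0.85)                    # great majority toward J-C
  expect_lt(toward, 1)                        # but a minority opposite
  igk <- pd$specs$igk_like
  vn <- grep("^igk_v", igk$sites$name, value = TRUE)
  expect_gt(igk$occupancy$pre_B[vn[1]], 0.5)
  expect_lte(igk$occupancy$pro_B[vn[1]], 0.05)
  expect_false(any(vn %in% names(igk$occupancy$MEF)))
  expect_false(is.null(tcrad$duplication))
  expect_equal(tcrad$duplication$n_copies, 3L)
})
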