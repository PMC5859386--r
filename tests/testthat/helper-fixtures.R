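# Shared fixtures, independent oracles, and a memoised end-to-end run of the
# default panel (built once, reused by every test that needs it).

.fixture_env <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force placement oracle: every offset, both strands, count mismatches
oracle_place <- function(read, chroms, v_max) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (ci in seq_along(chroms)) {
    g <- strsplit(chroms[[ci]], "")[[1]]
    for (strand in c("+", "-")) {
      q <- strsplit(if (strand == "+") read else rc(read), "")[[1]]
      for (off in 0:(length(g) - length(q))) {
        mm <- sum(q != g[(off + 1):(off + length(q))])
        if (mm <= v_max)
          out[[length(out) + 1L]] <- data.frame(
            chrom = names(chroms)[ci], start = off, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# exact hypergeometric upper tail by direct combinatorial enumeration
oracle_hyper_tail <- function(k, N, K, n) {
  j <- max(k, 0):min(K, n)
  if (!length(j) || k > min(K, n)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# transitive-closure clustering oracle via boolean reachability
oracle_merge_clusters <- function(starts, ends, min_overlap = 1L) {
  n <- length(starts)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    pmin(ends[i], ends[j]) - pmax(starts[i], starts[j]) >= min_overlap)
  reach <- adj
  repeat {
    new <- reach | (reach %*% reach > 0)
    if (identical(new, reach)) break
    reach <- new
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# brute-force loop-prediction oracle: nearest downstream minus anchor
oracle_loops <- function(starts, strands) {
  out <- list()
  for (i in seq_along(starts)) {
    if (strands[i] != "+") next
    down <- which(seq_along(starts) > i & strands == "-")
    if (!length(down)) next
    j <- down[which.min(starts[down])]
    out[[length(out) + 1L]] <- c(left = i, right = j, n_between = j - i - 1L)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# brute-force geometry census over all ordered pairs
oracle_census <- function(strands) {
  counts <- c(convergent = 0L, tandem = 0L, divergent = 0L)
  n <- length(strands)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      g <- if (strands[i] == strands[j]) "tandem"
           else if (strands[i] == "+") "convergent" else "divergent"
      counts[g] <- counts[g] + 1L
    }
  }
  counts
}

# small single-site locus used across module tests
tiny_spec <- function(occ = list(DN = c(s1 = 1)), length = 6000L,
                      pos = 3000L, strand = "+", motif = "ctcf_db1") {
  locus_spec("tiny", length, v_region = c(500L, 4000L),
             djc_region = c(4500L, 5500L), polarity = "right",
             sites = data.frame(name = "s1", pos = pos, strand = strand,
                                motif = motif, stringsAsFactors = FALSE),
             occupancy = occ)
}

# identical-triplicate locus for the mapping-policy tests
triplicate_truth <- function(seed = 5, divergence = 0) {
  sites <- data.frame(name = c("ctrl", "dup"), pos = c(2500L, 10500L),
                      strand = "+", motif = c("ctcf_db1", "ctcf_db2"),
                      stringsAsFactors = FALSE)
  spec <- locus_spec("trip", 27000L, v_region = c(500L, 26000L),
                     djc_region = c(26200L, 26900L), polarity = "right",
                     sites = sites, occupancy = list(DN = c(ctrl = 1, dup = 1)),
                     duplication = list(template = c(8000L, 14000L),
                                        n_copies = 3L,
                                        divergence = divergence))
  build_genome(spec, seed = seed)
}

# full default-panel pipeline run, built once per test session
default_bundle <- function() {
  memo("bundle", run_pipeline(pipeline_config(seed = 20260920L)))
}

# per-locus planted-site recovery against a bundle's oriented peaks
recovery_table <- function(bundle) {
  out <- list()
  for (nm in names(bundle$truths)) {
    truth <- bundle$truths[[nm]]
    if (!nrow(truth$sites)) next
    ct <- bundle$config$specs[[nm]]$rearranging
    o <- bundle$orientation[[nm]][[ct]]$result$peaks
    st <- truth$sites
    mid <- (st$start + st$end) %/% 2L
    pk_idx <- vapply(mid, function(m) {
      j <- which(o$start <= m & o$end > m)
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
    recovered <- !is.na(pk_idx) &
      o$call[ifelse(is.na(pk_idx), 1L, pk_idx)] %in% c("forward", "reverse")
    sign_ok <- recovered &
      o$strand[ifelse(is.na(pk_idx), 1L, pk_idx)] == st$strand
    out[[nm]] <- data.frame(locus = nm, site = st$name, strand = st$strand,
                            recovered = recovered,
                            sign_error = recovered & !sign_ok,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
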