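make_ev <- function(junctions, read_ids = sprintf("r%03d", seq_along(junctions)),
                    insert_seqs = strrep("A", 20)) {
  data.frame(read_id = read_ids,
             contig = rep("c1", length(junctions)),
             junction = junctions,
             insert_seq = rep_len(insert_seqs, length(junctions)),
             query_start = rep(0L, length(junctions)))
}

test_that("single-linkage clustering partitions by junction gaps", {
  cl <- cluster_inserts(make_ev(c(98L, 100L, 102L)), max_cluster_dist = 5)
  expect_equal(length(unique(cl$cluster)), 1L)
  expect_equal(cluster_table(cl)$mode_junction, 98L)  # all unique -> leftmost

  cl2 <- cluster_inserts(make_ev(c(100L, 120L)), max_cluster_dist = 5)
  expect_equal(length(unique(cl2$cluster)), 2L)

  expect_equal(nrow(cluster_inserts(make_ev(integer(0),
                                            read_ids = character(0),
                                            insert_seqs = character(0)),
                                    5)), 0L)
})

test_that("clustering equals brute-force transitive closure", {
  set.seed(11)
  closure_partition <- function(junctions, d) {
    n <- length(junctions)
    adj <- abs(outer(junctions, junctions, "-")) <= d
    lab <- seq_len(n)
    repeat {
      new <- vapply(seq_len(n), function(i) min(lab[adj[i, ]]), 0L)
      if (identical(new, lab)) break
      lab <- new
    }
    lab
  }
  for (i in 1:25) {
    n <- sample(10:120, 1)
    d <- sample(1:20, 1)
    junctions <- sort(sample(0:2000, n, replace = TRUE))
    ev <- make_ev(junctions)
    cl <- cluster_inserts(ev, d)
    got <- cl$cluster[match(sprintf("r%03d", seq_len(n)), cl$read_id)]
    want <- closure_partition(junctions, d)
    # same partition up to labelling
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(got, want, function(x) length(unique(x))) == 1))
  }
})

test_that("duplicate reads collapse to their longest insert", {
  ev <- data.frame(read_id = c("r1", "r1", "r2"), contig = "c1",
                   junction = c(100L, 101L, 100L),
                   insert_seq = c(strrep("A", 10), strrep("C", 30),
                                  strrep("G", 20)),
                   query_start = 0L)
  cl <- cluster_inserts(ev, 5)
  expect_equal(nrow(cl), 2L)
  expect_identical(cl$insert_seq[cl$read_id == "r1"], strrep("C", 30))
  expect_equal(cluster_table(cl)$n_reads, 2L)
})

test_that("coverage filter counts distinct reads", {
  ev <- make_ev(rep(100L, 3), read_ids = c("a", "b", "c"))
  cl <- cluster_inserts(ev, 5)
  expect_equal(nrow(filter_clusters(cl, 5)), 0L)
  ev5 <- make_ev(rep(100L, 5), read_ids = letters[1:5])
  expect_equal(nrow(filter_clusters(cluster_inserts(ev5, 5), 5)), 5L)
})

test_that("flanked segments slice reads with truncation at ends", {
  seq <- rand_seq(400, 0.5)
  aln <- data.frame(read_id = "r1", contig = "c1", ref_start = 0L,
                    mapq = 60L, cigar = "150M40I210M", seq = seq)
  members <- insert_evidence(aln, 10)
  members$cluster <- 1L
  fs <- extract_flanked_segments(members, aln, flank_len = 100)
  expect_identical(fs$seq, substring(seq, 51, 290))  # 100 + 40 + 100

  aln2 <- data.frame(read_id = "r2", contig = "c1", ref_start = 0L,
                     mapq = 60L, cigar = "20M40I340M", seq = seq)
  m2 <- insert_evidence(aln2, 10)
  fs2 <- extract_flanked_segments(m2, aln2, flank_len = 100)
  expect_identical(fs2$seq, substring(seq, 1, 160))  # left flank only 20 bp

  expect_error(extract_flanked_segments(m2, aln, flank_len = 100), "r2")
})

test_that("consensus is exact on identical and lightly mutated inputs", {
  expect_identical(consensus_seq("ACGT"), "ACGT")
  S <- rand_seq(120, 0.5)
  expect_identical(consensus_seq(rep(S, 5)), S)
  expect_error(consensus_seq(character(0)))

  # each copy carries one substitution at a distinct position: majority
  # recovers the original
  set.seed(5)
  v <- strsplit(S, "")[[1]]
  seqs <- vapply(c(10, 50, 90), function(pos) {
    w <- v
    w[pos] <- setdiff(c("A", "C", "G", "T"), w[pos])[1]
    paste(w, collapse = "")
  }, "")
  expect_identical(consensus_seq(seqs), S)
})

test_that("realignment recovers a planted insert and rejects none", {
  set.seed(9)
  ref <- c(c1 = rand_seq(1000))
  ins <- rand_seq(60, 0.5)
  junction <- 500L
  cons <- paste0(substring(ref, 401, 500), ins, substring(ref, 501, 600))
  res <- realign_consensus(cons, ref, "c1", c(380L, 620L))
  reins <- paste0(substring(ref, 1, res$junction), res$ies_seq,
                  substring(ref, res$junction + 1, 1000))
  truth_mic <- paste0(substring(ref, 1, 500), ins, substring(ref, 501, 1000))
  expect_identical(reins, truth_mic)  # shift-equivalent placement

  expect_null(realign_consensus(substring(ref, 401, 600), ref, "c1",
                                c(380L, 620L)))
})

test_that("insertion normalisation is shift-equivalence preserving", {
  set.seed(21)
  for (i in 1:50) {
    ref <- c(c1 = rand_seq(300))
    j <- sample(50:250, 1)
    ies <- rand_seq(sample(12:40, 1), 0.5)
    norm <- normalize_insertion(ies, ref, "c1", j)
    mic_raw <- paste0(substring(ref, 1, j), ies,
                      substring(ref, j + 1, 300))
    mic_norm <- paste0(substring(ref, 1, norm$junction), norm$ies_seq,
                       substring(ref, norm$junction + 1, 300))
    expect_identical(mic_norm, mic_raw)
    # leftmost: cannot shift further
    expect_true(norm$junction == 0 ||
                  substring(ref, norm$junction, norm$junction) !=
                  substring(norm$ies_seq, nchar(norm$ies_seq),
                            nchar(norm$ies_seq)))
  }
})

test_that("pointer detection finds the junction repeat", {
  # reference ...AAAA TAGGGG..., insert TACCCCC before the T: pointer TA
  ref <- c(c1 = paste0(rand_seq(50, 0.5), "AAAA", "TAGGGG", rand_seq(50, 0.5)))
  res <- detect_pointer("TACCCCC", ref, "c1", 54L)
  expect_identical(res$pointer, "TA")
  expect_true(detect_ta(res$pointer))

  ref2 <- c(c1 = paste0(strrep("C", 50), "TTTT", strrep("C", 50)))
  expect_identical(detect_pointer("GGGG", ref2, "c1", 50L)$pointer, "")
  expect_false(detect_ta(""))
  expect_false(detect_ta("TTAA"))
})

test_that("planted pointers of length 0-8 are recovered exactly", {
  # brute-force oracle: enumerate every shift-equivalent placement of the
  # insertion and take the longest junction repeat over all of them
  oracle_pointer <- function(ref, j, ies) {
    n <- nchar(ies)
    best <- 0L
    shifts <- list(list(j = j, ies = ies))
    jj <- j; ss <- ies
    while (jj > 0 && substring(ref, jj, jj) == substring(ss, n, n)) {
      ss <- paste0(substring(ref, jj, jj), substring(ss, 1, n - 1))
      jj <- jj - 1L
      shifts[[length(shifts) + 1L]] <- list(j = jj, ies = ss)
    }
    jj <- j; ss <- ies
    while (jj < nchar(ref) &&
           substring(ref, jj + 1, jj + 1) == substring(ss, 1, 1)) {
      ss <- paste0(substring(ss, 2, n), substring(ref, jj + 1, jj + 1))
      jj <- jj + 1L
      shifts[[length(shifts) + 1L]] <- list(j = jj, ies = ss)
    }
    for (sh in shifts) {
      k <- 0L
      while (k < n && substring(sh$ies, k + 1, k + 1) ==
             substring(ref, sh$j + k + 1, sh$j + k + 1)) k <- k + 1L
      best <- max(best, k)
    }
    best
  }
  set.seed(33)
  n_ok <- 0L
  n_tot <- 0L
  for (k in 0:8) {
    for (rep in 1:20) {
      p <- sim_params(seed = 1000 + k * 20 + rep, n_contigs = 1,
                      contig_len = 3000, n_iess = 1,
                      ta_fraction = if (k == 2) 1 else 0,
                      pointer_len_weights = as.numeric(0:8 == k))
      sim <- make_genomes(p)
      tt <- sim$truth
      expect_equal(nchar(tt$pointer), k)
      det <- detect_pointer(tt$ies_seq, sim$mac, tt$contig, tt$junction)
      orc <- oracle_pointer(sim$mac[[tt$contig]], tt$junction, tt$ies_seq)
      n_tot <- n_tot + 1L
      if (nchar(det$pointer) == k && orc == k) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("GFF3 output converts frames and round-trips", {
  rec <- data.frame(
    id = c("IES_c1_111", "IES_c2_6"), contig = c("c1", "c2"),
    junction = c(110L, 5L), ies_seq = c(strrep("TA", 15), strrep("ACT", 10)),
    length = c(30L, 30L), pointer = c("TA", ""),
    ta_bound = c(TRUE, FALSE), support = c(12L, 8L),
    spanning_total = c(20L, 10L), retention_score = c(0.6, 0.8),
    mode = "subread")
  gff <- tempfile(fileext = ".gff3")
  write_gff3(rec, gff, params = list(min_coverage = 5))
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  expect_true(any(grepl("min_coverage=5", lines)))
  f1 <- strsplit(grep("^c1\t", lines, value = TRUE), "\t")[[1]]
  expect_identical(f1[4], "111")
  expect_identical(f1[5], "111")

  back <- read_junction_gff(gff)
  expect_identical(back$contig, rec$contig)
  expect_identical(back$junction, rec$junction)
  expect_identical(back$id, rec$id)

  fa <- tempfile(fileext = ".fasta")
  write_ies_fasta(rec, fa)
  seqs <- as.character(Biostrings::readDNAStringSet(fa))
  expect_identical(unname(seqs), rec$ies_seq)
  expect_identical(names(seqs), rec$id)

  # empty record set still yields a valid header-only file
  write_gff3(rec[0, ], gff)
  expect_identical(readLines(gff), "##gff-version 3")
  expect_equal(nrow(read_junction_gff(gff)), 0L)
})

test_that("call_iess recovers planted IESs from clean CCS-like reads", {
  set.seed(13)
  p <- sim_params(seed = 31, n_contigs = 1, contig_len = 20000, n_iess = 6,
                  err_sub = 0.003, err_ins = 0.001, err_del = 0.001,
                  read_len_mean = 3000, read_len_sd = 500,
                  coverage_mac = 10, coverage_mic = 15)
  sim <- make_genomes(p)
  rd <- simulate_reads(sim, tempfile())
  # small library: a low coverage cutoff keeps junctions on the coverage
  # ramp near contig ends callable
  res <- call_iess(rd$bam, sim$mac, mode = "ccs", min_coverage = 3)
  m <- evaluate_calls(res$records, sim$truth, tol_bp = 0)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  # low-error reads: subread mode agrees on every junction
  res_sub <- call_iess(rd$bam, sim$mac, mode = "subread", min_coverage = 3)
  expect_identical(res_sub$records$junction, res$records$junction)

  # records carry retention scores near the MIC fraction of spanning reads
  expect_true(all(res$records$retention_score > 0.2 &
                    res$records$retention_score < 0.8))
})

test_that("call_iess on an empty or MAC-only library yields no calls", {
  p <- sim_params(seed = 41, n_contigs = 1, contig_len = 15000, n_iess = 4,
                  coverage_mic = 0, coverage_mac = 8,
                  read_len_mean = 2000, read_len_sd = 300)
  sim <- make_genomes(p)
  rd <- simulate_reads(sim, tempfile())
  res <- call_iess(rd$bam, sim$mac, mode = "subread")
  expect_equal(nrow(res$records), 0L)
})
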