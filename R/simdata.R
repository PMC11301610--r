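# Synthetic-data generator: paired MAC/MIC genomes with pointer/TA-structured
# IESs, long reads with a tunable error profile, and ground-truth alignments
# (emitted directly as a BAM so the whole pipeline is testable without an
# external mapper).

#' Simulation parameters
#'
#' Bundles and validates all knobs of the synthetic-data generator. Defaults
#' emulate a Paramecium-like target: an AT-rich somatic genome, short
#' TA-bounded IESs (26-100 bp), and insertion-dominated subread-like errors
#' totalling 10 percent.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_contigs,contig_len Number and length (bp) of MAC contigs.
#' @param gc GC content of the simulated MAC genome (default 0.28).
#' @param n_iess Total IESs planted across the genome.
#' @param ies_len_range Inclusive range of IES lengths (default 26-100 bp;
#'   26 bp is the canonical minimum IES size in Paramecium).
#' @param ta_fraction Fraction of IESs that are TA-bounded (pointer `"TA"`,
#'   default 1).
#' @param pointer_len_weights Sampling weights over pointer lengths 0..8 for
#'   the non-TA-bounded fraction.
#' @param read_len_mean,read_len_sd,read_len_min Read length distribution
#'   (normal, truncated below at `read_len_min`).
#' @param coverage_mac,coverage_mic Depth of MAC-origin and MIC-origin reads.
#' @param err_sub,err_ins,err_del Per-base substitution / insertion-event /
#'   deletion error probabilities. Insertion events have geometric lengths
#'   (p = 0.5, mean 2), so the expected inserted-base rate is about
#'   `2 * err_ins`; the defaults (0.02 / 0.03 / 0.02) give a total
#'   base-level error rate near 10 percent, the noisy-subread regime.
#' @param flank Minimum half-spacing between planted junctions; junctions
#'   are at least `2 * flank` apart so flank extraction windows never
#'   overlap two IESs.
#' @return A validated parameter list of class `"sim_params"`.
#' @export
sim_params <- function(seed = 1L, n_contigs = 5L, contig_len = 100000L,
                       gc = 0.28, n_iess = 100L,
                       ies_len_range = c(26L, 100L), ta_fraction = 1,
                       pointer_len_weights = rep(1, 9), read_len_mean = 8000,
                       read_len_sd = 2000, read_len_min = 500,
                       coverage_mac = 20, coverage_mic = 20,
                       err_sub = 0.02, err_ins = 0.03, err_del = 0.02,
                       flank = 100L) {
  p <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
            contig_len = as.integer(contig_len), gc = gc,
            n_iess = as.integer(n_iess),
            ies_len_range = as.integer(ies_len_range),
            ta_fraction = ta_fraction,
            pointer_len_weights = pointer_len_weights,
            read_len_mean = read_len_mean, read_len_sd = read_len_sd,
            read_len_min = read_len_min, coverage_mac = coverage_mac,
            coverage_mic = coverage_mic, err_sub = err_sub,
            err_ins = err_ins, err_del = err_del, flank = as.integer(flank))
  stopifnot(p$gc > 0, p$gc < 1, p$ta_fraction >= 0, p$ta_fraction <= 1,
            p$err_sub >= 0, p$err_ins >= 0, p$err_del >= 0,
            p$err_sub + p$err_ins + p$err_del < 0.5,
            length(p$pointer_len_weights) == 9L,
            p$ies_len_range[1] >= 10L,
            p$ies_len_range[2] >= p$ies_len_range[1],
            p$n_contigs >= 1L, p$contig_len >= 1000L)
  class(p) <- "sim_params"
  p
}

.rand_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# pick, for each element of `avoid`, a base different from it
.other_base <- function(avoid) {
  bases <- c("A", "C", "G", "T")
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  alt[cbind(match(avoid, bases), sample.int(3L, length(avoid), TRUE))]
}

#' Generate a paired MAC/MIC genome with planted IESs
#'
#' Simulates MAC contigs with the requested GC content, places IES
#' junctions with guaranteed spacing, and builds each IES as pointer +
#' random core. For a pointer of length k the MAC bases immediately right
#' of the junction are set to the pointer, so the germline form carries the
#' repeat at both IES ends and the somatic form retains one copy -- the
#' defining pointer structure. TA-bounded IESs use the fixed pointer
#' `"TA"`. Planted junctions are left-normalised by construction (the last
#' IES base never equals the base left of the junction) and pointers are
#' exact (the core never extends the repeat).
#'
#' @param params A [sim_params()] object.
#' @return `list(mac, mic, truth, params)`: `mac`/`mic` are named uppercase
#'   sequence vectors as from [read_reference()]; `truth` has one row per
#'   IES (`ies_id`, `contig`, `junction` 0-based on the MAC, `ies_seq`,
#'   `length`, `pointer`, `ta_bounded`). Inserting each `ies_seq` at its
#'   junction reproduces the MIC contig exactly (verified before return).
#' @export
make_genomes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  ctg_names <- sprintf("ctg%02d", seq_len(params$n_contigs))
  mac <- vapply(ctg_names, function(x) {
    paste(.rand_dna(params$contig_len, params$gc), collapse = "")
  }, "")
  # allocate IESs across contigs proportional to length (equal lengths here)
  n_per <- diff(round(seq(0, params$n_iess, length.out =
                            params$n_contigs + 1L)))
  min_gap <- 2L * params$flank
  margin <- 3L * params$flank
  truth <- list()
  mic <- mac
  for (ci in seq_along(ctg_names)) {
    n <- n_per[ci]
    if (n == 0L) next
    usable <- params$contig_len - 2L * margin - (n - 1L) * min_gap
    if (usable < n) {
      stop("junction spacing unsatisfiable on ", ctg_names[ci],
           "; reduce n_iess or increase contig_len")
    }
    u <- sort(sample.int(usable, n))
    junctions <- margin + u + (seq_len(n) - 1L) * min_gap
    refv <- strsplit(mac[[ci]], "")[[1]]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      j <- junctions[i]
      ta <- stats::runif(1) < params$ta_fraction
      if (ta) {
        k <- 2L
        pointer <- "TA"
      } else {
        k <- sample(0:8, 1L, prob = params$pointer_len_weights)
        pointer <- if (k > 0L) paste(.rand_dna(k, 0.5), collapse = "") else ""
      }
      if (k > 0L) {
        refv[(j + 1L):(j + k)] <- strsplit(pointer, "")[[1]]
      }
      len <- sample(params$ies_len_range[1]:params$ies_len_range[2], 1L)
      if (len <= k) len <- k + 4L
      core <- .rand_dna(len - k, params$gc)
      # pointer is exactly k long: core must not extend the repeat
      if (core[1] == refv[j + k + 1L]) {
        core[1] <- .other_base(refv[j + k + 1L])
      }
      # planted junction is the leftmost shift-equivalent placement
      if (core[length(core)] == refv[j]) {
        core[length(core)] <- .other_base(refv[j])
      }
      ies_seq <- paste0(pointer, paste(core, collapse = ""))
      rows[[i]] <- data.frame(
        contig = ctg_names[ci], junction = j, ies_seq = ies_seq,
        length = nchar(ies_seq), pointer = pointer, ta_bounded = ta)
    }
    mac[[ci]] <- paste(refv, collapse = "")
    tt <- do.call(rbind, rows)
    # build the MIC contig by interleaving MAC blocks and IESs
    cuts <- c(0L, tt$junction, params$contig_len)
    blocks <- character(0)
    for (i in seq_len(n)) {
      blocks <- c(blocks,
                  substring(mac[[ci]], cuts[i] + 1L, cuts[i + 1L]),
                  tt$ies_seq[i])
    }
    blocks <- c(blocks, substring(mac[[ci]], cuts[n + 1L] + 1L,
                                  params$contig_len))
    mic[[ci]] <- paste(blocks, collapse = "")
    truth[[length(truth) + 1L]] <- tt
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(0), junction = integer(0),
               ies_seq = character(0), length = integer(0),
               pointer = character(0), ta_bounded = logical(0))
  truth <- cbind(ies_id = sprintf("sim_ies_%04d", seq_len(nrow(truth))),
                 truth)
  rownames(truth) <- NULL
  # constructive invariant: reinsertion reproduces the MIC exactly
  for (ctg in unique(truth$contig)) {
    tt <- truth[truth$contig == ctg, , drop = FALSE]
    rebuilt <- .insert_all(mac[[ctg]], tt$junction, tt$ies_seq)
    if (!identical(rebuilt, mic[[ctg]])) {
      stop("internal error: reinsertion check failed on ", ctg)
    }
  }
  list(mac = mac, mic = mic, truth = truth, params = params)
}

.insert_all <- function(macseq, junctions, ies_seqs) {
  o <- order(junctions)
  junctions <- junctions[o]
  ies_seqs <- ies_seqs[o]
  cuts <- c(0L, junctions, nchar(macseq))
  parts <- character(0)
  for (i in seq_along(junctions)) {
    parts <- c(parts, substring(macseq, cuts[i] + 1L, cuts[i + 1L]),
               ies_seqs[i])
  }
  paste(c(parts, substring(macseq, cuts[length(junctions) + 1L] + 1L,
                           nchar(macseq))), collapse = "")
}

#' Write a genome to FASTA
#'
#' @param genome Named sequence vector (as from [read_reference()] or
#'   [make_genomes()]).
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# --- read simulation ---------------------------------------------------------

# Per-MIC-contig block map relating MIC intervals to MAC coordinates.
.mic_blocks <- function(truth_ctg, contig_len) {
  tt <- truth_ctg[order(truth_ctg$junction), , drop = FALSE]
  n <- nrow(tt)
  mac_cuts <- c(0L, tt$junction, contig_len)
  blocks <- list()
  mic_at <- 0L
  for (i in seq_len(n + 1L)) {
    mlen <- mac_cuts[i + 1L] - mac_cuts[i]
    if (mlen > 0L) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        type = "M", mic_start = mic_at, len = mlen, mac_start = mac_cuts[i])
      mic_at <- mic_at + mlen
    }
    if (i <= n) {
      ilen <- tt$length[i]
      blocks[[length(blocks) + 1L]] <- data.frame(
        type = "I", mic_start = mic_at, len = ilen, mac_start = tt$junction[i])
      mic_at <- mic_at + ilen
    }
  }
  do.call(rbind, blocks)
}

# Clean per-base op vector + MAC start position for a read on [s, e) of a
# genome. For MAC reads everything is M; for MIC reads IES bases are I and
# leading/trailing I runs become soft clips.
.clean_read_ops <- function(blocks, s, e) {
  if (is.null(blocks)) {
    return(list(ops = rep("M", e - s), pos = s))
  }
  sel <- which(blocks$mic_start < e & blocks$mic_start + blocks$len > s)
  ops <- character(0)
  pos <- NA_integer_
  for (bi in sel) {
    b <- blocks[bi, ]
    from <- max(s, b$mic_start)
    to <- min(e, b$mic_start + b$len)
    ops <- c(ops, rep(b$type, to - from))
    if (b$type == "M" && is.na(pos)) pos <- b$mac_start + (from - b$mic_start)
  }
  # unaligned partial IES at either read end is a soft clip
  r <- rle(ops)
  if (r$values[1] == "I") ops[seq_len(r$lengths[1])] <- "S"
  nr <- length(r$values)
  if (nr > 1L && r$values[nr] == "I") {
    ops[(length(ops) - r$lengths[nr] + 1L):length(ops)] <- "S"
  }
  list(ops = ops, pos = pos)
}

# Apply the iid per-base error model to (ops, bases); returns the final op
# vector (including D) and the read bases.
.apply_errors <- function(ops, bases, err_sub, err_ins, err_del) {
  L <- length(bases)
  sub_idx <- which(stats::runif(L) < err_sub)
  if (length(sub_idx)) bases[sub_idx] <- .other_base(bases[sub_idx])
  del_mask <- stats::runif(L) < err_del
  ins_mask <- stats::runif(L) < err_ins
  ins_count <- integer(L)
  if (any(ins_mask)) {
    ins_count[ins_mask] <- stats::rgeom(sum(ins_mask), 0.5) + 1L
  }
  reps <- 1L + ins_count
  idx <- rep.int(seq_len(L), reps)
  within <- sequence(reps)
  ops_out <- ops[idx]
  bases_out <- bases[idx]
  inserted <- within > 1L
  if (any(inserted)) {
    # inserted bases inside a soft clip stay soft-clipped
    ops_out[inserted] <- ifelse(ops_out[inserted] == "S", "S", "I")
    bases_out[inserted] <- sample(c("A", "C", "G", "T"), sum(inserted),
                                  replace = TRUE)
  }
  del_here <- !inserted & del_mask[idx]
  drop <- del_here & ops_out != "M"     # deleted insert/clip base vanishes
  to_d <- del_here & ops_out == "M"     # deleted reference base -> D op
  ops_out[to_d] <- "D"
  ops_out <- ops_out[!drop]
  bases_out <- bases_out[!drop]
  bases_out <- bases_out[ops_out != "D"]
  list(ops = ops_out, bases = bases_out)
}

# Trim/convert pathological read-terminal ops so the CIGAR is well formed:
# no leading/trailing D (shifts pos), terminal I runs become S.
.tidy_ops <- function(ops, pos) {
  repeat {
    r <- rle(ops)
    n <- length(r$values)
    changed <- FALSE
    if (r$values[1] == "D") {
      pos <- pos + r$lengths[1]
      ops <- ops[-seq_len(r$lengths[1])]
      changed <- TRUE
    } else if (r$values[1] == "I") {
      ops[seq_len(r$lengths[1])] <- "S"
      changed <- TRUE
    } else if (n >= 2L && r$values[1] == "S" && r$values[2] == "D") {
      i0 <- r$lengths[1]
      pos <- pos + r$lengths[2]
      ops <- ops[-((i0 + 1L):(i0 + r$lengths[2]))]
      changed <- TRUE
    }
    r <- rle(ops)
    n <- length(r$values)
    last <- length(ops)
    if (r$values[n] == "D") {
      ops <- ops[seq_len(last - r$lengths[n])]
      changed <- TRUE
    } else if (r$values[n] == "I") {
      ops[(last - r$lengths[n] + 1L):last] <- "S"
      changed <- TRUE
    } else if (n >= 2L && r$values[n] == "S" && r$values[n - 1L] == "D") {
      i1 <- last - r$lengths[n]
      ops <- ops[-((i1 - r$lengths[n - 1L] + 1L):i1)]
      changed <- TRUE
    }
    if (!changed) break
  }
  list(ops = ops, pos = pos)
}

.ops_to_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Simulate a long-read library with ground-truth alignments
#'
#' Draws reads from the MAC and MIC genomes at the requested depths,
#' applies the iid per-base error model, and writes (i) a FASTQ of the
#' reads and (ii) a coordinate-sorted, indexed truth BAM containing the
#' error-aware true alignment of every read to the MAC reference: planted
#' IESs appear as `I` operations at the true junctions, error indels as
#' short `I`/`D` operations, and partial IESs at read ends as soft clips.
#' The truth BAM makes the full detection pipeline testable without an
#' external mapper; the FASTQ supports optional real-mapper runs.
#'
#' @param sim Output of [make_genomes()].
#' @param out_prefix Path prefix for `<prefix>.bam` / `<prefix>.fastq`.
#' @param params Simulation parameters (default: those inside `sim`);
#'   override to change coverage or error rates on a fixed genome pair.
#' @param seed Seed for the read-level randomness (default
#'   `params$seed + 1`, so genome and reads can be regenerated
#'   independently).
#' @return `list(bam, fastq, reads)` where `reads` is the per-read truth:
#'   `read_id`, `origin` (`"mac"`/`"mic"`), `contig`, `start`, `end`
#'   (0-based half-open on the origin genome).
#' @export
simulate_reads <- function(sim, out_prefix, params = sim$params,
                           seed = params$seed + 1L) {
  set.seed(seed)
  blocks_by_ctg <- lapply(names(sim$mac), function(ctg) {
    tt <- sim$truth[sim$truth$contig == ctg, , drop = FALSE]
    if (nrow(tt) == 0L) NULL else .mic_blocks(tt, nchar(sim$mac[[ctg]]))
  })
  names(blocks_by_ctg) <- names(sim$mac)

  sam_rows <- list()
  fq_rows <- list()
  truth_rows <- list()
  counter <- 0L
  for (origin in c("mac", "mic")) {
    genome <- if (origin == "mac") sim$mac else sim$mic
    cov <- if (origin == "mac") params$coverage_mac else params$coverage_mic
    if (cov <= 0) next
    glen <- nchar(genome)
    n_reads <- ceiling(cov * sum(glen) / params$read_len_mean)
    ctg_idx <- sample.int(length(genome), n_reads, replace = TRUE,
                          prob = glen / sum(glen))
    rl <- pmax(params$read_len_min,
               round(stats::rnorm(n_reads, params$read_len_mean,
                                  params$read_len_sd)))
    starts <- floor(stats::runif(n_reads, 0, glen[ctg_idx]))
    for (i in seq_len(n_reads)) {
      ctg <- names(genome)[ctg_idx[i]]
      s <- starts[i]
      e <- min(s + rl[i], glen[ctg_idx[i]])
      if (e - s < params$read_len_min) {
        s <- max(0L, e - params$read_len_min)
      }
      if (e - s < 50L) next
      cl <- .clean_read_ops(if (origin == "mic") blocks_by_ctg[[ctg]] else
        NULL, s, e)
      if (is.na(cl$pos)) next  # read without any aligned base
      bases <- strsplit(substring(genome[[ctg_idx[i]]], s + 1L, e), "")[[1]]
      er <- .apply_errors(cl$ops, bases, params$err_sub, params$err_ins,
                          params$err_del)
      td <- .tidy_ops(er$ops, cl$pos)
      if (!any(td$ops == "M")) next
      counter <- counter + 1L
      rid <- sprintf("read_%s_%06d", origin, counter)
      seqstr <- paste(er$bases, collapse = "")
      sam_rows[[counter]] <- data.frame(
        qname = rid, rname = ctg, pos = td$pos + 1L,
        cigar = .ops_to_cigar(td$ops), seq = seqstr)
      fq_rows[[counter]] <- c(paste0("@", rid), seqstr, "+",
                              strrep("I", nchar(seqstr)))
      truth_rows[[counter]] <- data.frame(
        read_id = rid, origin = origin, contig = ctg, start = s, end = e)
    }
  }
  sam <- do.call(rbind, sam_rows)
  sam <- sam[order(match(sam$rname, names(sim$mac)), sam$pos, sam$qname), ,
             drop = FALSE]
  bam <- .write_bam(sam, sim$mac, paste0(out_prefix, ".bam"))
  fastq <- paste0(out_prefix, ".fastq")
  writeLines(unlist(fq_rows), fastq)
  reads <- do.call(rbind, truth_rows)
  rownames(reads) <- NULL
  list(bam = bam, fastq = fastq, reads = reads)
}

# Write alignment rows (qname, rname, pos 1-based, cigar, seq) as a
# coordinate-sorted indexed BAM against the given reference.
.write_bam <- function(sam, ref, bam_path) {
  samfile <- tempfile(fileext = ".sam")
  on.exit(unlink(samfile), add = TRUE)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)))
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  sam$qname, sam$rname, sam$pos, sam$cigar, sam$seq,
                  strrep("I", nchar(sam$seq)))
  writeLines(c(header, body), samfile)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(samfile, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Simulate telomere-bearing clipped reads at a chromosome breakage site
#'
#' Generates reads that align to the MAC assembly up to a planted breakage
#' position and carry telomeric repeat sequence as a terminal soft clip --
#' the read signature of breakage with de novo telomere addition. Breakpoint
#' positions jitter by up to `jitter_bp`; substitution errors are applied to
#' the whole read.
#'
#' @param ref Reference from [read_reference()] or [make_genomes()] `$mac`.
#' @param contig Contig carrying the site.
#' @param position 0-based breakage position.
#' @param side `"right"` (telomere right of the aligned block) or `"left"`.
#' @param n_reads Number of supporting reads (default 10).
#' @param motif Telomere repeat unit added at the break.
#' @param clip_len Telomeric clip length (default 60).
#' @param aligned_len Mean aligned length (default 300).
#' @param err_sub Substitution error rate (default 0.02).
#' @param jitter_bp Maximum per-read breakpoint jitter (default 2).
#' @param out_prefix Path prefix for the output BAM.
#' @param seed Seed.
#' @return Path to the coordinate-sorted indexed BAM.
#' @export
simulate_telomere_clips <- function(ref, contig, position,
                                    side = c("right", "left"),
                                    n_reads = 10L, motif = "TTGGGG",
                                    clip_len = 60L, aligned_len = 300L,
                                    err_sub = 0.02, jitter_bp = 2L,
                                    out_prefix = tempfile(), seed = 1L) {
  side <- match.arg(side)
  set.seed(seed)
  stopifnot(contig %in% names(ref))
  refseq <- ref[[contig]]
  rows <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    bp <- position + sample(seq(-jitter_bp, jitter_bp), 1L)
    alen <- max(100L, round(stats::rnorm(1, aligned_len, aligned_len / 10)))
    tel <- strrep(motif, ceiling(clip_len / nchar(motif)))
    phase <- sample.int(nchar(motif), 1L)
    tel <- substring(tel, phase, phase + clip_len - 1L)
    if (side == "right") {
      a0 <- max(0L, bp - alen)
      aligned <- substring(refseq, a0 + 1L, bp)
      seqstr <- paste0(aligned, tel)
      cigar <- sprintf("%dM%dS", nchar(aligned), nchar(tel))
      pos <- a0 + 1L
    } else {
      a1 <- min(nchar(refseq), bp + alen)
      aligned <- substring(refseq, bp + 1L, a1)
      seqstr <- paste0(tel, aligned)
      cigar <- sprintf("%dS%dM", nchar(tel), nchar(aligned))
      pos <- bp + 1L
    }
    v <- strsplit(seqstr, "")[[1]]
    sub_idx <- which(stats::runif(length(v)) < err_sub)
    if (length(sub_idx)) v[sub_idx] <- .other_base(v[sub_idx])
    rows[[i]] <- data.frame(
      qname = sprintf("telread_%s_%03d", side, i), rname = contig,
      pos = pos, cigar = cigar, seq = paste(v, collapse = ""))
  }
  sam <- do.call(rbind, rows)
  sam <- sam[order(sam$pos, sam$qname), , drop = FALSE]
  .write_bam(sam, ref, paste0(out_prefix, ".bam"))
}
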