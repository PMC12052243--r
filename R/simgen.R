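#' Simulation configuration
#'
#' Bundles every knob of the synthetic long-read generator: reference layout,
#' number and length law of implanted deletions, sequencing depth, read-length
#' law, small-error rates (the indel errors that shape CIGARs) and decoy
#' fractions (secondary/supplementary and unmapped records used to exercise
#' the FLAG filter).
#'
#' Deletion lengths are drawn log-uniformly on `[del_min, del_max]` so that
#' all five reporting bins ([50,200), [200,500), [500,1000), [1000,5000),
#' [5000,Inf)) are populated. Read lengths follow a lognormal law with median
#' `read_median` truncated to `[read_min, read_max]`, emulating ~10 kb long
#' reads. `sub_rate`, `small_ins_rate` and `small_del_rate` are per-base
#' event-start probabilities; indel error events have lengths uniform on
#' `1:small_err_max_len` and are always < 50 bp, so every >= 50 bp D op in a
#' simulated CIGAR corresponds to exactly one implanted deletion.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_deletions number of deletions to implant genome-wide.
#' @param del_min,del_max bounds of the log-uniform deletion length law (bp).
#' @param coverage target mean fold-depth over the donor genome.
#' @param read_median,read_sdlog,read_min,read_max lognormal read-length law:
#'   median, sdlog, truncation bounds (bp).
#' @param sub_rate per-base substitution probability (does not alter CIGARs
#'   under M semantics; kept for completeness of the error model).
#' @param small_ins_rate,small_del_rate per-base probabilities that a small
#'   insertion / deletion error event starts at a given base.
#' @param small_err_max_len maximum length of a small error indel (bp, < 50).
#' @param frac_secondary fraction of primary reads duplicated as secondary
#'   (FLAG 256) or supplementary (FLAG 2048) decoy records.
#' @param frac_unmapped fraction of unmapped (FLAG 4) decoy records.
#' @param seed integer seed; the whole simulation is a pure function of the
#'   configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 500000L,
                       n_deletions = 20L,
                       del_min = 50L,
                       del_max = 20000L,
                       coverage = 30,
                       read_median = 10000L,
                       read_sdlog = 0.3,
                       read_min = 1000L,
                       read_max = 20000L,
                       sub_rate = 0.05,
                       small_ins_rate = 0.015,
                       small_del_rate = 0.015,
                       small_err_max_len = 5L,
                       frac_secondary = 0.05,
                       frac_unmapped = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.integer(chrom_length),
    n_deletions = as.integer(n_deletions),
    del_min = as.integer(del_min), del_max = as.integer(del_max),
    coverage = coverage,
    read_median = as.integer(read_median), read_sdlog = read_sdlog,
    read_min = as.integer(read_min), read_max = as.integer(read_max),
    sub_rate = sub_rate, small_ins_rate = small_ins_rate,
    small_del_rate = small_del_rate,
    small_err_max_len = as.integer(small_err_max_len),
    frac_secondary = frac_secondary, frac_unmapped = frac_unmapped,
    seed = as.integer(seed)
  )
  rates <- c(cfg$sub_rate, cfg$small_ins_rate, cfg$small_del_rate,
             cfg$frac_secondary, cfg$frac_unmapped)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$n_chroms < 1L || cfg$chrom_length < 1L)
    stop("configuration error: non-positive reference dimensions")
  if (cfg$n_deletions < 0L) stop("configuration error: negative n_deletions")
  if (cfg$small_err_max_len >= 50L)
    stop("small_err_max_len must be < 50 (error ops must stay sub-SV scale)")
  if (cfg$small_err_max_len < 1L) stop("small_err_max_len must be >= 1")
  if (cfg$del_min < 50L) stop("deletions are SVs: del_min must be >= 50")
  if (cfg$del_max < cfg$del_min) stop("del_max < del_min")
  if (cfg$chrom_length <= 3L * cfg$del_max)
    stop("chrom_length must exceed 3x the maximum deletion length")
  if (cfg$read_min < 100L || cfg$read_max < cfg$read_min)
    stop("invalid read length bounds")
  if (cfg$coverage <= 0) stop("configuration error: coverage must be positive")
  class(cfg) <- "sim_config"
  cfg
}

chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

# minimum gap kept between implanted deletions (and chromosome ends)
min_del_gap <- function(cfg) 2L * cfg$read_max

#' Generate a random reference genome
#'
#' @param cfg a [sim_config()].
#' @return a [Biostrings::DNAStringSet] with `n_chroms` uniform-composition
#'   chromosomes, deterministic in `cfg$seed`.
#' @export
gen_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- chrom_names(cfg)
  ref
}

#' Reference metadata (contig names and lengths)
#'
#' @param ref a `DNAStringSet`.
#' @return data.frame with columns `chrom`, `length`.
#' @export
ref_meta <- function(ref) {
  data.frame(chrom = names(ref), length = Biostrings::width(ref),
             stringsAsFactors = FALSE)
}

draw_del_lengths <- function(n, cfg) {
  as.integer(round(exp(stats::runif(n, log(cfg$del_min), log(cfg$del_max)))))
}

#' Implant non-overlapping deletions into a reference
#'
#' Deletion lengths are drawn from the configured log-uniform law and split
#' round-robin across chromosomes. Placement keeps a gap of at least twice the
#' maximum read length between deletions (and chromosome ends), so truth
#' intervals are pairwise non-overlapping, non-adjacent, and each read can
#' span at most one deletion junction.
#'
#' @param ref reference `DNAStringSet` from [gen_reference()].
#' @param cfg the [sim_config()] that produced `ref`.
#' @return list with `donor` (a `DNAStringSet` with the deleted bases removed)
#'   and `truth`, a data.frame of class `truth_sv` with columns
#'   `chrom`, `start`, `end` (0-based half-open) and `svlen`, sorted by
#'   (chrom, start).
#' @export
implant_deletions <- function(ref, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  chroms <- names(ref)
  gap <- min_del_gap(cfg)
  n <- cfg$n_deletions
  truth <- empty_truth()
  if (n > 0L) {
    lens <- draw_del_lengths(n, cfg)
    assign_chrom <- rep(seq_along(chroms), length.out = n)
    rows <- vector("list", n)
    k <- 0L
    for (ci in seq_along(chroms)) {
      idx <- which(assign_chrom == ci)
      if (!length(idx)) next
      L <- lens[idx]
      kc <- length(L)
      clen <- Biostrings::width(ref)[ci]
      free <- clen - sum(L) - (kc + 1L) * gap
      if (free < 0L)
        stop(sprintf(
          "placement error: cannot fit %d deletions (total %d bp) plus %d bp gaps on %s (%d bp)",
          kc, sum(L), (kc + 1L) * gap, chroms[ci], clen))
      # stick-breaking: distribute the free space between slots
      extras <- diff(c(0, sort(stats::runif(kc)), 1)) * free
      pos <- gap + cumsum(extras[seq_len(kc)]) +
        c(0, cumsum(L[-kc] + gap))[seq_len(kc)]
      start <- as.integer(floor(pos))
      for (j in seq_len(kc)) {
        k <- k + 1L
        rows[[k]] <- data.frame(chrom = chroms[ci], start = start[j],
                                end = start[j] + L[j], svlen = L[j],
                                stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(match(truth$chrom, chroms), truth$start), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    class(truth) <- c("truth_sv", "data.frame")
  }
  donor <- ref
  for (ci in seq_along(chroms)) {
    tt <- truth[truth$chrom == chroms[ci], , drop = FALSE]
    if (!nrow(tt)) next
    keep <- IRanges::setdiff(
      IRanges::IRanges(1L, Biostrings::width(ref)[ci]),
      IRanges::IRanges(tt$start + 1L, tt$end))
    pieces <- Biostrings::extractAt(ref[[ci]], keep)
    donor[[ci]] <- Biostrings::DNAString(paste(as.character(pieces),
                                               collapse = ""))
  }
  list(donor = donor, truth = truth)
}

empty_truth <- function() {
  t0 <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   svlen = integer(0), stringsAsFactors = FALSE)
  class(t0) <- c("truth_sv", "data.frame")
  t0
}

draw_read_lengths <- function(n, cfg) {
  L <- stats::rlnorm(n, meanlog = log(cfg$read_median), sdlog = cfg$read_sdlog)
  as.integer(pmin(pmax(round(L), cfg$read_min), cfg$read_max))
}

# Sample small-indel error events strictly interior to a match run of length
# m_len. Returns a data.frame(pos, type, len) with pos the 0-based offset of
# the event inside the run, events separated by > small_err_max_len so no two
# error ops (or an error op and a flanking true-deletion op) can fuse.
draw_error_events <- function(m_len, cfg) {
  none <- data.frame(pos = integer(0), type = character(0), len = integer(0),
                     stringsAsFactors = FALSE)
  if (m_len < 4L || (cfg$small_ins_rate <= 0 && cfg$small_del_rate <= 0))
    return(none)
  n_ins <- stats::rbinom(1L, m_len, cfg$small_ins_rate)
  n_del <- stats::rbinom(1L, m_len, cfg$small_del_rate)
  n_ev <- n_ins + n_del
  if (n_ev == 0L) return(none)
  interior <- (m_len - 2L)  # candidate offsets 1 .. m_len-2
  pos <- sort(sample.int(interior, min(n_ev, interior))) # 1-based offsets
  # enforce separation so consecutive ops keep an M run between them
  sep <- cfg$small_err_max_len + 1L
  keep <- c(TRUE, diff(pos) > sep)
  pos <- pos[keep]
  type <- sample(rep(c("I", "D"), times = c(n_ins, n_del)))[seq_along(pos)]
  len <- sample.int(cfg$small_err_max_len, length(pos), replace = TRUE)
  # a deletion event must stay inside the run with >= 1 M on each side
  d <- type == "D"
  len[d] <- pmin(len[d], pmax(1L, m_len - 1L - pos[d]))
  data.frame(pos = pos, type = type, len = as.integer(len),
             stringsAsFactors = FALSE)
}

# split one match run of length m_len into M/I/D ops around error events
inject_errors_into_run <- function(m_len, cfg) {
  ev <- draw_error_events(m_len, cfg)
  if (!nrow(ev)) return(list(op = "M", len = m_len))
  op <- character(0); len <- integer(0)
  cur <- 0L
  for (j in seq_len(nrow(ev))) {
    op <- c(op, "M"); len <- c(len, ev$pos[j] - cur)
    op <- c(op, ev$type[j]); len <- c(len, ev$len[j])
    cur <- ev$pos[j] + if (ev$type[j] == "D") ev$len[j] else 0L
  }
  if (m_len - cur > 0L) { op <- c(op, "M"); len <- c(len, m_len - cur) }
  list(op = op, len = as.integer(len))
}

collapse_cigar <- function(op, len) {
  keep <- len > 0L
  op <- op[keep]; len <- len[keep]
  if (!length(op)) return("*")
  same <- c(FALSE, op[-1] == op[-length(op)])
  grp <- cumsum(!same)
  len <- as.integer(tapply(len, grp, sum))
  op <- op[!same]
  paste0(len, op, collapse = "")
}

#' Simulate long reads with analytic alignments
#'
#' Reads are sampled from the donor genome (the reference with deletions
#' removed) and their alignments back to the reference are computed directly
#' from the known donor-to-reference coordinate map, so a read crossing a
#' deletion junction carries that deletion as a single D op of exactly its
#' length. Small indel sequencing errors are then injected into match runs
#' (always < 50 bp and never adjacent to a true deletion op). Secondary /
#' supplementary and unmapped decoy records are appended to exercise the FLAG
#' filter. No external aligner is involved; CIGAR semantics follow minimap2's
#' M-based convention.
#'
#' @param donor,truth output of [implant_deletions()].
#' @param ref the reference `DNAStringSet`.
#' @param cfg the [sim_config()].
#' @param sam_path optional path; when given, a coordinate-sorted SAM file is
#'   written with [write_sam()].
#' @return a data.frame of class `alignments` with columns `qname`, `flag`,
#'   `chrom`, `pos` (1-based), `mapq`, `cigar`, `read_len`, sorted by
#'   (chrom, pos), unmapped records last.
#' @export
simulate_reads <- function(donor, truth, ref, cfg, sam_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$coverage <= 0) stop("configuration error: coverage must be positive")
  set.seed(cfg$seed + 2L)
  chroms <- names(ref)
  recs <- list()
  read_no <- 0L
  for (ci in seq_along(chroms)) {
    dlen <- Biostrings::width(donor)[ci]
    tt <- truth[truth$chrom == chroms[ci], , drop = FALSE]
    # donor-coordinate junction of each deletion and cumulative shift
    junc <- if (nrow(tt)) tt$start - c(0L, cumsum(tt$svlen))[seq_len(nrow(tt))]
            else integer(0)
    svlen <- tt$svlen
    target <- cfg$coverage * dlen
    emitted <- 0
    while (emitted < target) {
      L <- draw_read_lengths(1L, cfg)
      if (L >= dlen) L <- dlen - 1L
      s <- floor(stats::runif(1, 0, dlen - L))
      e <- s + L
      shift <- if (length(junc)) sum(svlen[junc <= s]) else 0L
      ref_start <- s + shift
      inside <- which(junc > s & junc < e)
      # alternating M / D skeleton from the donor->reference map
      bounds <- c(s, junc[inside], e)
      op <- character(0); len <- integer(0)
      for (j in seq_along(bounds[-1])) {
        m <- bounds[j + 1L] - bounds[j]
        run <- inject_errors_into_run(m, cfg)
        op <- c(op, run$op); len <- c(len, run$len)
        if (j <= length(inside)) { op <- c(op, "D"); len <- c(len, svlen[inside[j]]) }
      }
      read_no <- read_no + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        qname = sprintf("read_%06d", read_no),
        flag = sample(c(0L, 16L), 1L),
        chrom = chroms[ci], pos = as.integer(ref_start + 1L), mapq = 60L,
        cigar = collapse_cigar(op, len),
        stringsAsFactors = FALSE)
      emitted <- emitted + L
    }
  }
  recs <- do.call(rbind, recs)
  # decoys: secondary/supplementary duplicates (truncated via soft clip)
  n_pri <- nrow(recs)
  n_sec <- round(cfg$frac_secondary * n_pri)
  if (n_sec > 0L) {
    pick <- sample.int(n_pri, n_sec, replace = n_sec > n_pri)
    sec <- recs[pick, , drop = FALSE]
    rl <- cigar_read_len(sec$cigar)
    h <- pmax(1L, rl %/% 2L)
    sec$cigar <- paste0(h, "M", rl - h, "S")
    sec$flag <- bitwOr(sec$flag, sample(c(256L, 2048L), n_sec, replace = TRUE))
    sec$mapq <- 0L
    recs <- rbind(recs, sec)
  }
  n_unm <- round(cfg$frac_unmapped * n_pri)
  if (n_unm > 0L) {
    unm <- data.frame(
      qname = sprintf("unmapped_%06d", seq_len(n_unm)),
      flag = 4L, chrom = NA_character_, pos = 0L, mapq = 0L, cigar = "*",
      stringsAsFactors = FALSE)
    recs <- rbind(recs, unm)
  }
  recs$read_len <- cigar_read_len(recs$cigar)
  ord <- order(is.na(recs$chrom), match(recs$chrom, chroms), recs$pos,
               recs$qname)
  recs <- recs[ord, , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- c("alignments", "data.frame")
  if (!is.null(sam_path)) write_sam(recs, ref_meta(ref), sam_path)
  recs
}

# read bases consumed by a CIGAR ("*" -> 0)
cigar_read_len <- function(cigar) {
  out <- integer(length(cigar))
  ok <- cigar != "*"
  if (any(ok))
    out[ok] <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar[ok])
  out
}

#' Write alignments to a SAM file
#'
#' Emits a minimal coordinate-sorted SAM (SEQ/QUAL as `*`; only placement and
#' CIGAR carry signal downstream).
#'
#' @param recs an `alignments` data.frame.
#' @param meta reference metadata from [ref_meta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(recs, meta, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", meta$chrom, meta$length),
           "@PG\tID:svdelnet\tPN:svdelnet")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  recs$qname, recs$flag,
                  ifelse(is.na(recs$chrom), "*", recs$chrom),
                  recs$pos, recs$mapq, recs$cigar)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a truth deletion set as VCF (+ BED mirror)
#'
#' Writes VCFv4.2 with one symbolic `<DEL>` record per truth interval
#' (POS = start + 1, INFO `SVTYPE=DEL;END=end;SVLEN=-svlen`) and a BED mirror
#' (0-based half-open) next to it.
#'
#' @param truth a `truth_sv` data.frame.
#' @param path output VCF path.
#' @param meta reference metadata from [ref_meta()]; contig lines are written
#'   from it and unknown chromosome names are an error.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path, meta) {
  bad <- setdiff(unique(truth$chrom), meta$chrom)
  if (length(bad))
    stop("reference mismatch: unknown chromosome(s) ", paste(bad, collapse = ", "))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svdelnet-simulator",
           sprintf("##contig=<ID=%s,length=%d>", meta$chrom, meta$length),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(truth))
    body <- sprintf("%s\t%d\tDEL%05d\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d",
                    truth$chrom, truth$start + 1L, seq_len(nrow(truth)),
                    truth$end, truth$svlen)
  writeLines(c(hdr, body), path)
  bed <- sub("\\.vcf$", ".bed", path)
  if (identical(bed, path)) bed <- paste0(path, ".bed")
  bed_body <- if (nrow(truth))
    sprintf("%s\t%d\t%d", truth$chrom, truth$start, truth$end) else character(0)
  writeLines(bed_body, bed)
  invisible(path)
}

#' Read a deletion truth/call VCF
#'
#' Parses DEL records (symbolic or sequence-resolved) back into the 0-based
#' half-open interval convention.
#'
#' @param path VCF path.
#' @return a `truth_sv` data.frame sorted by (chrom, start); `SUPPORT` and
#'   `QUAL`-derived columns are attached when present (see [read_sv_vcf()]).
#' @export
read_truth <- function(path) {
  v <- read_sv_vcf(path)
  t0 <- data.frame(chrom = v$chrom, start = v$start, end = v$end,
                   svlen = v$svlen, stringsAsFactors = FALSE)
  class(t0) <- c("truth_sv", "data.frame")
  t0
}

#' One-call synthetic dataset generator
#'
#' Convenience wrapper running [gen_reference()], [implant_deletions()] and
#' [simulate_reads()], optionally writing FASTA/SAM/VCF artifacts.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, writes `ref.fasta`,
#'   `reads.sam`, `truth.vcf` (+ `truth.bed`).
#' @return list with `ref`, `donor`, `truth`, `reads`, `meta` and (when `dir`
#'   is given) the file `paths`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "ref.fasta"),
                  sam = file.path(dir, "reads.sam"),
                  vcf = file.path(dir, "truth.vcf"))
    Biostrings::writeXStringSet(ref, paths$fasta)
  }
  reads <- simulate_reads(imp$donor, imp$truth, ref, cfg,
                          sam_path = if (is.null(dir)) NULL else paths$sam)
  if (!is.null(dir)) write_truth(imp$truth, paths$vcf, ref_meta(ref))
  list(ref = ref, donor = imp$donor, truth = imp$truth, reads = reads,
       meta = ref_meta(ref), paths = paths)
}
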