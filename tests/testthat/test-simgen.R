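small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 2L, chrom_length = 200000L, n_deletions = 4L,
         coverage = 8, read_median = 8000L, read_min = 1000L,
         read_max = 15000L, del_max = 8000L, seed = 1L),
    list(...))
  do.call(sim_config, args)
}

test_that("sim_config validates rates and geometry", {
  expect_error(sim_config(sub_rate = 1.5), "rates")
  expect_error(sim_config(small_err_max_len = 50), "< 50")
  expect_error(sim_config(chrom_length = 10000, del_max = 5000), "3x")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(n_chroms = 0), "non-positive")
})

test_that("reference generation is seeded, sized, and near-uniform", {
  cfg <- sim_config(n_chroms = 2L, chrom_length = 500000L, seed = 1L)
  ref1 <- gen_reference(cfg)
  ref2 <- gen_reference(cfg)
  expect_identical(as.character(ref1), as.character(ref2))
  expect_equal(length(ref1), 2L)
  expect_equal(Biostrings::width(ref1), c(500000L, 500000L))
  # binomial bound: each base frequency within 25% +/- 2% at 500 kb
  fr <- Biostrings::alphabetFrequency(ref1[[1]])[c("A", "C", "G", "T")]
  expect_true(all(abs(fr / 500000 - 0.25) < 0.02))
})

test_that("deletion implantation conserves length and sorts truth", {
  cfg <- small_cfg()
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  expect_equal(sum(Biostrings::width(imp$donor)) + sum(imp$truth$svlen),
               sum(Biostrings::width(ref)))
  for (ch in names(ref)) {
    tt <- imp$truth[imp$truth$chrom == ch, ]
    expect_equal(Biostrings::width(imp$donor)[names(ref) == ch],
                 cfg$chrom_length - sum(tt$svlen))
    if (nrow(tt) > 1) {
      expect_true(all(diff(tt$start) > 0))
      expect_true(all(tt$start[-1] - tt$end[-nrow(tt)] >=
                        2L * cfg$read_max))
    }
  }
  expect_true(all(imp$truth$svlen >= 50))
  expect_equal(imp$truth$svlen, imp$truth$end - imp$truth$start)
  # donor sequence equals reference with truth intervals excised
  ch1 <- as.character(ref[[1]])
  tt <- imp$truth[imp$truth$chrom == "chr1", ]
  kept <- ch1
  for (i in rev(seq_len(nrow(tt))))
    kept <- paste0(substr(kept, 1, tt$start[i]),
                   substr(kept, tt$end[i] + 1, nchar(kept)))
  expect_identical(as.character(imp$donor[[1]]), kept)
})

test_that("zero deletions yields donor == reference and empty truth", {
  cfg <- small_cfg(n_deletions = 0L)
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  expect_identical(as.character(imp$donor), as.character(ref))
  expect_equal(nrow(imp$truth), 0L)
})

test_that("deletion length law populates all five bins over a draw of 50", {
  cfg <- sim_config(n_chroms = 5L, chrom_length = 600000L,
                    n_deletions = 50L, read_max = 15000L, seed = 7L)
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  bins <- table(cut(imp$truth$svlen, c(50, 200, 500, 1000, 5000, Inf),
                    right = FALSE))
  expect_equal(sum(bins), 50)
  expect_true(all(bins > 0))
})

test_that("unplaceable deletions raise a placement error", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 70000L, n_deletions = 8L,
                    del_max = 20000L, read_max = 20000L, seed = 2L)
  ref <- gen_reference(cfg)
  expect_error(implant_deletions(ref, cfg), "placement error")
})

test_that("spanning reads carry each deletion as one exact D op", {
  cfg <- small_cfg()
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  reads <- simulate_reads(imp$donor, imp$truth, ref, cfg)
  pri <- reads[reads$flag < 256 & reads$flag != 4, ]
  for (i in seq_len(nrow(imp$truth))) {
    tv <- imp$truth[i, ]
    hits <- grepl(paste0("(^|[A-Z])", tv$svlen, "D"), pri$cigar) &
      pri$chrom == tv$chrom
    expect_gt(sum(hits), 0)
  }
  # no D op of >= 50 bp that is not a truth svlen
  dops <- regmatches(pri$cigar, gregexpr("[0-9]+D", pri$cigar))
  dlen <- as.integer(sub("D", "", unlist(dops)))
  big <- dlen[dlen >= 50]
  expect_true(all(big %in% imp$truth$svlen))
  expect_true(all(dlen[!dlen %in% imp$truth$svlen] < 50))
})

test_that("noise-free simulation of a deletion-free genome gives pure-M CIGARs", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 100000L, n_deletions = 0L,
                    coverage = 3, sub_rate = 0, small_ins_rate = 0,
                    small_del_rate = 0, frac_secondary = 0,
                    frac_unmapped = 0, read_max = 15000L, seed = 3L)
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  reads <- simulate_reads(imp$donor, imp$truth, ref, cfg)
  expect_true(all(grepl("^[0-9]+M$", reads$cigar)))
})

test_that("empirical depth tracks the configured coverage within 15%", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 300000L, n_deletions = 2L,
                    coverage = 30, read_max = 15000L, seed = 3L)
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  reads <- simulate_reads(imp$donor, imp$truth, ref, cfg)
  pri <- reads[reads$flag < 256 & reads$flag != 4, ]
  # M bases land on the non-deleted reference; D bases cover deleted bases
  m_bases <- sum(unlist(GenomicAlignments::explodeCigarOpLengths(
    pri$cigar, ops = "M")))
  depth <- m_bases / (cfg$chrom_length - sum(imp$truth$svlen))
  expect_gt(depth, 30 * 0.85)
  expect_lt(depth, 30 * 1.15)
})

test_that("decoy records carry the advertised FLAGs and proportions", {
  cfg <- small_cfg(frac_secondary = 0.1, frac_unmapped = 0.05)
  ref <- gen_reference(cfg)
  imp <- implant_deletions(ref, cfg)
  reads <- simulate_reads(imp$donor, imp$truth, ref, cfg)
  sec <- reads[bitwAnd(reads$flag, 256L) > 0 | bitwAnd(reads$flag, 2048L) > 0, ]
  unm <- reads[reads$flag == 4L, ]
  pri <- nrow(reads) - nrow(sec) - nrow(unm)
  expect_equal(nrow(sec), round(0.1 * pri))
  expect_equal(nrow(unm), round(0.05 * pri))
  expect_true(all(unm$cigar == "*"))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in c("ref.fasta", "reads.sam", "truth.vcf"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("truth VCF round-trips exactly and follows the coordinate convention", {
  truth <- make_truth("chr1", c(999, 5000), c(1599, 12000))
  meta <- data.frame(chrom = "chr1", length = 50000L)
  path <- tempfile(fileext = ".vcf")
  write_truth(truth, path, meta)
  lines <- readLines(path)
  rec <- strsplit(grep("^chr1", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(rec[2]), 1000L)            # POS is 1-based
  expect_match(rec[8], "SVTYPE=DEL")
  expect_match(rec[8], "END=1599")
  expect_match(rec[8], "SVLEN=-600")
  back <- read_truth(path)
  expect_equal(back$chrom, truth$chrom)
  expect_equal(back$start, truth$start)
  expect_equal(back$end, truth$end)
  expect_equal(back$svlen, truth$svlen)
  # BED mirror is 0-based half-open
  bed <- read.table(sub("\\.vcf$", ".bed", path))
  expect_equal(bed$V2, truth$start)
  expect_equal(bed$V3, truth$end)
  expect_error(write_truth(make_truth("chrX", 10, 100), tempfile("x", fileext = ".vcf"), meta),
               "reference mismatch")
})

test_that("an empty truth set writes a header-only VCF that reads back empty", {
  meta <- data.frame(chrom = "chr1", length = 1000L)
  path <- tempfile(fileext = ".vcf")
  write_truth(make_truth(character(0), integer(0), integer(0)), path, meta)
  expect_true(all(startsWith(readLines(path), "#")))
  expect_equal(nrow(read_truth(path)), 0L)
})

test_that("50-record truth round trip is exact", {
  set.seed(9)
  starts <- sort(sample.int(1e6, 50)) * 3L
  truth <- make_truth("chr1", starts, starts + sample(50:9000, 50, TRUE))
  meta <- data.frame(chrom = "chr1", length = 10000000L)
  path <- tempfile(fileext = ".vcf")
  write_truth(truth, path, meta)
  back <- read_truth(path)
  expect_equal(back, truth, ignore_attr = TRUE)
})
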