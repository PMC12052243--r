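sam_cigar_re <- "^(\\*|([0-9]+[MIDNSHP=X])+)$"

#' Parse a CIGAR string into operations
#'
#' `=`/`X` are normalized to `M` (adjacent runs merged).
#'
#' @param cigar a single CIGAR string.
#' @param qname record name used in error messages.
#' @return data.frame with columns `op`, `len`.
#' @export
parse_cigar <- function(cigar, qname = "?") {
  if (!grepl(sam_cigar_re, cigar))
    stop(sprintf("parse error: record '%s' has malformed CIGAR '%s'",
                 qname, cigar))
  if (cigar == "*") return(data.frame(op = character(0), len = integer(0)))
  op <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  len <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  op[op %in% c("=", "X")] <- "M"
  same <- c(FALSE, op[-1] == op[-length(op)])
  grp <- cumsum(!same)
  data.frame(op = op[!same],
             len = as.integer(tapply(len, grp, sum)),
             stringsAsFactors = FALSE)
}

normalize_cigar <- function(cigar, qname = "?") {
  p <- parse_cigar(cigar, qname)
  if (!nrow(p)) return("*")
  paste0(p$len, p$op, collapse = "")
}

#' Read long-read alignments from SAM/BAM
#'
#' SAM input is converted with [Rsamtools::asBam()] (after validating the
#' CIGAR column against the SAM grammar, since htslib silently drops
#' malformed records); records are returned in (chrom, pos) order with
#' `=`/`X` CIGAR ops normalized to `M`.
#'
#' @param path a `.sam` or `.bam` file.
#' @param region optional samtools-style region string `"chrom:start-end"`
#'   (1-based inclusive); requires a BAM index (created on the fly for SAM
#'   input).
#' @return an `alignments` data.frame (`qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `read_len`).
#' @export
read_alignments <- function(path, region = NULL) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "@")]
    if (length(body)) {
      f <- strsplit(body, "\t", fixed = TRUE)
      cg <- vapply(f, `[[`, "", 6L)
      qn <- vapply(f, `[[`, "", 1L)
      bad <- which(!grepl(sam_cigar_re, cg))
      if (length(bad))
        stop(sprintf("parse error: record '%s' has malformed CIGAR '%s'",
                     qn[bad[1]], cg[bad[1]]))
    }
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!is.null(region) && !file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam)))
      stop("usage error: region query requires a BAM index (.bai)")
  }
  param_what <- c("qname", "flag", "rname", "pos", "mapq", "cigar")
  if (is.null(region)) {
    prm <- Rsamtools::ScanBamParam(what = param_what)
  } else {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("usage error: bad region string: ", region)
    gr <- GenomicRanges::GRanges(m[2],
                                 IRanges::IRanges(as.integer(m[3]),
                                                  as.integer(m[4])))
    prm <- Rsamtools::ScanBamParam(what = param_what, which = gr)
  }
  res <- Rsamtools::scanBam(bam, param = prm)
  res <- do.call(Map, c(list(c), res))  # concatenate region chunks
  cig <- as.character(res$cigar)
  need <- !is.na(cig) & grepl("[=X]", cig)
  cig[need] <- vapply(which(need), function(i)
    normalize_cigar(cig[i], res$qname[i]), character(1))
  cig[is.na(cig)] <- "*"
  recs <- data.frame(
    qname = as.character(res$qname),
    flag = as.integer(res$flag),
    chrom = as.character(res$rname),
    pos = ifelse(is.na(res$pos), 0L, as.integer(res$pos)),
    mapq = ifelse(is.na(res$mapq), 0L, as.integer(res$mapq)),
    cigar = cig,
    stringsAsFactors = FALSE)
  recs$read_len <- cigar_read_len(recs$cigar)
  ord <- order(is.na(recs$chrom), recs$chrom, recs$pos, recs$qname)
  recs <- recs[ord, , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- c("alignments", "data.frame")
  recs
}

#' Filter alignment records by SAM FLAG
#'
#' A record is kept iff `flag != 4` and `flag < 256`: unmapped, secondary
#' (0x100), supplementary (0x800) and duplicate-range records are all removed
#' before graph construction.
#'
#' @param recs an `alignments` data.frame.
#' @return the filtered `alignments` data.frame (possibly empty).
#' @export
filter_records <- function(recs) {
  keep <- recs$flag != 4L & recs$flag < 256L
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

op_codes <- c(M = 0L, I = 1L, D = 2L, S = 3L)

#' Decompose one alignment into typed segments with dual coordinates
#'
#' Walks the CIGAR with a reference cursor (0-based, starting at `pos - 1`)
#' and a read cursor. Each retained op becomes one segment carrying both its
#' reference and read interval (half-open). I and D ops shorter than
#' `min_svlen` are absorbed: a small D advances the reference cursor, a small
#' I the read cursor, and the flanking match context is coalesced into a
#' single match segment (whose reference and read spans may therefore
#' differ; its `length` is the larger of the two extents). `S` emits a clip
#' segment,
#' `H` and `P` emit nothing, and `N` advances the reference like a deletion
#' but never emits a variant segment.
#'
#' @param record one row of an `alignments` data.frame (must have survived
#'   [filter_records()]).
#' @param min_svlen minimum indel length (bp) kept as a variant segment.
#' @return data.frame of class `segments`: `op_code` (0 match, 1 insertion,
#'   2 deletion, 3 clip), `length`, `ref_start`, `ref_end`, `read_start`,
#'   `read_end`, in read order.
#' @export
segment_ops <- function(record, min_svlen = 50L) {
  if (min_svlen < 1L) stop("configuration error: min_svlen must be >= 1")
  p <- parse_cigar(record$cigar, record$qname)
  ref <- record$pos - 1L
  rd <- 0L
  segs <- list()
  # open coalesced match context: NA when closed
  m_ref0 <- NA_integer_; m_rd0 <- NA_integer_
  open_match <- function(r, q) {
    if (is.na(m_ref0)) { m_ref0 <<- r; m_rd0 <<- q }
  }
  close_match <- function() {
    if (!is.na(m_ref0) && (ref > m_ref0 || rd > m_rd0)) {
      segs[[length(segs) + 1L]] <<- data.frame(
        op_code = 0L, length = max(ref - m_ref0, rd - m_rd0),
        ref_start = m_ref0, ref_end = ref,
        read_start = m_rd0, read_end = rd)
    }
    m_ref0 <<- NA_integer_; m_rd0 <<- NA_integer_
  }
  emit <- function(code, len, r0, r1, q0, q1) {
    close_match()
    segs[[length(segs) + 1L]] <<- data.frame(
      op_code = code, length = len, ref_start = r0, ref_end = r1,
      read_start = q0, read_end = q1)
  }
  for (i in seq_len(nrow(p))) {
    op <- p$op[i]; len <- p$len[i]
    if (op == "M") {
      open_match(ref, rd); ref <- ref + len; rd <- rd + len
    } else if (op == "I") {
      if (len >= min_svlen) {
        emit(1L, len, ref, ref, rd, rd + len)
      } else open_match(ref, rd)
      rd <- rd + len
    } else if (op == "D") {
      if (len >= min_svlen) {
        emit(2L, len, ref, ref + len, rd, rd)
      } else open_match(ref, rd)
      ref <- ref + len
    } else if (op == "N") {
      open_match(ref, rd)   # splice-like skip: consumption only
      ref <- ref + len
    } else if (op == "S") {
      emit(3L, len, ref, ref, rd, rd + len)
      rd <- rd + len
    }                       # H, P: no consumption of either sequence
  }
  close_match()
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(op_code = integer(0), length = integer(0),
               ref_start = integer(0), ref_end = integer(0),
               read_start = integer(0), read_end = integer(0))
  rownames(out) <- NULL
  class(out) <- c("segments", "data.frame")
  out
}
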