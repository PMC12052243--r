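length_bins <- function() {
  data.frame(lo = c(50, 200, 500, 1000, 5000),
             hi = c(200, 500, 1000, 5000, Inf),
             name = c("[50,200)", "[200,500)", "[500,1000)",
                      "[1000,5000)", "[5000,Inf)"),
             stringsAsFactors = FALSE)
}

bin_of <- function(svlen) {
  b <- length_bins()
  findInterval(svlen, c(b$lo, Inf))
}

#' Write deletion calls as VCF
#'
#' VCFv4.2 with one symbolic `<DEL>` record per call: `POS = start + 1`,
#' `REF = N`, `ALT = <DEL>`, `QUAL = round(100 * score)` and INFO
#' `SVTYPE=DEL;END=end;SVLEN=-svlen;SUPPORT=support`. Contig header lines
#' come from `meta`; a call extending beyond its contig is an error.
#'
#' @param calls an `sv_calls` data.frame (sorted).
#' @param meta reference metadata from [ref_meta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, meta, path) {
  bad <- setdiff(unique(calls$chrom), meta$chrom)
  if (length(bad))
    stop("reference mismatch: unknown chromosome(s) ",
         paste(bad, collapse = ", "))
  lim <- meta$length[match(calls$chrom, meta$chrom)]
  if (any(calls$end > lim))
    stop("reference mismatch: call beyond contig length")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svdelnet",
           sprintf("##contig=<ID=%s,length=%d>", meta$chrom, meta$length),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of distinct supporting reads\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls))
    body <- sprintf(
      "%s\t%d\tDEL%05d\tN\t<DEL>\t%d\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d;SUPPORT=%d",
      calls$chrom, calls$start + 1L, seq_len(nrow(calls)),
      as.integer(round(100 * calls$score)), calls$end, calls$svlen,
      calls$support)
  writeLines(c(hdr, body), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' Read deletion calls from a VCF
#'
#' Parses DEL records (INFO `SVTYPE=DEL` with `END` and/or `SVLEN`) back to
#' 0-based half-open intervals; `SUPPORT` and `QUAL` are recovered when
#' present.
#'
#' @param path a VCF file.
#' @return an `sv_calls` data.frame sorted by (chrom, start).
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), svlen = integer(0),
                      support = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    class(empty) <- c("sv_calls", "data.frame")
    return(empty)
  }
  svtype <- info_field(fix$INFO, "SVTYPE")
  del <- which(svtype == "DEL" | grepl("<DEL>", fix$ALT, fixed = TRUE))
  fix <- fix[del, , drop = FALSE]
  if (!nrow(fix)) {
    class(empty) <- c("sv_calls", "data.frame")
    return(empty)
  }
  start <- as.integer(fix$POS) - 1L
  end <- suppressWarnings(as.integer(info_field(fix$INFO, "END")))
  svlen <- suppressWarnings(abs(as.integer(info_field(fix$INFO, "SVLEN"))))
  end[is.na(end)] <- start[is.na(end)] + svlen[is.na(end)]
  svlen[is.na(svlen)] <- end[is.na(svlen)] - start[is.na(svlen)]
  support <- suppressWarnings(as.integer(info_field(fix$INFO, "SUPPORT")))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  out <- data.frame(chrom = fix$CHROM, start = start, end = end,
                    svlen = svlen,
                    support = ifelse(is.na(support), 0L, support),
                    score = ifelse(is.na(qual), 0, qual / 100),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Score predicted calls against a truth set
#'
#' A predicted call and a truth interval on the same chromosome match iff
#' both breakpoints agree within `bp_tol` and their reciprocal overlap
#' (overlap divided by the longer interval) is at least `min_ro`. Matching
#' is greedy one-to-one by descending reciprocal overlap (ties to the
#' leftmost truth start, then leftmost predicted start). Per-bin metrics
#' use the five deletion-length bins [50,200), [200,500), [500,1000),
#' [1000,5000), [5000,Inf): recall bins by truth length, precision bins by
#' predicted length.
#'
#' @param pred an `sv_calls` (or compatible) data.frame, sorted.
#' @param truth a `truth_sv` data.frame, sorted, non-overlapping.
#' @param bp_tol breakpoint tolerance (bp).
#' @param min_ro reciprocal-overlap threshold.
#' @return an object of class `eval_result`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `per_bin` (data.frame), `matches` (index pairs).
#' @export
evaluate_calls <- function(pred, truth, bp_tol = 1000, min_ro = 0.7) {
  tt <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  for (ch in unique(tt$chrom)) {
    cc <- tt[tt$chrom == ch, , drop = FALSE]
    if (nrow(cc) > 1L && any(cc$start[-1L] < cc$end[-nrow(cc)]))
      stop("invariant error: overlapping truth records on ", ch)
  }
  np <- nrow(pred); nt <- nrow(tt)
  pairs <- NULL
  if (np && nt) {
    cand <- list()
    for (i in seq_len(np)) {
      j <- which(tt$chrom == pred$chrom[i] &
                   abs(pred$start[i] - tt$start) <= bp_tol &
                   abs(pred$end[i] - tt$end) <= bp_tol)
      if (!length(j)) next
      ov <- pmin(pred$end[i], tt$end[j]) - pmax(pred$start[i], tt$start[j])
      ro <- ov / pmax(pred$end[i] - pred$start[i], tt$end[j] - tt$start[j])
      ok <- ro >= min_ro
      if (any(ok))
        cand[[length(cand) + 1L]] <- data.frame(p = i, t = j[ok],
                                                ro = ro[ok])
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(-cand$ro, tt$start[cand$t], pred$start[cand$p]), ,
                   drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        if (!used_p[cand$p[k]] && !used_t[cand$t[k]]) {
          keep[k] <- TRUE
          used_p[cand$p[k]] <- TRUE
          used_t[cand$t[k]] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- np - tp
  fn <- nt - tp
  prf <- function(tp, fp, fn) {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    c(precision = precision, recall = recall, f1 = f1)
  }
  overall <- prf(tp, fp, fn)
  b <- length_bins()
  pb <- bin_of(pred$svlen)
  tb <- bin_of(tt$svlen)
  matched_p <- if (is.null(pairs)) integer(0) else pairs$p
  matched_t <- if (is.null(pairs)) integer(0) else pairs$t
  per_bin <- do.call(rbind, lapply(seq_len(nrow(b)), function(k) {
    tp_t <- sum(tb[matched_t] == k)        # matched truth in bin (recall)
    fn_k <- sum(tb == k) - tp_t
    tp_p <- sum(pb[matched_p] == k)        # matched preds in bin (precision)
    fp_k <- sum(pb == k) - tp_p
    pr <- if (tp_p + fp_k > 0) tp_p / (tp_p + fp_k) else 0
    rc <- if (tp_t + fn_k > 0) tp_t / (tp_t + fn_k) else 0
    f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    data.frame(bin = b$name[k], truth_n = sum(tb == k), tp = tp_t,
               fn = fn_k, pred_n = sum(pb == k), fp = fp_k,
               precision = pr, recall = rc, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  res <- list(tp = tp, fp = fp, fn = fn,
              precision = unname(overall["precision"]),
              recall = unname(overall["recall"]),
              f1 = unname(overall["f1"]),
              per_bin = per_bin, matches = pairs)
  class(res) <- "eval_result"
  res
}

#' @method print eval_result
#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\nprecision %.4f  recall %.4f  f1 %.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  cat("per length bin:\n")
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param res an `eval_result`.
#' @param path output TSV path (overall row plus one row per bin).
#' @return `path`, invisibly.
#' @export
write_eval_tsv <- function(res, path) {
  overall <- data.frame(bin = "overall", truth_n = res$tp + res$fn,
                        tp = res$tp, fn = res$fn,
                        pred_n = res$tp + res$fp, fp = res$fp,
                        precision = res$precision, recall = res$recall,
                        f1 = res$f1, stringsAsFactors = FALSE)
  utils::write.table(rbind(overall, res$per_bin), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
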