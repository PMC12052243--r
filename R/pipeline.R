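#' Run configuration
#'
#' Merged view of every stage's tunables, loadable from YAML and
#' overridable by name. Every field has a default; unknown fields are an
#' error so typos fail fast.
#'
#' @param yaml_path optional YAML file whose top-level keys override the
#'   defaults.
#' @param ... named overrides applied after the YAML file.
#' @return a `run_config` list with components `min_svlen`, `length_scale`,
#'   `model` (a [model_config()]), `eps`, `min_samples`, `alpha`, `ratio`,
#'   `merge_mode`, `min_support`, `bp_tol`, `min_ro`, `seed`.
#' @export
run_config <- function(yaml_path = NULL, ...) {
  defaults <- list(
    min_svlen = 50L, length_scale = 1 / 1000,
    d1 = 8L, d2 = 4L, grid = 5L, degree = 3L, head = "kan_fc",
    weight = 0.9, lambda = 1e-4, lr = 1e-3, epochs = 50L, batch_size = 32L,
    eps = 500, min_samples = 2L, alpha = 3000, ratio = 0.7,
    merge_mode = "any", min_support = 2L,
    bp_tol = 1000, min_ro = 0.7, seed = 42L)
  ov <- list()
  if (!is.null(yaml_path)) ov <- yaml::read_yaml(yaml_path)
  ov <- utils::modifyList(ov, list(...))
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, ov)
  cfg$model <- model_config(
    d1 = cfg$d1, d2 = cfg$d2, grid = cfg$grid, degree = cfg$degree,
    head = cfg$head, length_scale = cfg$length_scale, weight = cfg$weight,
    lambda = cfg$lambda, lr = cfg$lr, epochs = cfg$epochs,
    batch_size = cfg$batch_size, seed = cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(verbose, ...) {
  if (verbose) message(sprintf("[svdelnet] %s", sprintf(...)))
}

#' Train a deletion classifier from alignments and a truth set
#'
#' Reads alignments, applies the FLAG filter, builds labeled graphs
#' (optionally restricted to training chromosomes), and trains the
#' classifier.
#'
#' @param sam_path SAM/BAM with long-read alignments.
#' @param truth_path truth deletion VCF.
#' @param cfg a [run_config()].
#' @param chroms optional character vector restricting training to these
#'   chromosomes (the validation split stays untouched).
#' @param checkpoint optional path; when given the trained parameters are
#'   saved there.
#' @param verbose log stage progress to stderr.
#' @return trained `gkn_params` (with loss `history` attribute).
#' @export
sv_train <- function(sam_path, truth_path, cfg = run_config(),
                     chroms = NULL, checkpoint = NULL, verbose = FALSE) {
  recs <- read_alignments(sam_path)
  truth <- read_truth(truth_path)
  n0 <- nrow(recs)
  recs <- filter_records(recs)
  log_msg(verbose, "train: %d records in, %d removed by FLAG filter",
          n0, n0 - nrow(recs))
  if (!is.null(chroms)) recs <- recs[recs$chrom %in% chroms, , drop = FALSE]
  graphs <- graphs_from_alignments(
    recs, truth, min_svlen = cfg$min_svlen,
    scales = graph_scales(cfg$length_scale))
  log_msg(verbose, "train: %d graphs, %d nodes", length(graphs),
          sum(vapply(graphs, function(g) nrow(g$feat), integer(1))))
  params <- train_model(graphs, cfg$model, seed = cfg$seed)
  if (!is.null(checkpoint)) save_checkpoint(params, checkpoint)
  params
}

#' Call deletions from alignments
#'
#' The four-stage calling pipeline: alignment ingestion and FLAG/length
#' filtering, graph representation, node classification, and candidate
#' consolidation (density clustering, fragment merging, secondary
#' clustering).
#'
#' @param sam_path SAM/BAM with long-read alignments.
#' @param params trained `gkn_params` or a checkpoint path.
#' @param cfg a [run_config()].
#' @param chroms optional chromosome restriction.
#' @param vcf_path optional output VCF; requires `meta`.
#' @param meta reference metadata from [ref_meta()] (contig lines for the
#'   VCF); when `NULL` it is reconstructed from the SAM header via
#'   [Rsamtools::scanBamHeader()].
#' @param verbose log stage progress (record counts, node counts, candidate
#'   and call counts) to stderr.
#' @return an `sv_calls` data.frame; the raw `candidates` are attached as
#'   attribute `"candidates"`.
#' @export
sv_call <- function(sam_path, params, cfg = run_config(), chroms = NULL,
                    vcf_path = NULL, meta = NULL, verbose = FALSE) {
  if (is.character(params)) params <- load_checkpoint(params)
  recs <- read_alignments(sam_path)
  n0 <- nrow(recs)
  recs <- filter_records(recs)
  log_msg(verbose, "call: %d records in, %d removed by FLAG filter",
          n0, n0 - nrow(recs))
  if (!is.null(chroms)) recs <- recs[recs$chrom %in% chroms, , drop = FALSE]
  graphs <- graphs_from_alignments(
    recs, truth = NULL, min_svlen = cfg$min_svlen,
    scales = graph_scales(cfg$length_scale))
  log_msg(verbose, "call: %d graphs", length(graphs))
  preds <- predict_nodes(graphs, params)
  cands <- extract_candidates(graphs, preds)
  log_msg(verbose, "call: %d candidate deletion nodes", nrow(cands))
  calls <- consolidate_candidates(
    cands, eps = cfg$eps, min_samples = cfg$min_samples,
    alpha = cfg$alpha, ratio = cfg$ratio, mode = cfg$merge_mode,
    min_support = cfg$min_support)
  log_msg(verbose, "call: %d consensus calls", nrow(calls))
  if (!is.null(vcf_path)) {
    if (is.null(meta)) {
      hd <- Rsamtools::scanBamHeader(
        if (grepl("\\.sam$", sam_path)) Rsamtools::asBam(
          sam_path, tempfile(), overwrite = TRUE) else sam_path)[[1]]
      meta <- data.frame(chrom = names(hd$targets),
                         length = as.integer(hd$targets),
                         stringsAsFactors = FALSE)
    }
    write_vcf(calls, meta, vcf_path)
  }
  attr(calls, "candidates") <- cands
  calls
}
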