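#' Reference synthetic benchmarks
#'
#' Fixed study conditions used by the package's own validation runs:
#'
#' * `standard` — 50 deletions spanning all five length bins over a
#'   4 x 800 kb genome at 30x coverage with ONT-like 8% error (4%
#'   substitutions, 2% small insertions, 2% small deletions), seed 7.
#' * `noise_free` — 20 deletions over 2 x 700 kb at 20x with all error
#'   rates and decoy fractions zero, seed 1.
#' * `long_deletion` — ten deletions of at least 5 kb over 2 x 500 kb at
#'   30x with the ONT-like error profile, seed 1.
#'
#' @param type benchmark name.
#' @param seed optional seed override (defaults to the condition's seed).
#' @return a [sim_config()].
#' @export
benchmark_sim_config <- function(type = c("standard", "noise_free",
                                          "long_deletion"),
                                 seed = NULL) {
  type <- match.arg(type)
  cfg <- switch(type,
    standard = sim_config(n_chroms = 4L, chrom_length = 800000L,
                          n_deletions = 50L, coverage = 30,
                          sub_rate = 0.04, small_ins_rate = 0.02,
                          small_del_rate = 0.02, seed = 7L),
    noise_free = sim_config(n_chroms = 2L, chrom_length = 700000L,
                            n_deletions = 20L, coverage = 20,
                            sub_rate = 0, small_ins_rate = 0,
                            small_del_rate = 0, frac_secondary = 0,
                            frac_unmapped = 0, seed = 1L),
    long_deletion = sim_config(n_chroms = 2L, chrom_length = 500000L,
                               n_deletions = 10L, coverage = 30,
                               del_min = 5000L, del_max = 20000L,
                               sub_rate = 0.04, small_ins_rate = 0.02,
                               small_del_rate = 0.02, seed = 1L))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

#' Simulate a benchmark and split it by chromosome
#'
#' Simulates reads under a benchmark condition and splits the labeled
#' graphs chromosome-wise into a training half and a held-out evaluation
#' half (the first half of the chromosomes trains, the rest evaluates),
#' mirroring the train-on-some-chromosomes / validate-on-the-rest protocol.
#'
#' @param cfg a [sim_config()], typically from [benchmark_sim_config()].
#' @return list with `sim` (the [simulate_dataset()] output),
#'   `graphs_train`, `graphs_eval` (labeled `read_graph` lists) and
#'   `truth_eval` (truth restricted to the evaluation chromosomes).
#' @export
benchmark_data <- function(cfg) {
  sim <- simulate_dataset(cfg)
  chroms <- names(sim$ref)
  train_chr <- chroms[seq_len(max(1L, length(chroms) %/% 2L))]
  eval_chr <- setdiff(chroms, train_chr)
  if (!length(eval_chr)) eval_chr <- train_chr
  recs <- filter_records(sim$reads)
  g_tr <- graphs_from_alignments(recs[recs$chrom %in% train_chr, ,
                                      drop = FALSE], sim$truth)
  g_ev <- graphs_from_alignments(recs[recs$chrom %in% eval_chr, ,
                                      drop = FALSE], sim$truth)
  truth_eval <- sim$truth[sim$truth$chrom %in% eval_chr, , drop = FALSE]
  class(truth_eval) <- c("truth_sv", "data.frame")
  list(sim = sim, train_chroms = train_chr, eval_chroms = eval_chr,
       graphs_train = g_tr, graphs_eval = g_ev, truth_eval = truth_eval)
}

#' Node-level classification scores on labeled graphs
#'
#' @param graphs labeled `read_graph` list.
#' @param params trained `gkn_params`.
#' @return named vector with `precision`, `recall`, `f1` over node labels.
#' @export
node_scores <- function(graphs, params) {
  pr <- predict_nodes(graphs, params)
  lab <- unlist(lapply(graphs, `[[`, "labels"))
  hard <- unlist(lapply(pr, `[[`, "label"))
  tp <- sum(hard == 1L & lab == 1L)
  fp <- sum(hard == 1L & lab == 0L)
  fn <- sum(hard == 0L & lab == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Train, call and evaluate one benchmark split
#'
#' Trains the classifier on the training graphs (12 epochs suffice on
#' these well-separated synthetic conditions), predicts the evaluation
#' graphs, consolidates candidates into calls, and scores both the raw
#' per-node candidates and the consolidated calls against the held-out
#' truth.
#'
#' @param data a [benchmark_data()] result.
#' @param head classifier head (see [model_config()]).
#' @param epochs training epochs.
#' @param seed training seed.
#' @return list with `params`, `node` (node-level scores on the held-out
#'   half), `candidates`, `calls`, `eval_raw` (per-node candidates scored
#'   as calls) and `eval` (consolidated calls scored).
#' @export
benchmark_run <- function(data, head = "kan_fc", epochs = 12L, seed = 7L) {
  params <- train_model(data$graphs_train,
                        model_config(head = head, epochs = epochs,
                                     seed = seed))
  pr <- predict_nodes(data$graphs_eval, params)
  cands <- extract_candidates(data$graphs_eval, pr)
  calls <- consolidate_candidates(cands)
  list(params = params,
       node = node_scores(data$graphs_eval, params),
       candidates = cands, calls = calls,
       eval_raw = evaluate_calls(cands, data$truth_eval),
       eval = evaluate_calls(calls, data$truth_eval))
}
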