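# Confusion-matrix evaluation of an inferred network against a gold
# standard of directed TF -> target edges, over a declared pair universe.

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Confusion counts of a network against a gold standard
#'
#' Tallies true/false positives and negatives over an explicitly declared
#' pair universe. Under `"tf_by_target"` (the default, matching a gold
#' standard that covers only a small set of transcription factors) the
#' universe is every (tf, target) pair with `tf` in the gold standard's TF
#' list and `target` among the network's genes (target != tf); an undirected
#' predicted edge {a, b} predicts the pair (a, b) when `a` is a TF and
#' (b, a) when `b` is a TF, and predicted edges touching no TF are outside
#' the universe. Under `"all_pairs"` the universe is every unordered gene
#' pair and gold edges are symmetrized.
#'
#' @param net A `grn_network`.
#' @param gold A `gold_standard`; the network's genes must all appear in its
#'   `gene_universe`.
#' @param universe_mode `"tf_by_target"` or `"all_pairs"`.
#' @return A `confusion_counts` list: `tp`, `fp`, `fn`, `tn`,
#'   `universe_size`, `universe_mode`, `n_predicted`.
#' @export
confusion_vs_gold <- function(net, gold,
                              universe_mode = c("tf_by_target", "all_pairs")) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(inherits(net, "grn_network"), inherits(gold, "gold_standard"))
  if (!all(net$gene_ids %in% gold$gene_universe)) {
    stopf("network contains genes outside the gold standard's gene universe")
  }
  edges <- network_edges(net)

  if (universe_mode == "tf_by_target") {
    tfs <- gold$tf_ids
    genes <- net$gene_ids
    universe_size <- as.integer(length(tfs) * length(genes) -
                                  sum(tfs %in% genes))  # no (tf, tf) pairs
    pred <- character(0)
    if (nrow(edges) > 0L) {
      a_tf <- edges$gene_a %in% tfs
      b_tf <- edges$gene_b %in% tfs
      pred <- unique(c(pair_key(edges$gene_a[a_tf], edges$gene_b[a_tf]),
                       pair_key(edges$gene_b[b_tf], edges$gene_a[b_tf])))
    }
    in_univ <- gold$edges[, 1L] %in% tfs & gold$edges[, 2L] %in% genes
    gold_keys <- unique(pair_key(gold$edges[in_univ, 1L],
                                 gold$edges[in_univ, 2L]))
  } else {
    genes <- net$gene_ids
    universe_size <- as.integer(length(genes) * (length(genes) - 1L) / 2)
    pred <- if (nrow(edges) > 0L) pair_key(edges$gene_a, edges$gene_b) else character(0)
    ga <- pmin(gold$edges[, 1L], gold$edges[, 2L])
    gb <- pmax(gold$edges[, 1L], gold$edges[, 2L])
    keep <- ga %in% genes & gb %in% genes
    gold_keys <- unique(pair_key(ga[keep], gb[keep]))
  }

  tp <- sum(pred %in% gold_keys)
  fp <- length(pred) - tp
  fn <- length(gold_keys) - tp
  tn <- universe_size - tp - fp - fn
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         universe_size = universe_size, universe_mode = universe_mode,
         n_predicted = length(pred)),
    class = "confusion_counts"
  )
}

#' Diagnostic accuracy measures from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `specificity = TN/(TN+FP)`.
#' A measure with a zero denominator is returned as 0 and named in the
#' `flagged` component rather than propagating NaN.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/fn/tn).
#' @return A list with `precision`, `recall`, `accuracy`, `specificity` and
#'   `flagged` (character vector of degenerate measures).
#' @export
diagnostic_measures <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total <= 0) stopf("universe size must be positive")
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flagged <<- c(flagged, name); return(0) }
    num / den
  }
  list(
    precision = safe(tp, tp + fp, "precision"),
    recall = safe(tp, tp + fn, "recall"),
    accuracy = (tp + tn) / total,
    specificity = safe(tn, tn + fp, "specificity"),
    flagged = flagged
  )
}

#' Support-recovery F1 of a network against a true precision support
#'
#' Compares the unordered edge set of a thresholded network with the true
#' conditional-dependence pairs of a simulated precision matrix.
#'
#' @param net A `grn_network` over the simulated genes.
#' @param support Two-column matrix of true pairs (indices into
#'   `net$gene_ids`, i < j).
#' @return F1 = 2 * precision * recall / (precision + recall) (0 when both
#'   are 0).
#' @export
support_f1 <- function(net, support) {
  genes <- net$gene_ids
  truth_keys <- if (nrow(support) > 0L) {
    pair_key(genes[support[, 1L]], genes[support[, 2L]])
  } else character(0)
  edges <- network_edges(net)
  # network_edges orders lexicographically; support is index-ordered, so
  # normalize both to sorted-id keys
  norm_key <- function(a, b) pair_key(pmin(a, b), pmax(a, b))
  pred_keys <- if (nrow(edges) > 0L) norm_key(edges$gene_a, edges$gene_b) else character(0)
  truth_keys <- if (length(truth_keys) > 0L) {
    a <- genes[support[, 1L]]; b <- genes[support[, 2L]]
    norm_key(a, b)
  } else character(0)
  tp <- sum(pred_keys %in% truth_keys)
  prec <- if (length(pred_keys) > 0L) tp / length(pred_keys) else 0
  rec <- if (length(truth_keys) > 0L) tp / length(truth_keys) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
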