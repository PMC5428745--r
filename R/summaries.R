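# Posterior summarization: MAP pseudotimes and branches, bifurcation-gene
# ranking via the inverse shrinkage precision, agreement-maximizing label
# matching, and small evaluation helpers.

check_trace <- function(trace) {
  if (!inherits(trace, "bmfa_trace")) stop_invalid("not a bmfa_trace")
  if (n_states(trace) < 1L) stop_invalid("trace holds no kept states")
  invisible(trace)
}

#' MAP pseudotime estimates
#'
#' "MAP" is operationalized as the posterior mean over kept states (the
#' marginal posterior of each `t_i` is unimodal within the mode the sampler
#' explores); `method = "best"` instead returns the single kept state with
#' the highest joint log density. Equal-tailed credible intervals are
#' computed from the kept states.
#'
#' @param trace A `bmfa_trace`.
#' @param level Credible-interval level (default 0.95).
#' @param method `"mean"` (default) or `"best"` (joint-maximizing sample).
#' @return A data.frame with columns `cell_id`, `t_map`, `t_lower`,
#'   `t_upper`.
#' @export
map_pseudotime <- function(trace, level = 0.95, method = c("mean", "best")) {
  check_trace(trace)
  method <- match.arg(method)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_invalid("level must lie in (0, 1)")
  t_map <- if (method == "mean") colMeans(trace$t)
           else trace$t[which.max(trace$log_joint), ]
  a <- (1 - level) / 2
  qs <- apply(trace$t, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(cell_id = trace$meta$cell_ids, t_map = t_map,
             t_lower = qs[1L, ], t_upper = qs[2L, ],
             stringsAsFactors = FALSE)
}

#' MAP branch assignments
#'
#' Per cell, the modal branch label over kept states; ties break toward the
#' smaller label index.
#'
#' @param trace A `bmfa_trace`.
#' @return Integer vector of labels in `1..B`, named by cell id.
#' @export
map_branch <- function(trace) {
  check_trace(trace)
  B <- trace$meta$B
  lab <- apply(trace$gamma, 2L, function(g) which.max(tabulate(g, B)))
  stats::setNames(as.integer(lab), trace$meta$cell_ids)
}

#' Gene relevance to the bifurcation via inverse shrinkage precision
#'
#' A gene whose branch gradients the data hold apart gets a small posterior
#' shrinkage precision `chi_g`, so `1 / E[chi_g | Y]` ranks genes by the
#' evidence that they are involved in the bifurcation (largest score =
#' strongest evidence).
#'
#' @param trace A `bmfa_trace`.
#' @return A data.frame with columns `gene_id`, `chi_inverse` and `rank`
#'   (1 = most bifurcation-associated), in input gene order.
#' @export
chi_relevance <- function(trace) {
  check_trace(trace)
  score <- 1 / colMeans(trace$chi)
  data.frame(gene_id = trace$meta$gene_ids, chi_inverse = score,
             rank = as.integer(rank(-score, ties.method = "first")),
             stringsAsFactors = FALSE)
}

# All permutations of 1..n (n small), as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  j <- 0L
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      j <- j + 1L
      rest <- seq_len(n)[-i]
      out[[j]] <- c(i, rest[p])
    }
  }
  out
}

#' Match mixture-component labels between two labelings
#'
#' Mixture-component indices are non-identifiable, so agreement between a
#' ground-truth and an inferred labeling is measured after permuting the
#' inferred labels to maximize it. The optimum is found exhaustively over
#' the permutations of the B x B confusion matrix (supported for B <= 8;
#' cost is B!·B on the table, independent of N).
#'
#' @param true_labels,inferred_labels Integer vectors of equal length with
#'   entries in `1..B`.
#' @param B Number of components.
#' @return A list: `permutation` (integer vector; inferred label b is
#'   mapped to `permutation[b]`), `accuracy` (agreement in `[0, 1]` after
#'   relabeling), `relabeled` (the permuted inferred labels).
#' @export
match_branch_labels <- function(true_labels, inferred_labels, B) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop_invalid("B must be a positive integer")
  if (B > 8L) stop_invalid("label matching supports B <= 8")
  true_labels <- as.integer(true_labels)
  inferred_labels <- as.integer(inferred_labels)
  if (length(true_labels) != length(inferred_labels))
    stop_invalid("label vectors must have equal length")
  if (anyNA(true_labels) || anyNA(inferred_labels) ||
      any(true_labels < 1L) || any(true_labels > B) ||
      any(inferred_labels < 1L) || any(inferred_labels > B))
    stop_invalid("labels must lie in 1..", B)
  conf <- table(factor(inferred_labels, levels = seq_len(B)),
                factor(true_labels, levels = seq_len(B)))
  best <- NULL; best_agree <- -1L
  for (p in all_permutations(B)) {
    agree <- sum(conf[cbind(seq_len(B), p)])
    if (agree > best_agree) { best_agree <- agree; best <- p }
  }
  list(permutation = best,
       accuracy = best_agree / length(true_labels),
       relabeled = best[inferred_labels])
}

#' Area under the ROC curve of a score against binary flags
#'
#' Rank-statistic (Mann-Whitney) formulation; used to evaluate how well the
#' inverse-chi scores separate truly bifurcating genes.
#'
#' @param score Numeric scores, larger = more positive.
#' @param flag Logical vector of the same length, TRUE = positive class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, flag) {
  flag <- as.logical(flag)
  if (length(score) != length(flag)) stop_invalid("length mismatch")
  n1 <- sum(flag); n0 <- sum(!flag)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("AUROC needs both positive and negative examples")
  r <- rank(score)
  (sum(r[flag]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full posterior summary of a fitted trace
#'
#' @param trace A `bmfa_trace`.
#' @param level Credible-interval level for pseudotimes.
#' @return A list of class `bmfa_summary`: `cells` (data.frame with MAP
#'   pseudotime, credible interval and MAP branch), `genes` (data.frame of
#'   inverse-chi relevance scores and ranks) and `omega_mean` (posterior
#'   mean mixture weights).
#' @export
posterior_summary <- function(trace, level = 0.95) {
  check_trace(trace)
  cells <- map_pseudotime(trace, level = level)
  cells$gamma_map <- as.integer(map_branch(trace))
  structure(list(cells = cells, genes = chi_relevance(trace),
                 omega_mean = colMeans(trace$omega)),
            class = "bmfa_summary")
}
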