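# Model selection (energy ranking, TM clustering) and ensemble quality
# assessment: long-range contact satisfaction (MQA_LR), mean pairwise
# TM-score and the combined score CS, plus fold-correctness classification
# and the fragment-fit outlier rule.

#' Rank decoys by energy
#'
#' Ascending-energy ranking with ties broken by decoy id. `top1` is the
#' lowest-energy model; `top5` the five lowest. In benchmark mode (native
#' supplied) `best_top5_tm` is the highest TM-score to the native among the
#' top-5.
#'
#' @param ensemble An `ensemble`.
#' @param native Optional native `conformation`.
#' @return List of class `selection_report`: `order`, `top1`, `top5`,
#'   `energies` and optionally `best_top5_tm`, `tm_top1`.
#' @export
rank_by_energy <- function(ensemble, native = NULL) {
  n <- n_decoys(ensemble)
  if (n == 0) stop("empty ensemble")
  e <- vapply(ensemble$decoys, `[[`, 0, "energy")
  ord <- order(e, seq_len(n))
  if (n < 5) warning("fewer than 5 decoys; top5 truncated to ", n)
  top5 <- ord[seq_len(min(5, n))]
  out <- list(order = ord, top1 = ord[1], top5 = top5, energies = e)
  if (!is.null(native)) {
    tms <- vapply(top5, function(k)
      tm_score(ensemble$decoys[[k]]$conformation, native), 0)
    out$best_top5_tm <- max(tms)
    out$tm_top1 <- tms[1]
  }
  structure(out, class = "selection_report")
}

#' Pairwise TM-score matrix of an ensemble
#'
#' Symmetric matrix; each pair is scored in both orientations and the larger
#' value kept (equal lengths make the two directions equivalent up to search
#' noise).
#'
#' @param ensemble An `ensemble`.
#' @return `n x n` matrix with unit diagonal.
#' @export
pairwise_tm <- function(ensemble) {
  n <- n_decoys(ensemble)
  cas <- lapply(ensemble$decoys, function(d) ca_coords(d$conformation))
  m <- diag(n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- max(.cpp_tm_score(cas[[i]], cas[[j]],
                                              tm_d0(nrow(cas[[j]]))),
                                .cpp_tm_score(cas[[j]], cas[[i]],
                                              tm_d0(nrow(cas[[i]]))))
    }
  }
  m
}

#' Mean pairwise TM-score of an ensemble
#'
#' Mean of the TM-score over all unordered decoy pairs; a tight ensemble
#' (high structural consensus) scores close to 1.
#'
#' @param ensemble An `ensemble` with at least 2 decoys.
#' @param tm Optional precomputed [pairwise_tm()] matrix.
#' @return Mean TM in (0, 1].
#' @export
mean_pairwise_tm <- function(ensemble, tm = NULL) {
  n <- n_decoys(ensemble)
  if (n < 2) stop("need at least 2 decoys")
  m <- tm %||% pairwise_tm(ensemble)
  mean(m[upper.tri(m)])
}

#' Greedy TM-score clustering of an ensemble
#'
#' Repeatedly takes the decoy with the most neighbours at TM >=
#' `threshold` as a cluster representative and removes it with its
#' neighbours; ties break by decoy id. Clusters are disjoint and cover the
#' ensemble.
#'
#' @param ensemble An `ensemble` with at least 2 decoys.
#' @param threshold TM similarity threshold (default 0.5).
#' @param tm Optional precomputed [pairwise_tm()] matrix.
#' @return List of class `tmclust`: `clusters` (list of
#'   `list(representative, members)`, largest first) and `top5`
#'   (representatives of the 5 largest).
#' @export
tmclust <- function(ensemble, threshold = 0.5, tm = NULL) {
  n <- n_decoys(ensemble)
  if (n < 2) stop("need at least 2 decoys")
  m <- tm %||% pairwise_tm(ensemble)
  left <- seq_len(n)
  clusters <- list()
  while (length(left)) {
    nb <- vapply(left, function(i) sum(m[i, left] >= threshold), 0)
    rep_i <- left[order(-nb, left)[1]]
    members <- left[m[rep_i, left] >= threshold]
    members <- sort(unique(c(rep_i, members)))
    clusters[[length(clusters) + 1L]] <-
      list(representative = rep_i, members = members)
    left <- setdiff(left, members)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 0)
  clusters <- clusters[order(-sizes, vapply(clusters, `[[`, 0,
                                            "representative"))]
  structure(list(clusters = clusters,
                 top5 = vapply(head(clusters, 5), `[[`, 0, "representative")),
            class = "tmclust")
}

#' Long-range contact quality score MQA_LR
#'
#' Counts the top-L predicted contacts with sequence separation > 23
#' (`N_LR`), measures the fraction of them satisfied in the model at CB-CB
#' distance <= `d_con` (`CON_LR`), and combines them as
#' `MQA_LR = CON_LR * ln(1 + N_LR)`, so the score grows both with the
#' satisfied fraction and with the amount of long-range information.
#'
#' @param model A `conformation`.
#' @param contacts A `contact_list` with known `L`.
#' @param d_con Contact distance bound (default 8 A).
#' @return List: `n_lr`, `con_lr`, `score`.
#' @export
mqa_lr <- function(model, contacts, d_con = 8) {
  tl <- top_l(contacts)$records
  lr <- tl[tl$j - tl$i > 23, , drop = FALSE]
  n_lr <- nrow(lr)
  if (n_lr == 0) {
    warning("no long-range contacts in the top-L list; MQA_LR = 0")
    return(list(n_lr = 0L, con_lr = NA_real_, score = 0))
  }
  cb <- contact_coords(model)
  d <- sqrt(rowSums((cb[lr$i, , drop = FALSE] - cb[lr$j, , drop = FALSE])^2))
  con_lr <- mean(d <= d_con)
  list(n_lr = n_lr, con_lr = con_lr, score = con_lr * log1p(n_lr))
}

#' Combined model quality score CS
#'
#' Linear combination of the ensemble's mean pairwise TM-score and the
#' final model's long-range contact score: `CS = w_tm * TM + w_lr * MQA_LR`
#' with default weights 7 and 1.
#'
#' @param mean_tm Mean pairwise ensemble TM-score.
#' @param mqa MQA_LR score of the assessed (lowest-energy) model.
#' @param w_tm,w_lr Weights (defaults 7 and 1).
#' @return CS value.
#' @export
combined_score <- function(mean_tm, mqa, w_tm = 7, w_lr = 1) {
  w_tm * mean_tm + w_lr * mqa
}

#' Classify fold correctness from CS
#'
#' A model is predicted correct (expected TM-score at or above the paired
#' TM threshold) when its CS exceeds the given threshold. Default threshold
#' 3.4 corresponds to the TM >= 0.5 correctness claim; 3.0 and 6.0 pair with
#' TM >= 0.4 and 0.7.
#'
#' @param cs CS value(s).
#' @param threshold CS threshold (default 3.4).
#' @return Logical vector.
#' @export
classify_fold <- function(cs, threshold = 3.4) {
  cs > threshold
}

#' Precision and recall of fold-correctness predictions
#'
#' @param predictions Logical vector of predicted-correct calls.
#' @param truths Logical vector of actual correctness labels.
#' @return List: `precision`, `recall`, `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_classification <- function(predictions, truths) {
  if (!length(predictions) || length(predictions) != length(truths))
    stop("need equal-length non-empty prediction and truth vectors")
  tp <- sum(predictions & truths)
  fp <- sum(predictions & !truths)
  fn <- sum(!predictions & truths)
  tn <- sum(!predictions & !truths)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Upper-fence outliers by the 1.5 IQR rule
#'
#' Values at or above `Q3 + 1.5 * IQR` (quartiles by linear interpolation,
#' type 7). A constant list has no outliers.
#'
#' @param values Numeric vector of at least 4 values.
#' @return Indices of outlying values.
#' @export
iqr_outliers <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(integer(0))
  which(values >= q[2] + 1.5 * iqr)
}

#' Assess an ensemble
#'
#' Computes the full QA report: energy ranking, mean pairwise TM-score,
#' MQA_LR of the lowest-energy model, CS and the fold-correctness call;
#' in benchmark mode (native given) also TM-scores to the native.
#'
#' @param ensemble An `ensemble`.
#' @param contacts A `contact_list` (for MQA_LR).
#' @param native Optional native `conformation`.
#' @param cs_threshold CS correctness threshold (default 3.4).
#' @return List of class `qa_report`: `per_decoy` data frame (decoy_id,
#'   energy, rank, mode and optionally tm_native), and ensemble-level
#'   `n_lr`, `con_lr`, `mqa_lr`, `mean_pairwise_tm`, `cs`,
#'   `predicted_correct`, `selection`.
#' @export
assess_ensemble <- function(ensemble, contacts, native = NULL,
                            cs_threshold = 3.4) {
  sel <- rank_by_energy(ensemble, native)
  tmm <- if (n_decoys(ensemble) >= 2) pairwise_tm(ensemble) else NULL
  mtm <- if (!is.null(tmm)) mean_pairwise_tm(ensemble, tmm) else NA_real_
  final <- ensemble$decoys[[sel$top1]]$conformation
  mq <- suppressWarnings(mqa_lr(final, contacts))
  cs <- combined_score(mtm, mq$score)
  per <- data.frame(
    decoy_id = seq_len(n_decoys(ensemble)),
    energy = sel$energies,
    rank = match(seq_len(n_decoys(ensemble)), sel$order),
    mode = vapply(ensemble$decoys, function(d) d$mode %||% NA_character_, ""))
  if (!is.null(native))
    per$tm_native <- vapply(ensemble$decoys, function(d)
      tm_score(d$conformation, native), 0)
  structure(list(per_decoy = per, n_lr = mq$n_lr, con_lr = mq$con_lr,
                 mqa_lr = mq$score, mean_pairwise_tm = mtm, cs = cs,
                 predicted_correct = classify_fold(cs, cs_threshold),
                 selection = sel, tm_matrix = tmm),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> mean pairwise TM =", sprintf("%.3f", x$mean_pairwise_tm),
      "| MQA_LR =", sprintf("%.3f", x$mqa_lr),
      "| CS =", sprintf("%.3f", x$cs),
      "| predicted", if (x$predicted_correct) "CORRECT" else "incorrect",
      "\n")
  invisible(x)
}

#' Write a QA report as TSV
#' @param report A `qa_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  per <- report$per_decoy
  per$n_lr <- report$n_lr
  per$con_lr <- report$con_lr
  per$mqa_lr <- report$mqa_lr
  per$mean_pairwise_tm <- report$mean_pairwise_tm
  per$cs <- report$cs
  per$predicted_correct <- report$predicted_correct
  write.table(per, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
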