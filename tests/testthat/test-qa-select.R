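# Model selection, clustering and quality assessment.

mini_ensemble <- function(energies) {
  toy <- fx_toy()
  ens <- make_decoy_set(toy$native, n_near = length(energies), n_far = 0,
                        seed = 1)
  for (k in seq_along(energies)) ens$decoys[[k]]$energy <- energies[k]
  ens
}

test_that("energy ranking orders decoys and reports best top-5 TM", {
  ens <- mini_ensemble(c(5, 3, 9, 1, 2))
  sel <- rank_by_energy(ens)
  expect_equal(sel$top1, 4)
  expect_equal(sel$order[1:3], c(4, 5, 2))
  expect_length(sel$top5, 5)
  expect_true(sel$top1 %in% sel$top5)

  expect_warning(sel3 <- rank_by_energy(mini_ensemble(c(3, 1, 2))), "fewer")
  expect_length(sel3$top5, 3)
  expect_error(rank_by_energy(new_ensemble(list())), "empty")

  # benchmark mode: best_top5_tm equals the max over an explicit loop
  toy <- fx_toy()
  ens2 <- make_decoy_set(toy$native, 3, 3, seed = 7, em = fx_em(),
                         contacts = fx_true_contacts(), ss_pred = toy$ss)
  sel2 <- rank_by_energy(ens2, native = toy$native)
  want <- max(vapply(sel2$top5, function(k)
    tm_score(ens2$decoys[[k]]$conformation, toy$native), 0))
  expect_equal(sel2$best_top5_tm, want, tolerance = 1e-9)
})

test_that("tmclust partitions the ensemble with the declared greedy rule", {
  # two internally tight, mutually distant groups: near-native decoys of
  # two different folds of the same length
  toy <- fx_toy()
  other <- make_toy("mixed", 60, seed = 9)
  expect_lt(tm_score(other$native, toy$native), 0.45)
  ens <- make_decoy_set(toy$native, n_near = 4, n_far = 0, seed = 9,
                        near_sigma = 4)
  grp2 <- make_decoy_set(other$native, n_near = 4, n_far = 0, seed = 10,
                         near_sigma = 4)
  ens$decoys <- c(ens$decoys, grp2$decoys)
  cl <- tmclust(ens, threshold = 0.5)
  expect_length(cl$clusters, 2)
  sizes <- vapply(cl$clusters, function(x) length(x$members), 0)
  expect_equal(sort(sizes), c(4, 4))
  expect_setequal(unlist(lapply(cl$clusters, `[[`, "members")), 1:8)
  members1 <- cl$clusters[[1]]$members
  expect_true(all(members1 %in% 1:4) || all(members1 %in% 5:8))

  # identical decoys collapse into one cluster
  same <- new_ensemble(rep(list(ens$decoys[[1]]), 4))
  cl_same <- tmclust(same, threshold = 0.5)
  expect_length(cl_same$clusters, 1)
  # impossible threshold: all-singleton clusters
  cl_tight <- tmclust(ens, threshold = 1.0000001)
  expect_true(all(vapply(cl_tight$clusters,
                         function(x) length(x$members), 0) == 1))
})

test_that("mean pairwise TM equals the explicit pair-loop mean", {
  toy <- fx_toy()
  ens <- make_decoy_set(toy$native, 3, 3, seed = 5)
  m <- pairwise_tm(ens)
  expect_equal(m, t(m))
  vals <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    a <- ca_coords(ens$decoys[[i]]$conformation)
    b <- ca_coords(ens$decoys[[j]]$conformation)
    vals <- c(vals, max(tm_score(a, b), tm_score(b, a)))
  }
  expect_equal(mean_pairwise_tm(ens, m), mean(vals), tolerance = 1e-9)
  expect_gt(mean_pairwise_tm(ens, m), 0)
  expect_lte(mean_pairwise_tm(ens, m), 1)
  one <- new_ensemble(ens$decoys[1])
  expect_error(mean_pairwise_tm(one), "at least 2")
  same <- new_ensemble(rep(list(ens$decoys[[1]]), 3))
  expect_equal(mean_pairwise_tm(same), 1, tolerance = 1e-9)
})

test_that("MQA_LR counts top-L long-range contacts and scales with CON_LR", {
  toy <- fx_toy()
  truec <- fx_true_contacts()
  mq <- mqa_lr(toy$native, truec)
  lr <- top_l(truec)$records
  lr <- lr[lr$j - lr$i > 23, ]
  expect_equal(mq$n_lr, nrow(lr))
  expect_equal(mq$con_lr, 1.0)      # native satisfies its own contacts
  expect_equal(mq$score, log1p(nrow(lr)))

  # CON_LR = 0 gives 0; halving CON_LR halves the score
  ext <- build_chain(toy$record$sequence, cbind(rep(-139, 60), rep(135, 60)))
  mq0 <- mqa_lr(ext, truec)
  expect_equal(mq0$score, 0)
  # linearity: score / con_lr is the same constant for any model
  near <- make_decoy_set(toy$native, 2, 0, seed = 11)$decoys
  for (d in near) {
    m <- mqa_lr(d$conformation, truec)
    if (m$n_lr > 0 && !is.na(m$con_lr) && m$con_lr > 0)
      expect_equal(m$score / m$con_lr, log1p(m$n_lr), tolerance = 1e-12)
  }
  # no long-range information -> 0 with warning
  short_only <- contact_list(data.frame(i = 1:5, j = 1:5 + 6, ppv = 0.9),
                             L = 60)
  expect_warning(mq_na <- mqa_lr(toy$native, short_only), "long-range")
  expect_equal(mq_na$score, 0)
})

test_that("combined score is the stated linear form with weights 7 and 1", {
  expect_equal(combined_score(0.3, 2.0), 4.1)
  expect_equal(combined_score(0, 0), 0)
  expect_equal(combined_score(0.5, 1.2, w_tm = 2, w_lr = 3), 4.6)
  set.seed(1)
  a <- runif(20); b <- runif(20, 0, 4)
  expect_true(all(diff(combined_score(sort(a), 1)) >= 0))
  expect_true(all(diff(combined_score(0.4, sort(b))) >= 0))
})

test_that("fold classification and precision/recall match the confusion matrix", {
  expect_true(classify_fold(3.5))
  expect_false(classify_fold(3.4))
  pred <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  truth <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  ev <- evaluate_classification(pred, truth)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  ev1 <- evaluate_classification(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(ev1$precision, 1)
  expect_equal(ev1$recall, 1)
  ev0 <- evaluate_classification(c(FALSE, FALSE), c(TRUE, FALSE))
  expect_equal(ev0$recall, 0)
  expect_error(evaluate_classification(logical(0), logical(0)), "non-empty")
})

test_that("IQR outlier rule uses type-7 quartiles with the upper fence", {
  expect_equal(iqr_outliers(c(1, 2, 3, 4, 100)), 5L)
  expect_equal(iqr_outliers(rep(3, 6)), integer(0))
  expect_equal(iqr_outliers(1:10), integer(0))  # fence 13.375
  expect_error(iqr_outliers(c(1, 2, 3)), "at least 4")
  # boundary: a value exactly on the fence is an outlier ("1.5 times or
  # more"); for c(1, 1, 3, 3, 6): Q1 = 1, Q3 = 3, fence = 3 + 1.5*2 = 6
  expect_equal(iqr_outliers(c(1, 1, 3, 3, 6)), 5L)
})

test_that("assess_ensemble separates near-native from shuffled decoy pools", {
  toy <- fx_toy()
  pred <- simulate_predictions(toy$native, 30, 0.9, seed = 21)
  good <- make_decoy_set(toy$native, 8, 2, seed = 2, em = fx_em(),
                         contacts = pred, ss_pred = toy$ss)
  bad <- make_decoy_set(toy$native, 0, 10, seed = 3, em = fx_em(),
                        contacts = pred, ss_pred = toy$ss)
  qa_good <- assess_ensemble(good, pred, native = toy$native)
  qa_bad <- assess_ensemble(bad, pred, native = toy$native)
  expect_gt(qa_good$cs, qa_bad$cs)
  expect_true(qa_good$predicted_correct)
  expect_false(qa_bad$predicted_correct)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_qa_report(qa_good, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_true(all(c("decoy_id", "energy", "rank", "con_lr", "mqa_lr",
                    "mean_pairwise_tm", "cs", "predicted_correct")
                  %in% names(df)))
  expect_equal(nrow(df), 10)
})
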