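# Contact pseudo-energy, schedules, contact order, satisfaction statistics.

test_that("rrcon_energy matches its defining values and laws", {
  expect_equal(rrcon_energy(0.8, 5.0), -0.80)
  expect_equal(rrcon_energy(0.6, 8 + 4 * log(2)), 0.0, tolerance = 1e-12)
  expect_equal(rrcon_energy(0.5, 1e6), 0.5, tolerance = 1e-9)
  expect_error(rrcon_energy(0, 5), "positive")

  # continuity, flat well, monotonicity, linear scaling in P
  set.seed(21)
  for (k in 1:200) {
    p <- runif(1, 0.01, 1)
    d <- runif(1, 0, 30)
    expect_equal(rrcon_energy(2 * p / 2, d), rrcon_energy(p, d))
    expect_equal(rrcon_energy(p, d), p * rrcon_energy(1, d),
                 tolerance = 1e-12)
  }
  d_in <- runif(50, 0, 8)
  expect_true(all(rrcon_energy(0.7, d_in) == -0.7))
  d_out <- sort(runif(50, 8, 40))
  v <- rrcon_energy(0.7, d_out)
  expect_true(all(diff(v) > 0))
  # continuity at the well edge
  expect_equal(rrcon_energy(0.9, 8), rrcon_energy(0.9, 8 + 1e-9),
               tolerance = 1e-6)
})

test_that("rrcon_total equals the naive double-loop oracle and respects the schedule", {
  toy <- make_toy("three_helix_bundle", 56, seed = 6)
  conf <- toy$native
  pred <- simulate_predictions(conf, 30, 0.7, seed = 7)
  cb <- contact_coords(conf)
  oracle <- function(max_sep = Inf) {
    s <- 0
    for (r in seq_len(nrow(pred$records))) {
      i <- pred$records$i[r]; j <- pred$records$j[r]
      if (j - i > max_sep) next
      d <- sqrt(sum((cb[i, ] - cb[j, ])^2))
      p <- pred$records$ppv[r]
      s <- s + if (d <= 8) -p else p * (1 - 2 * exp(-(d - 8) / 4))
    }
    s
  }
  expect_equal(rrcon_total(conf, pred), oracle(), tolerance = 1e-9)
  expect_equal(rrcon_total(conf, pred, max_sep = 15), oracle(15),
               tolerance = 1e-9)
  empty <- contact_list(data.frame(i = integer(), j = integer(),
                                   ppv = numeric()), L = n_res(conf))
  expect_equal(rrcon_total(conf, empty), 0)
  bad <- contact_list(data.frame(i = 1, j = 999, ppv = 0.5), L = 999)
  expect_error(rrcon_total(conf, bad), "out of range")
})

test_that("all satisfied contacts at unit ppv give minus the ppv sum", {
  toy <- fx_toy()
  truec <- fx_true_contacts()
  expect_equal(rrcon_total(toy$native, truec),
               -sum(truec$records$ppv), tolerance = 1e-9)
})

test_that("sequential schedule is linear, nested and anchored at the range classes", {
  expect_equal(schedule_max_separation(0, 10, 100), 9)
  expect_equal(schedule_max_separation(10, 10, 100), 99)
  expect_equal(schedule_max_separation(5, 10, 109), 59)  # round-half-up of 58.5
  expect_equal(schedule_max_separation(3, 0, 100), 99)   # T = 0: all active
  for (L in c(40, 80, 120)) {
    T <- 25
    seps <- vapply(0:T, schedule_max_separation, 0, T = T, L = L)
    expect_true(all(diff(seps) >= 0))
    expect_equal(seps[1], 9)
    expect_equal(seps[T + 1], L - 1)
  }
})

test_that("contact range classes partition separations at 9/10 and 23/24", {
  r <- contact_range(c(5, 9, 10, 23, 24, 50))
  expect_equal(as.character(r),
               c("short", "short", "mid", "mid", "long", "long"))
  expect_error(contact_range(4), "below 5")
})

test_that("contact order matches hand computations", {
  cl <- contact_list(data.frame(i = c(1, 2), j = c(10, 20),
                                ppv = c(0.9, 0.8)), L = 20)
  expect_equal(contact_order(cl), 67.5)
  single <- contact_list(data.frame(i = 7, j = 12, ppv = 1), L = 100)
  expect_equal(contact_order(single), 5.0)
  # all contacts at identical separation s -> exactly 100 s / L
  same <- contact_list(data.frame(i = 1:10, j = 1:10 + 8,
                                  ppv = seq(1, 0.1, length.out = 10)),
                       L = 40)
  expect_equal(contact_order(same), 100 * 8 / 40)
  empty <- contact_list(data.frame(i = integer(), j = integer(),
                                   ppv = numeric()), L = 10)
  expect_error(contact_order(empty), "no contacts")
})

test_that("top_l truncates deterministically with lexicographic tie-break", {
  df <- data.frame(i = c(5, 1, 3), j = c(20, 16, 18), ppv = c(0.5, 0.5, 0.5))
  cl <- contact_list(df, L = 2)
  tl <- top_l(cl)$records
  expect_equal(nrow(tl), 2)
  expect_equal(tl$i, c(1, 3))  # equal ppv: ordered by (i, j)
})

test_that("satisfaction statistics match a brute-force loop oracle", {
  toy <- make_toy("mixed", 40, seed = 3)
  native <- toy$native
  pred <- simulate_predictions(native, 20, 0.6, seed = 3)
  model <- make_decoy_set(native, 1, 0, seed = 5)$decoys[[1]]$conformation
  st <- satisfaction_stats(model, pred, native = native, k = Inf)
  cb <- contact_coords(model); nb <- contact_coords(native)
  df <- pred$records
  d <- sqrt(rowSums((cb[df$i, ] - cb[df$j, ])^2))
  nd <- sqrt(rowSums((nb[df$i, ] - nb[df$j, ])^2))
  sat <- d <= 8; tr <- nd <= 8
  rng <- cut(df$j - df$i, c(4, 9, 23, Inf), labels = c("short", "mid", "long"))
  for (cl in c("short", "mid", "long")) {
    idx <- rng == cl
    row <- st[st$range == cl, ]
    expect_equal(row$n_predicted, sum(idx))
    expect_equal(row$n_satisfied, sum(sat[idx]))
    expect_equal(row$n_true, sum(tr[idx]))
    expect_equal(row$n_false_satisfied, sum(sat[idx] & !tr[idx]))
  }
  ov <- st[st$range == "overall", ]
  expect_equal(ov$fraction, mean(sat))

  # model = native with all-true predictions: satisfied fraction 1 everywhere
  truec <- native_contacts(native)
  st2 <- satisfaction_stats(native, truec, native = native, k = Inf)
  expect_true(all(st2$fraction[st2$n_predicted > 0] == 1))

  # hand-constructed: one satisfied + one unsatisfied long-range contact
  ext <- build_chain(strrep("A", 40), cbind(rep(-139, 40), rep(135, 40)))
  hp <- make_toy("helix_hairpin", 40, seed = 2)$native
  lr <- native_contacts(hp)$records
  lr <- lr[lr$j - lr$i > 23, ][1, ]
  two <- contact_list(rbind(lr, data.frame(i = 1, j = 40, ppv = 1)), L = 40)
  two$records$ppv <- c(1, 1)
  sat_hp <- satisfaction_stats(hp, two, k = Inf)
  # in the hairpin native, the native long-range pair is satisfied; termini
  # (1, 40) are on the same side, check directly which is satisfied
  cbh <- contact_coords(hp)
  manual <- sqrt(rowSums((cbh[two$records$i, ] - cbh[two$records$j, ])^2)) <= 8
  expect_equal(sat_hp[sat_hp$range == "long", "fraction"], mean(manual))
})
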