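# Statistical potential training, term evaluation, weight calibration.

test_that("inverse Boltzmann pair table follows its defining ratios", {
  pt <- fx_pair_table()
  # symmetry in residue classes
  for (sc in c("sr", "lr")) {
    for (a in 1:7) for (b in 1:7) {
      expect_equal(pt[[sc]][a, b, ], pt[[sc]][b, a, ])
    }
  }
  # observed == expected -> zero energy; ratio e -> -1 kT; doubling
  # invariance (exact at zero pseudocount)
  k0 <- energy_defaults(); k0$pseudocount <- 0
  one <- build_chain(strrep("A", 30), cbind(rep(-57, 30), rep(-47, 30)))
  t1 <- train_pair_potential(list(one), constants = k0)
  # duplicating the reference set doubles every count but not the table
  t2 <- train_pair_potential(list(one, one), constants = k0)
  finite <- is.finite(t1$sr) & is.finite(t2$sr)
  expect_equal(t1$sr[finite], t2$sr[finite], tolerance = 1e-12)
  expect_error(train_pair_potential(list()), "empty")

  # direct ratio check on one populated cell of the fixture table
  cnt_check <- local({
    confs <- fx_train()
    k <- energy_defaults()
    nbin <- k$pair_dmax / k$pair_bw
    cnt <- array(0, c(7, 7, nbin))
    for (conf in confs) {
      cb <- contact_coords(conf); cls <- aa_class(conf$aa)
      L <- n_res(conf)
      for (i in 1:(L - 5)) for (j in (i + 5):L) {
        if (j - i > 10) next
        d <- sqrt(sum((cb[i, ] - cb[j, ])^2))
        if (d >= 15) next
        bin <- min(nbin, floor(d / 0.5) + 1)
        cnt[cls[i], cls[j], bin] <- cnt[cls[i], cls[j], bin] + 1
        if (cls[i] != cls[j])
          cnt[cls[j], cls[i], bin] <- cnt[cls[j], cls[i], bin] + 1
      }
    }
    cnt
  })
  marg <- apply(cnt_check, 3, sum)
  p_bin <- marg / sum(marg)
  a <- 1; b <- 3
  expected <- sum(cnt_check[a, b, ]) * p_bin
  want <- -log((cnt_check[a, b, ] + 1) / (expected + 1))
  expect_equal(pt$sr[a, b, ], want, tolerance = 1e-9)
})

test_that("energy terms match independent double-loop oracles on a toy", {
  toy <- make_toy("mixed", 42, seed = 9)
  conf <- toy$native
  em <- energy_model(fx_pair_table(), fx_solv_table())
  pred <- simulate_predictions(conf, 21, 0.7, seed = 9)
  terms <- evaluate_terms(conf, em, pred, toy$ss)
  k <- energy_defaults()
  cb <- contact_coords(conf); cls <- aa_class(conf$aa); L <- n_res(conf)

  sr <- lr <- 0
  for (i in 1:(L - 5)) for (j in (i + 5):L) {
    d <- sqrt(sum((cb[i, ] - cb[j, ])^2))
    if (d >= k$pair_dmax) next
    bin <- min(30, floor(d / k$pair_bw) + 1)
    if (j - i <= 10) sr <- sr + em$pair$sr[cls[i], cls[j], bin]
    else lr <- lr + em$pair$lr[cls[i], cls[j], bin]
  }
  expect_equal(unname(terms["SR"]), sr, tolerance = 1e-9)
  expect_equal(unname(terms["LR"]), lr, tolerance = 1e-9)

  solv <- 0
  for (i in 1:L) {
    bur <- sum(sqrt(rowSums((cb[-i, , drop = FALSE] -
                             matrix(cb[i, ], L - 1, 3,
                                    byrow = TRUE))^2)) <= k$solv_r)
    solv <- solv + em$solv[cls[i], min(bur, k$max_burial) + 1]
  }
  expect_equal(unname(terms["SOLV"]), solv, tolerance = 1e-9)

  st <- ss_from_torsions(conf)
  hb <- -sum(toy$ss$states %in% c("H", "E") & st == toy$ss$states)
  expect_equal(unname(terms["HB"]), hb)

  rg <- radius_of_gyration(conf)
  expect_equal(unname(terms["COMPACT"]), (rg - 2.2 * L^0.38)^2,
               tolerance = 1e-9)

  steric <- 0
  radii <- unname(k$radii)
  for (i in 1:(L - 2)) for (j in (i + 2):L) {
    ai <- if (conf$aa[i] == "G") 1:4 else 1:5
    aj <- if (conf$aa[j] == "G") 1:4 else 1:5
    for (a in ai) for (b in aj) {
      d <- sqrt(sum((conf$xyz[i, a, ] - conf$xyz[j, b, ])^2))
      rc <- radii[a] + radii[b]
      if (d < rc) steric <- steric + (rc - d)^2
    }
  }
  expect_equal(unname(terms["STERIC"]), steric, tolerance = 1e-9)

  expect_equal(unname(terms["RR"]), rrcon_total(conf, pred),
               tolerance = 1e-9)
})

test_that("steric term sees forced clashes and extended chains are clash-free", {
  ext <- build_chain(strrep("A", 30), cbind(rep(-139, 30), rep(135, 30)))
  em <- energy_model(fx_pair_table(), fx_solv_table())
  t_ext <- evaluate_terms(ext, em)
  expect_lt(t_ext["STERIC"], 1e-6)
  expect_gt(t_ext["COMPACT"], 100)   # far beyond the globular Rg target
  # force two CB atoms very close via a tight turn-back
  coil <- build_chain(strrep("A", 8),
                      cbind(c(-139, -139, -139, 60, 60, -139, -139, -139),
                            c(135, 135, 135, -140, -60, 135, 135, 135)))
  cbd <- as.matrix(dist(contact_coords(coil)))
  if (any(cbd[abs(row(cbd) - col(cbd)) >= 2] < 3.2)) {
    expect_gt(evaluate_terms(coil, em)["STERIC"], 0)
  }
})

test_that("calibrated weights equalize weighted spreads against the SR term", {
  em <- fx_em()
  expect_equal(unname(em$weights["SR"]), 1.0)
  sds <- em$calibration_sds
  for (k in ENERGY_TERMS) {
    expect_equal(unname(em$weights[k]),
                 unname(em$factors[k] * sds["SR"] / sds[k]),
                 tolerance = 1e-12)
  }
  # a term with twice the SR spread and factor 1 gets weight 0.5, by the
  # same rule applied to synthetic spreads
  expect_equal(1 * sds[["SR"]] / (2 * sds[["SR"]]), 0.5)
  expect_error(calibrate_weights(em, "AAAA", n_random = 10), "at least 50")
})

test_that("total energy is the weighted term sum and catches uncalibrated models", {
  toy <- fx_toy()
  em <- fx_em()
  pred <- fx_true_contacts()
  e <- total_energy(toy$native, em, pred, toy$ss)
  expect_equal(e, sum(em$weights * evaluate_terms(toy$native, em, pred,
                                                  toy$ss)),
               tolerance = 1e-12)
  raw <- energy_model(fx_pair_table(), fx_solv_table())
  expect_error(total_energy(toy$native, raw, pred, toy$ss), "calibrated")
  # contacts-only weighting: total reduces to W_RR * rrcon_total
  em2 <- em
  em2$weights[setdiff(ENERGY_TERMS, "RR")] <- 0
  expect_equal(total_energy(toy$native, em2, pred, toy$ss),
               em$weights[["RR"]] * rrcon_total(toy$native, pred),
               tolerance = 1e-9)
})

test_that("pair table serializes to TSV with the declared columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(fx_pair_table(), f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(df), c("type_a", "type_b", "sep_class", "bin_low",
                            "bin_high", "energy"))
  expect_equal(nrow(df), 2 * 7 * 7 * 30)
})
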