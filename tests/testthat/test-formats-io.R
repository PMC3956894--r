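# File-format readers/writers and MSA preprocessing.

test_that("read_contacts parses CASP RR, filters separations and sorts by ppv", {
  f <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "TARGET toy",
               "3 40 0 8 0.9", "5 10 0 8 0.2", "10 12 0 8 0.7"), f)
  cl <- read_contacts(f, L = 50)
  expect_equal(nrow(cl$records), 2)             # (10,12) dropped: sep 2 < 5
  expect_equal(unlist(cl$records[1, c("i", "j")]), c(i = 3, j = 40))
  expect_equal(cl$records$ppv, c(0.9, 0.2))
  # boundary of the separation rule: sep 4 dropped, sep 5 kept
  writeLines(c("5 9 0 8 0.5", "5 10 0 8 0.5"), f)
  kept <- read_contacts(f)
  expect_equal(nrow(kept$records), 1)
  expect_equal(kept$records$j, 10)

  # bare two/three-column dialects
  writeLines(c("2 30", "4 44 0.5"), f)
  cl2 <- read_contacts(f)
  expect_equal(cl2$records$ppv, c(1.0, 0.5))

  # strict ppv > min_ppv: zero-probability records are excluded
  writeLines(c("3 40 0 8 0.0", "5 20 0 8 0.4"), f)
  cl3 <- read_contacts(f)
  expect_equal(nrow(cl3$records), 1)
  expect_equal(cl3$records$i, 5)

  # duplicates keep the highest ppv; i > j normalized
  writeLines(c("40 3 0 8 0.3", "3 40 0 8 0.8"), f)
  cl4 <- read_contacts(f)
  expect_equal(nrow(cl4$records), 1)
  expect_equal(cl4$records$ppv, 0.8)

  writeLines(c("3 40 0 8 0.9", "oops not numbers"), f)
  expect_error(read_contacts(f), "line 2")
})

test_that("contact list ordering is invariant to input line order and round-trips", {
  set.seed(2)
  df <- data.frame(i = sample(1:30, 20), j = 0, ppv = runif(20, 0.01, 1))
  df$j <- df$i + sample(5:20, 20, replace = TRUE)
  f <- withr::local_tempfile(fileext = ".rr")
  writeLines(sprintf("%d %d 0 8 %.6f", df$i, df$j, df$ppv), f)
  a <- read_contacts(f, L = 60)
  perm <- sample(nrow(df))
  writeLines(sprintf("%d %d 0 8 %.6f", df$i[perm], df$j[perm], df$ppv[perm]),
             f)
  b <- read_contacts(f, L = 60)
  expect_equal(a$records, b$records)
  # write -> read round-trip preserves records to 1e-6
  f2 <- withr::local_tempfile(fileext = ".rr")
  write_contacts(a, f2)
  c2 <- read_contacts(f2, L = 60)
  expect_equal(c2$records$ppv, a$records$ppv, tolerance = 1e-6)
  expect_equal(c2$records[, 1:2], a$records[, 1:2])
})

test_that("read_ss2 parses states, validates length, renormalizes triplets", {
  f <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", "",
               "   1 M C   0.9  0.0  0.1",
               "   2 A H   0.1  0.8  0.1",
               "   3 L H   0.0  0.9  0.1"), f)
  ss <- read_ss2(f, sequence = "MAL")
  expect_equal(ss$states, c("C", "H", "H"))
  expect_equal(unname(ss$conf[2, "H"]), 0.8)
  expect_error(read_ss2(f, sequence = "MALN"), "does not match")

  writeLines(character(0), f)
  expect_error(read_ss2(f), "empty")

  writeLines("   1 M C   0.3  0.1  0.1", f)
  expect_warning(ss2 <- read_ss2(f), "renormalized")
  expect_equal(sum(ss2$conf), 1, tolerance = 1e-9)

  # write -> read round-trip
  toy <- fx_toy()
  f3 <- withr::local_tempfile(fileext = ".ss2")
  write_ss2(toy$ss, f3)
  back <- read_ss2(f3, sequence = toy$record$sequence)
  expect_equal(back$states, toy$ss$states)
  expect_equal(unname(back$conf), unname(toy$ss$conf), tolerance = 1e-3)
})

test_that("PDB write -> read round-trips coordinates and selects chains", {
  toy <- fx_toy()$native
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy, f)
  back <- read_structure(f)
  expect_equal(back$sequence, toy$sequence)
  expect_lt(max(abs(ca_coords(back) - ca_coords(toy))), 1e-3)
  expect_lt(max(abs(back$xyz - toy$xyz)), 2e-3)
  # torsions derived from coordinates agree with the originals
  expect_lt(max(abs(wrap_angle(back$torsions[-1, 1] - toy$torsions[-1, 1]))),
            0.1)

  # two chains in one file: chain selection
  f2 <- withr::local_tempfile(fileext = ".pdb")
  small <- make_toy("beta_hairpin", 30, seed = 3)$native
  write_structure(toy, f2, chain = "A")
  write_structure(small, f2, chain = "B", append = TRUE)
  got <- read_structure(f2, chain = "B")
  expect_equal(got$sequence, small$sequence)

  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")))
})

test_that("glycine CB synthesis on read matches ideal geometry", {
  g <- build_chain("AGAGA", cbind(rep(-57, 5), rep(-47, 5)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g, f)   # no CB emitted for G residues
  back <- read_structure(f)
  for (i in which(back$aa == "G")) {
    want <- ideal_cb(back$xyz[i, "N", ], back$xyz[i, "CA", ],
                     back$xyz[i, "C", ])
    expect_lt(sqrt(sum((back$xyz[i, "CB", ] - want)^2)), 1e-3)
  }
})

test_that("ensemble multi-MODEL round-trip preserves energies and coordinates", {
  toy <- fx_toy()
  ens <- make_decoy_set(toy$native, n_near = 2, n_far = 1, seed = 4,
                        em = fx_em(), contacts = fx_true_contacts(),
                        ss_pred = toy$ss)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$energy, ens$decoys[[k]]$energy, tolerance = 1e-5)
    expect_lt(max(abs(ca_coords(back[[k]]$conformation) -
                      ca_coords(ens$decoys[[k]]$conformation))), 1e-3)
    expect_equal(back[[k]]$mode, ens$decoys[[k]]$mode)
  }
})

test_that("filter_msa removes duplicates, query-gap columns and distant rows", {
  aln <- rbind(
    query = strsplit("MKL-AVLIT", "")[[1]],
    dup1  = strsplit("MKLFAVLIT", "")[[1]],
    dup2  = strsplit("MKLFAVLIT", "")[[1]],
    far   = strsplit("WWPPGHHEE", "")[[1]],
    near  = strsplit("MKLFAVLIS", "")[[1]])
  out <- filter_msa(aln, min_identity = 0.30)
  expect_equal(ncol(out), 8)                   # query gap column removed
  expect_false(any(out[1, ] %in% c("-", ".")))
  expect_equal(nrow(out), 3)                   # one dup gone, far row gone
  expect_true("near" %in% rownames(out))
  # identity is counted over non-gap query columns: 2/8 = 0.25 removed
  aln2 <- rbind(q = strsplit("AAAAAAAA", "")[[1]],
                r = strsplit("AACCCCCC", "")[[1]])
  expect_equal(nrow(filter_msa(aln2, 0.30)), 1)
  expect_equal(nrow(filter_msa(aln2, 0.25)), 2)
  # fasta round trip into filter
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(list(id = "q", sequence = "MKL-AV"),
                   list(id = "r", sequence = "MKLFAV")), f)
  recs <- read_fasta(f)
  out2 <- filter_msa(recs)
  expect_equal(ncol(out2), 5)
})
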