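# The seven-term objective: knowledge-based pair potentials (short/long
# separation classes), solvation, secondary-structure reward, compactness,
# steric repulsion and the predicted-contact term, with standard-deviation
# based weight calibration.

ENERGY_TERMS <- c("SR", "LR", "SOLV", "HB", "COMPACT", "STERIC", "RR")

#' Default energy-model constants
#'
#' @return Named list of tunable constants: distance binning of the pair
#'   potentials (0-15 A in 0.5 A steps), solvation neighbour radius (10 A),
#'   contact well `d_con` (8 A) and decay length (4 A), radius-of-gyration
#'   target `2.2 L^0.38`, soft-sphere atom radii and the minimum residue
#'   separation entering the steric sum.
#' @export
energy_defaults <- function() {
  list(
    pair_dmax = 15, pair_bw = 0.5,
    solv_r = 10, max_burial = 20,
    d_con = 8, decay = 4,
    rg_coef = 2.2, rg_exp = 0.38,
    radii = c(N = 1.45, CA = 1.6, C = 1.6, O = 1.35, CB = 1.6),
    steric_minsep = 2,
    pseudocount = 1
  )
}

#' Train distance-binned pair potentials by inverse Boltzmann statistics
#'
#' Counts CB-CB distances (CA for glycine) between residues of the reduced
#' 7-class alphabet in two separation classes (SR: `5 <= j-i <= 10`, LR:
#' `j-i > 10`), bins them (default 0-15 A in 0.5 A steps) and converts to
#' energies `E = -ln((observed + pc) / (expected + pc))`, with the expected
#' count taken from the bin frequencies marginalized over residue classes.
#' Tables are symmetrized in the residue classes.
#'
#' @param reference_structures List of `conformation` objects.
#' @param constants Constant list from [energy_defaults()].
#' @return List with `sr` and `lr` arrays (`7 x 7 x nbin`), plus binning
#'   metadata; class `pair_table`.
#' @export
train_pair_potential <- function(reference_structures,
                                 constants = energy_defaults()) {
  if (!length(reference_structures)) stop("empty reference set")
  nbin <- as.integer(constants$pair_dmax / constants$pair_bw)
  counts <- list(sr = array(0, c(7, 7, nbin)), lr = array(0, c(7, 7, nbin)))
  for (conf in reference_structures) {
    cb <- contact_coords(conf)
    cls <- aa_class(conf$aa)
    L <- n_res(conf)
    dm <- as.matrix(dist(cb))
    for (i in seq_len(L - 5)) {
      for (j in (i + 5):L) {
        d <- dm[i, j]
        if (d >= constants$pair_dmax) next
        bin <- min(nbin, floor(d / constants$pair_bw) + 1)
        key <- if (j - i <= 10) "sr" else "lr"
        a <- cls[i]; b <- cls[j]
        counts[[key]][a, b, bin] <- counts[[key]][a, b, bin] + 1
        if (a != b) counts[[key]][b, a, bin] <- counts[[key]][b, a, bin] + 1
      }
    }
  }
  pc <- constants$pseudocount
  tab <- lapply(counts, function(cnt) {
    e <- array(0, dim(cnt))
    marg <- apply(cnt, 3, sum)
    p_bin <- if (sum(marg) > 0) marg / sum(marg) else rep(0, nbin)
    for (a in 1:7) for (b in 1:7) {
      n_ab <- sum(cnt[a, b, ])
      expected <- n_ab * p_bin
      e[a, b, ] <- -log((cnt[a, b, ] + pc) / (expected + pc))
    }
    e
  })
  structure(c(tab, list(dmax = constants$pair_dmax, bw = constants$pair_bw,
                        nbin = nbin)),
            class = "pair_table")
}

#' Train the burial (solvation) potential
#'
#' Counts, per residue class, the number of CB neighbours within the
#' solvation radius (capped at `max_burial`) and converts the burial-count
#' histogram to energies by the same inverse Boltzmann ratio as
#' [train_pair_potential()], with the expected distribution marginalized
#' over classes.
#'
#' @param reference_structures List of `conformation` objects.
#' @param constants Constant list from [energy_defaults()].
#' @return `7 x (max_burial + 1)` matrix; class `solv_table`.
#' @export
train_solv_potential <- function(reference_structures,
                                 constants = energy_defaults()) {
  if (!length(reference_structures)) stop("empty reference set")
  mb <- constants$max_burial
  cnt <- matrix(0, 7, mb + 1)
  for (conf in reference_structures) {
    cb <- contact_coords(conf)
    cls <- aa_class(conf$aa)
    dm <- as.matrix(dist(cb))
    bur <- pmin(rowSums(dm <= constants$solv_r) - 1, mb)
    for (i in seq_along(bur)) cnt[cls[i], bur[i] + 1] <-
        cnt[cls[i], bur[i] + 1] + 1
  }
  pc <- constants$pseudocount
  marg <- colSums(cnt)
  p_b <- if (sum(marg) > 0) marg / sum(marg) else rep(0, mb + 1)
  e <- matrix(0, 7, mb + 1)
  for (a in 1:7) {
    expected <- sum(cnt[a, ]) * p_b
    e[a, ] <- -log((cnt[a, ] + pc) / (expected + pc))
  }
  structure(e, class = "solv_table")
}

#' Construct an energy model
#'
#' Bundles the trained statistical tables, the user weighting factors
#' (1 for every term except STERIC, weighted by an additional factor of 3,
#' and RR by 5) and, after [calibrate_weights()], the per-term weights
#' `W1..W7`.
#'
#' @param pair_table A `pair_table` from [train_pair_potential()].
#' @param solv_table A `solv_table` from [train_solv_potential()].
#' @param factors Named user factors per term.
#' @param constants Constant list from [energy_defaults()].
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(pair_table, solv_table,
                         factors = c(SR = 1, LR = 1, SOLV = 1, HB = 1,
                                     COMPACT = 1, STERIC = 3, RR = 5),
                         constants = energy_defaults()) {
  stopifnot(inherits(pair_table, "pair_table"),
            inherits(solv_table, "solv_table"))
  factors <- factors[ENERGY_TERMS]
  if (anyNA(factors)) stop("factors must name all seven terms")
  structure(list(pair = pair_table, solv = solv_table, factors = factors,
                 constants = constants, weights = NULL),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model>", if (is.null(x$weights)) "(uncalibrated)" else
    paste0("W = [", paste(sprintf("%.3g", x$weights), collapse = ", "), "]"),
    "\n")
  invisible(x)
}

# Pack model parameters for the C++ evaluators.
em_par_list <- function(em) {
  k <- em$constants
  list(pair_sr = as.numeric(em$pair$sr), pair_lr = as.numeric(em$pair$lr),
       pair_dim = c(7L, 7L, em$pair$nbin),
       solv = unclass(em$solv),
       pair_dmax = k$pair_dmax, pair_bw = k$pair_bw, solv_r = k$solv_r,
       d_con = k$d_con, decay = k$decay,
       rg_coef = k$rg_coef, rg_exp = k$rg_exp,
       radii = unname(k$radii), steric_minsep = as.integer(k$steric_minsep))
}

ss_states_int <- function(ss_pred, L) {
  if (is.null(ss_pred)) return(rep(-1L, L))
  states <- if (is.character(ss_pred)) ss_pred else ss_pred$states
  if (length(states) != L) stop("secondary-structure length mismatch")
  match(states, c("C", "H", "E")) - 1L
}

contacts_int <- function(contacts, L) {
  df <- if (is.null(contacts)) data.frame(i = integer(), j = integer(),
                                          ppv = numeric())
        else contacts$records
  if (nrow(df) && (any(df$j > L) || any(df$i < 1)))
    stop("contact index out of range")
  list(idx = cbind(as.integer(df$i) - 1L, as.integer(df$j) - 1L),
       ppv = as.numeric(df$ppv))
}

#' Evaluate the seven raw energy terms of a model
#'
#' Returns the unweighted values of SR, LR (pair potentials in the two
#' separation classes), SOLV (burial), HB (negative count of residues whose
#' backbone torsions realize their predicted H/E state), COMPACT (squared
#' deviation of the CA radius of gyration from `2.2 L^0.38`), STERIC
#' (soft-sphere overlap squared) and RR (contact pseudo-energy, optionally
#' restricted by the sequential schedule).
#'
#' @param model A `conformation`.
#' @param em An `energy_model`.
#' @param contacts A `contact_list` (or NULL for no contacts).
#' @param ss_pred Predicted secondary structure (`ss2_prediction`, character
#'   vector, or NULL to skip the HB reward).
#' @param max_sep Active contact separation bound (NULL = all).
#' @return Named numeric vector of the seven terms.
#' @export
evaluate_terms <- function(model, em, contacts = NULL, ss_pred = NULL,
                           max_sep = NULL) {
  L <- n_res(model)
  flat <- matrix(aperm(model$xyz, c(2, 1, 3)), nrow = 5 * L, ncol = 3)
  co <- contacts_int(contacts, L)
  tor <- model$torsions
  .cpp_eval_terms(flat, aa_class(model$aa) - 1L,
                  as.integer(model$aa == "G"), ss_states_int(ss_pred, L),
                  ifelse(is.na(tor[, 1]), 0, tor[, 1]),
                  ifelse(is.na(tor[, 2]), 0, tor[, 2]),
                  co$idx, co$ppv,
                  if (is.null(max_sep)) -1L else as.integer(max_sep),
                  em_par_list(em))
}

#' Random-torsion conformations for weight calibration
#'
#' Samples torsions from a mixture of the helical and extended basins plus a
#' fraction of uniform angles, mimicking the conformational diversity of
#' fragment-assembled chains.
#'
#' @param sequence Target sequence.
#' @param n Number of conformations.
#' @param seed Integer seed.
#' @return List of `conformation` objects.
#' @export
random_conformations <- function(sequence, n, seed = 1) {
  aa <- seq_to_vec(sequence)
  L <- length(aa)
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    basin <- sample.int(3, L, replace = TRUE, prob = c(0.45, 0.35, 0.2))
    phi <- ifelse(basin == 1, rnorm(L, -63, 15),
                  ifelse(basin == 2, rnorm(L, -120, 20), runif(L, -180, 180)))
    psi <- ifelse(basin == 1, rnorm(L, -42, 15),
                  ifelse(basin == 2, rnorm(L, 135, 20), runif(L, -180, 180)))
    build_chain(aa, cbind(phi, psi, 180))
  })
}

#' Calibrate per-term weights from random-conformation spreads
#'
#' Weights are set so that every weighted term has the same standard
#' deviation, across an ensemble of random conformations of the target, as
#' the short-range pair term, scaled by the user factors (default STERIC x3,
#' RR x5, all others x1): `W_k = factor_k * sd(SR) / sd(term_k)`.
#'
#' @param em An `energy_model`.
#' @param sequence Target sequence.
#' @param contacts A `contact_list` used for the RR spread (or NULL; RR then
#'   calibrates from its factor alone).
#' @param ss_pred Predicted secondary structure for the HB term.
#' @param n_random Ensemble size (default 200, minimum 50).
#' @param seed Integer seed.
#' @return The energy model with `weights` filled in.
#' @export
calibrate_weights <- function(em, sequence, contacts = NULL, ss_pred = NULL,
                              n_random = 200, seed = 1) {
  if (n_random < 50) stop("n_random must be at least 50")
  ens <- random_conformations(sequence, n_random, seed = seed)
  tm <- t(vapply(ens, evaluate_terms, numeric(7), em = em,
                 contacts = contacts, ss_pred = ss_pred))
  sds <- apply(tm, 2, sd)
  names(sds) <- ENERGY_TERMS
  w <- numeric(7)
  names(w) <- ENERGY_TERMS
  for (k in ENERGY_TERMS) {
    if (sds[k] == 0 || !is.finite(sds[k])) {
      warning("term ", k, " has zero spread; weight set from factor only")
      w[k] <- em$factors[k]
    } else {
      w[k] <- em$factors[k] * sds["SR"] / sds[k]
    }
  }
  em$weights <- w
  em$calibration_sds <- sds
  em
}

#' Total weighted energy of a model
#'
#' `sum_k W_k * term_k` over the seven terms; requires a calibrated model.
#'
#' @inheritParams evaluate_terms
#' @return Scalar energy (kT units).
#' @export
total_energy <- function(model, em, contacts = NULL, ss_pred = NULL,
                         max_sep = NULL) {
  if (is.null(em$weights)) stop("energy model is not calibrated")
  sum(em$weights * evaluate_terms(model, em, contacts, ss_pred, max_sep))
}

#' Write trained pair tables as TSV
#' @param pair_table A `pair_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pair_table, path) {
  nbin <- pair_table$nbin
  rows <- do.call(rbind, lapply(c("sr", "lr"), function(sc) {
    do.call(rbind, lapply(1:7, function(a) do.call(rbind, lapply(1:7,
      function(b) data.frame(type_a = a, type_b = b,
                             sep_class = toupper(sc),
                             bin_low = (seq_len(nbin) - 1) * pair_table$bw,
                             bin_high = seq_len(nbin) * pair_table$bw,
                             energy = pair_table[[sc]][a, b, ])))))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
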