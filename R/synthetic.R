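# Synthetic fixture generation: idealized toy proteins, noisy contact
# "predictions" at controlled precision, and labelled decoy sets. Everything
# downstream is testable from these with no external data.

# Loop torsion motifs joining ideal secondary-structure elements. Each was
# selected (once) by seeded search over torsion space for clash-free packing
# of the flanking elements that stays clash-free under the generator's
# sigma = 5 degree loop jitter.
LOOP_HELIX_HAIRPIN <- rbind(c(130.6, -48.1), c(10.3, 52.9), c(-16.3, -5.7),
                            c(-98.6, 47.0))
LOOP_BETA_TURN <- rbind(c(-103.3, -11.3), c(195.0, -181.7), c(-15.8, -98.3),
                        c(34.7, 176.1))
LOOP_BUNDLE2 <- rbind(c(3.8, 163.7), c(-74.4, 124.4), c(136.5, 12.7),
                      c(61.0, -177.0))
LOOP_SHEET_HELIX <- rbind(c(-18.4, 45.8), c(-153.5, -168.7), c(-10.8, -142.3),
                          c(-150.9, -151.1))

HELIX_PHIPSI <- c(-57, -47)
STRAND_PHIPSI <- c(-139, 135)

toy_layout <- function(topology, length) {
  el <- switch(topology,
    helix_hairpin = {
      nh <- (length - 4) %/% 2
      list(c("H", nh), c("L1", 4), c("H", length - 4 - nh))
    },
    beta_hairpin = {
      ns <- (length - 4) %/% 2
      list(c("E", ns), c("L2", 4), c("E", length - 4 - ns))
    },
    three_helix_bundle = {
      nh <- (length - 8) %/% 3
      list(c("H", nh), c("L1", 4), c("H", nh), c("L3", 4),
           c("H", length - 8 - 2 * nh))
    },
    mixed = {
      nh <- round(0.35 * (length - 8))
      ns <- (length - 8 - nh) %/% 2
      list(c("E", ns), c("L2", 4), c("E", length - 8 - nh - ns),
           c("L4", 4), c("H", nh))
    },
    stop("unknown topology: ", topology))
  el
}

loop_torsions <- function(tag) {
  switch(tag, L1 = LOOP_HELIX_HAIRPIN, L2 = LOOP_BETA_TURN,
         L3 = LOOP_BUNDLE2, L4 = LOOP_SHEET_HELIX)
}

AA_HYDROPHOBIC <- c("L", "A", "V", "I", "M", "F")
AA_POLAR <- c("S", "T", "N", "Q")
AA_CHARGED <- c("E", "K", "R", "D")
AA_LOOP <- c("G", "G", "N", "D")

toy_sequence <- function(states) {
  # Hydrophobic-patterned but aperiodic: the buried face of helices (heptad
  # positions a/d) and alternate strand positions draw hydrophobic residues,
  # the rest polar/charged, with the identity of each residue drawn from the
  # seeded RNG so different toys have distinguishable sequences.
  L <- length(states)
  aa <- character(L)
  hpos <- 0; epos <- 0
  for (i in seq_len(L)) {
    if (states[i] == "H") {
      hpos <- hpos + 1
      hept <- (hpos - 1) %% 7
      aa[i] <- if (hept %in% c(0, 3)) sample(AA_HYDROPHOBIC, 1)
               else if (hept %in% c(1, 4)) sample(AA_CHARGED, 1)
               else sample(c(AA_POLAR, "A"), 1)
    } else if (states[i] == "E") {
      epos <- epos + 1
      aa[i] <- if (epos %% 2 == 1) sample(AA_HYDROPHOBIC, 1)
               else sample(AA_POLAR, 1)
    } else aa[i] <- sample(AA_LOOP, 1)
  }
  aa
}

#' Generate an idealized toy protein
#'
#' Builds a clash-free native structure from ideal secondary-structure
#' torsions joined by fixed loop motifs with seeded jitter
#' (sigma = 5 degrees on loop torsions), a hydrophobic-patterned sequence
#' consistent with the topology, and the true secondary-structure states.
#' Loop jitter is resampled (up to `max_attempts`) until the chain is both
#' clash-free and well packed (at least `min_contact_frac * length` native
#' contacts at separation >= 5), so every toy native is a usable folding
#' target.
#'
#' @param topology One of `"helix_hairpin"`, `"three_helix_bundle"`,
#'   `"beta_hairpin"`, `"mixed"`.
#' @param length Chain length, 30-120 residues.
#' @param seed Integer seed.
#' @param max_attempts Loop-resampling attempts before giving up.
#' @param min_contact_frac Minimum native contacts per residue (default
#'   0.5).
#' @return List with `native` (a `conformation` carrying attribute
#'   `ss_true`), `record` (`list(id, sequence)`) and `ss`
#'   (`ss2_prediction` with the true states at confidence 0.85); class
#'   `toy_protein`.
#' @export
make_toy <- function(topology = c("helix_hairpin", "three_helix_bundle",
                                  "beta_hairpin", "mixed"),
                     length = 60, seed = 1, max_attempts = 100,
                     min_contact_frac = 0.5) {
  topology <- match.arg(topology)
  stopifnot(length >= 30, length <= 120)
  layout <- toy_layout(topology, length)
  states <- unlist(lapply(layout, function(e)
    rep(if (startsWith(e[1], "L")) "C" else e[1], as.integer(e[2]))))
  set.seed(seed)
  aa <- toy_sequence(states)
  conf <- NULL
  for (attempt in seq_len(max_attempts)) {
    phi <- numeric(0); psi <- numeric(0)
    for (e in layout) {
      n <- as.integer(e[2])
      if (e[1] == "H") {
        phi <- c(phi, rep(HELIX_PHIPSI[1], n))
        psi <- c(psi, rep(HELIX_PHIPSI[2], n))
      } else if (e[1] == "E") {
        phi <- c(phi, rep(STRAND_PHIPSI[1], n))
        psi <- c(psi, rep(STRAND_PHIPSI[2], n))
      } else {
        lt <- loop_torsions(e[1]) + matrix(rnorm(2 * n, 0, 5), n, 2)
        phi <- c(phi, lt[, 1]); psi <- c(psi, lt[, 2])
      }
    }
    cand <- build_chain(aa, cbind(phi, psi, 180))
    if (has_clash(cand)) next
    if (nrow(native_contacts(cand)$records) >= min_contact_frac * length) {
      conf <- cand
      break
    }
  }
  if (is.null(conf))
    stop("could not generate a clash-free, packed ", topology, " in ",
         max_attempts, " attempts")
  attr(conf, "ss_true") <- states
  ss <- list(states = states,
             conf = make_ss_conf(states, 0.85),
             residues = aa)
  class(ss) <- "ss2_prediction"
  structure(list(
    native = conf,
    record = list(id = sprintf("toy_%s_L%d_s%d", topology, length, seed),
                  sequence = paste(aa, collapse = "")),
    ss = ss, topology = topology, seed = seed), class = "toy_protein")
}

make_ss_conf <- function(states, p_true = 0.85) {
  conf <- matrix((1 - p_true) / 2, length(states), 3,
                 dimnames = list(NULL, c("H", "E", "C")))
  for (i in seq_along(states)) conf[i, states[i]] <- p_true
  conf
}

has_clash <- function(conf, min_dist = 3.3) {
  cb <- contact_coords(conf)
  L <- nrow(cb)
  dm <- as.matrix(dist(cb))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  any(dm[sep >= 2 & upper.tri(dm)] < min_dist)
}

#' Native contact list of a structure
#'
#' All residue pairs with sequence separation >= 5 and CB-CB distance
#' (CA for glycine) at most `d_con`, each with ppv 1.
#'
#' @param native A `conformation`.
#' @param d_con Contact distance bound (default 8 A).
#' @return A `contact_list`.
#' @export
native_contacts <- function(native, d_con = 8) {
  cb <- contact_coords(native)
  L <- nrow(cb)
  dm <- as.matrix(dist(cb))
  idx <- which(upper.tri(dm) & dm <= d_con &
               abs(outer(seq_len(L), seq_len(L), "-")) >= 5, arr.ind = TRUE)
  contact_list(data.frame(i = idx[, 1], j = idx[, 2], ppv = 1), L = L)
}

#' Simulate a noisy predicted-contact list
#'
#' Samples `round(n * p)` true native contacts (CB-CB <= 8 A, separation
#' >= 5) and `n - round(n * p)` false pairs (separation >= 5, native
#' distance > 12 A so that "false" stays unambiguous under coordinate
#' jitter). Probabilities (PPV) are drawn either truth-independently
#' (uniform, so the expected precision of any top-k prefix equals `p`) or
#' truth-correlated (true: Beta(4,2), false: Beta(2,4)), mimicking an
#' informative but imperfect ranking.
#'
#' @param native A `conformation`.
#' @param n_contacts Number of predicted contacts.
#' @param target_precision Fraction of true contacts in the list, in [0,1].
#' @param ppv_mode `"independent"` or `"correlated"`.
#' @param seed Integer seed.
#' @param d_con Contact distance bound (default 8 A).
#' @return A `contact_list` with an attribute `truth` (logical per record,
#'   in record order).
#' @export
simulate_predictions <- function(native, n_contacts, target_precision = 0.8,
                                 ppv_mode = c("independent", "correlated"),
                                 seed = 1, d_con = 8) {
  ppv_mode <- match.arg(ppv_mode)
  if (n_contacts <= 0) stop("n_contacts must be positive")
  stopifnot(target_precision >= 0, target_precision <= 1)
  cb <- contact_coords(native)
  L <- nrow(cb)
  dm <- as.matrix(dist(cb))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  ut <- upper.tri(dm)
  true_pool <- which(ut & sep >= 5 & dm <= d_con, arr.ind = TRUE)
  false_pool <- which(ut & sep >= 5 & dm > 12, arr.ind = TRUE)
  n_true <- round(n_contacts * target_precision)
  n_false <- n_contacts - n_true
  if (nrow(true_pool) < n_true)
    stop("native has only ", nrow(true_pool), " true contacts; need ", n_true)
  if (nrow(false_pool) < n_false)
    stop("not enough non-contact pairs for ", n_false, " false predictions")
  set.seed(seed)
  ti <- true_pool[sample.int(nrow(true_pool), n_true), , drop = FALSE]
  fi <- false_pool[sample.int(nrow(false_pool), n_false), , drop = FALSE]
  truth <- c(rep(TRUE, n_true), rep(FALSE, n_false))
  if (ppv_mode == "independent") {
    ppv <- runif(n_contacts, 0.05, 0.95)
  } else {
    ppv <- numeric(n_contacts)
    ppv[truth] <- rbeta(n_true, 4, 2)
    ppv[!truth] <- rbeta(n_false, 2, 4)
    ppv <- pmin(pmax(ppv, 1e-6), 1)
  }
  df <- data.frame(i = c(ti[, 1], fi[, 1]), j = c(ti[, 2], fi[, 2]),
                   ppv = ppv, truth = truth)
  cl <- contact_list(df[, c("i", "j", "ppv")], L = L)
  # carry truth labels through the (ppv-sorted) record order
  key <- paste(df$i, df$j)
  attr(cl, "truth") <- df$truth[match(paste(cl$records$i, cl$records$j), key)]
  cl
}

#' Generate a labelled near/far decoy set
#'
#' Near-native decoys jitter the native torsions (sigma = 8 degrees,
#' loop residues only); far decoys shuffle 9-residue torsion fragments of
#' the native and re-draw a fraction of positions from the broad
#' helical/extended torsion basins, destroying the topology while keeping
#' the chain locally protein-like.
#' Each decoy is labelled with its TM-score to the native.
#'
#' @param native A `conformation` (ideally from [make_toy()], which stores
#'   the true secondary-structure states used to locate loops).
#' @param n_near,n_far Decoy counts.
#' @param near_sigma Loop-torsion jitter width for near decoys (degrees,
#'   default 8); larger values emulate harder modelling targets whose
#'   "best" models drift from the native.
#' @param near_sigma_global Additional all-residue jitter width for near
#'   decoys (degrees, default 0); nonzero values also degrade secondary
#'   structure elements, emulating targets whose models are wrong
#'   throughout rather than merely re-hinged.
#' @param seed Integer seed.
#' @param em Optional calibrated `energy_model`: decoy energies are then
#'   recorded (with `contacts`/`ss_pred` as given).
#' @param contacts,ss_pred Optional scoring context for `em`.
#' @return An `ensemble` whose decoys carry `tm_native` labels.
#' @export
make_decoy_set <- function(native, n_near, n_far, seed = 1, em = NULL,
                           contacts = NULL, ss_pred = NULL, near_sigma = 8,
                           near_sigma_global = 0) {
  stopifnot(n_near >= 0, n_far >= 0)
  states <- attr(native, "ss_true") %||% ss_from_torsions(native)
  loops <- which(states == "C")
  L <- n_res(native)
  set.seed(seed)
  decoys <- list()
  add <- function(tor, mode, k) {
    conf <- build_chain(native$aa, tor)
    e <- terms <- NULL
    if (!is.null(em)) {
      terms <- evaluate_terms(conf, em, contacts, ss_pred)
      e <- sum(em$weights * terms)
    }
    list(conformation = conf, energy = e %||% NA_real_, terms = terms,
         mode = mode, seed = k, tm_native = tm_score(conf, native))
  }
  for (k in seq_len(n_near)) {
    tor <- native$torsions
    if (length(loops))
      tor[loops, 1:2] <- tor[loops, 1:2] +
        matrix(rnorm(2 * length(loops), 0, near_sigma), length(loops), 2)
    if (near_sigma_global > 0)
      tor[, 1:2] <- tor[, 1:2] +
        matrix(rnorm(2 * L, 0, near_sigma_global), L, 2)
    decoys[[length(decoys) + 1L]] <- add(tor, "near", k)
  }
  for (k in seq_len(n_far)) {
    blocks <- split(seq_len(L), ceiling(seq_len(L) / 9))
    tor <- native$torsions[unlist(blocks[sample.int(length(blocks))]), ,
                           drop = FALSE]
    redraw <- sample.int(L, round(0.3 * L))
    basin <- sample.int(2, length(redraw), replace = TRUE)
    tor[redraw, 1] <- ifelse(basin == 1, rnorm(length(redraw), -63, 25),
                             rnorm(length(redraw), -120, 30))
    tor[redraw, 2] <- ifelse(basin == 1, rnorm(length(redraw), -42, 25),
                             rnorm(length(redraw), 135, 30))
    decoys[[length(decoys) + 1L]] <- add(tor, "far", n_near + k)
  }
  new_ensemble(decoys)
}
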