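# Replica-exchange simulated-annealing fragment assembly.

#' Annealing configuration
#'
#' `steps` is the total Monte Carlo move budget summed over replicas (each
#' replica performs `steps / n_replicas` moves), matching the convention of
#' quoting one total step count per folding run. The replica ladder is
#' geometric between `t_low` (coldest) and `t_high`, and the whole ladder is
#' annealed linearly to a fraction `t_low / t_high` of its starting value
#' over the run. `mode` selects how predicted contacts enter the objective:
#' `"all"` (every contact active throughout), `"sequential"` (separation
#' bound grows linearly from `s0` to `L - 1` across `n_cycles` cycles),
#' `"no_contacts"` (RR weight zero) or `"contacts_only"` (all statistical
#' weights zero).
#'
#' @param steps Total MC moves across replicas.
#' @param n_replicas Number of replicas (default 8).
#' @param t_high,t_low Temperature ladder bounds in kT (defaults 10, 0.5).
#' @param exchange_interval Moves (per replica) between neighbour-exchange
#'   attempts (default 500).
#' @param mode One of `"all"`, `"sequential"`, `"no_contacts"`,
#'   `"contacts_only"`.
#' @param seed Integer seed; every fold run is bit-reproducible given it.
#' @param n_cycles Temperature/schedule cycles per run (default 50).
#' @param s0 Starting separation bound of the sequential schedule
#'   (default 9).
#' @param p_frag Probability of a fragment-replacement move (default 0.8,
#'   else a single-residue torsion perturbation of sigma
#'   `perturb_sigma` degrees).
#' @param perturb_sigma Torsion perturbation width (default 10 degrees).
#' @return List of class `anneal_config`.
#' @export
anneal_config <- function(steps = 50000, n_replicas = 8, t_high = 10,
                          t_low = 0.5, exchange_interval = 500,
                          mode = c("all", "sequential", "no_contacts",
                                   "contacts_only"),
                          seed = 1, n_cycles = 50, s0 = 9, p_frag = 0.8,
                          perturb_sigma = 10) {
  mode <- match.arg(mode)
  stopifnot(steps >= 0, n_replicas >= 1, t_high > t_low, t_low > 0)
  structure(list(steps = as.integer(steps),
                 n_replicas = as.integer(n_replicas),
                 t_high = t_high, t_low = t_low,
                 exchange_interval = as.integer(exchange_interval),
                 mode = mode, seed = as.integer(seed),
                 n_cycles = as.integer(n_cycles), s0 = as.integer(s0),
                 p_frag = p_frag, perturb_sigma = perturb_sigma),
            class = "anneal_config")
}

mode_weights <- function(em, mode) {
  w <- em$weights
  if (is.null(w)) stop("energy model is not calibrated")
  if (mode == "no_contacts") w["RR"] <- 0
  if (mode == "contacts_only") w[setdiff(ENERGY_TERMS, "RR")] <- 0
  w
}

#' One annealing run producing a single decoy
#'
#' Metropolis Monte Carlo over fragment-replacement moves (random position,
#' random shortlist member) and single-residue torsion perturbations, across
#' a replica-exchange temperature ladder annealed over the run, starting
#' from the extended chain. Returns the lowest-energy conformation visited
#' in the coldest replica; the recorded energy and terms are recomputed from
#' the returned coordinates with the full contact set active, so they are
#' reproducible from the decoy alone.
#'
#' @param target Target sequence (string or `list(id, sequence)`).
#' @param ss_pred `ss2_prediction` for the target.
#' @param shortlists Per-position fragment shortlists from
#'   [shortlists_for_target()].
#' @param em Calibrated `energy_model`.
#' @param contacts A `contact_list` (ignored in `no_contacts` mode).
#' @param cfg An [anneal_config()].
#' @return A decoy: `list(conformation, energy, terms, mode, seed,
#'   diagnostics)`.
#' @export
anneal <- function(target, ss_pred, shortlists, em, contacts, cfg) {
  aa <- seq_to_vec(if (is.list(target)) target$sequence else target)
  check_sequence(aa)
  L <- length(aa)
  nonempty <- sum(lengths(shortlists) > 0)
  if (nonempty == 0 && cfg$steps > 0)
    stop("all fragment shortlists are empty")
  tor0 <- cbind(phi = rep(-139, L), psi = rep(135, L), omega = rep(180, L))
  w <- mode_weights(em, cfg$mode)
  use_contacts <- if (cfg$mode == "no_contacts") NULL else contacts
  co <- contacts_int(use_contacts, L)
  sl_cpp <- lapply(shortlists, function(sl)
    lapply(sl, function(f) unname(f$torsions)))
  ccfg <- list(steps = cfg$steps, n_replicas = cfg$n_replicas,
               t_high = cfg$t_high, t_low = cfg$t_low,
               exchange_interval = cfg$exchange_interval,
               n_cycles = cfg$n_cycles,
               sequential = cfg$mode == "sequential", s0 = cfg$s0,
               p_frag = cfg$p_frag, perturb_sigma = cfg$perturb_sigma,
               seed = cfg$seed)
  res <- .cpp_remc(aa_class(aa) - 1L, as.integer(aa == "G"),
                   ss_states_int(ss_pred, L),
                   tor0[, 1], tor0[, 2], tor0[, 3],
                   sl_cpp, co$idx, co$ppv, unname(w), em_par_list(em), ccfg)
  tor <- res$torsions
  colnames(tor) <- c("phi", "psi", "omega")
  conf <- build_chain(aa, tor)
  terms <- evaluate_terms(conf, em, use_contacts, ss_pred)
  list(conformation = conf, energy = sum(w * terms), terms = terms,
       mode = cfg$mode, seed = cfg$seed,
       diagnostics = list(accept_rate = res$accept_rate,
                          exchange_rate = res$exchange_rate,
                          trace = res$trace,
                          final_max_sep = res$final_max_sep,
                          frag_used = res$frag_used))
}

new_ensemble <- function(decoys) {
  structure(list(decoys = decoys), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  e <- vapply(x$decoys, `[[`, 0, "energy")
  cat("<ensemble> ", length(x$decoys), " decoys; energy range [",
      paste(sprintf("%.2f", range(e)), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Ensemble length
#' @param ens An `ensemble`.
#' @return Number of decoys.
#' @export
n_decoys <- function(ens) length(ens$decoys)

#' Generate a decoy ensemble
#'
#' Runs [anneal()] `n_decoys` times with seeds `cfg$seed + 0 ... + n - 1`.
#' In `"combined"` mode the pool holds `n_decoys` all-contacts plus
#' `n_decoys` sequential-contacts runs, tagged by mode, from which the best
#' low-energy models can be selected jointly.
#'
#' @inheritParams anneal
#' @param n_decoys Decoys per mode.
#' @param mode Override of `cfg$mode`; additionally accepts `"combined"`.
#' @return An `ensemble`.
#' @export
generate_ensemble <- function(target, ss_pred, shortlists, em, contacts, cfg,
                              n_decoys = 200, mode = NULL) {
  stopifnot(n_decoys >= 1)
  mode <- mode %||% cfg$mode
  modes <- if (mode == "combined") c("all", "sequential") else mode
  decoys <- list()
  for (m in modes) {
    for (k in seq_len(n_decoys)) {
      ck <- cfg
      ck$mode <- m
      ck$seed <- cfg$seed + (k - 1L)
      decoys[[length(decoys) + 1L]] <-
        anneal(target, ss_pred, shortlists, em, contacts, ck)
    }
  }
  new_ensemble(decoys)
}
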