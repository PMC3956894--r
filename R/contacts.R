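# Predicted-contact handling: the contact pseudo-energy term, contact
# introduction schedules, contact order and satisfaction statistics.

#' Contact list objects
#'
#' An ordered list of predicted residue-residue contacts `(i, j, ppv)` with
#' `i < j`, sequence separation `j - i >= 5`, sorted by descending ppv (ties
#' broken by `(i, j)` lexicographic order for determinism). Only contacts
#' with `ppv > min_ppv` are retained; the default keeps every contact with
#' positive probability.
#'
#' @param records Data frame with columns `i`, `j`, `ppv`.
#' @param L Target chain length (needed for top-L selection; may be NA).
#' @param min_ppv Strict lower bound on `ppv`.
#' @return Object of class `contact_list` with elements `records` and `L`.
#' @export
contact_list <- function(records, L = NULL, min_ppv = 0) {
  df <- as.data.frame(records)
  stopifnot(all(c("i", "j", "ppv") %in% names(df)))
  if (nrow(df)) {
    if (any(df$i >= df$j)) stop("contact records require i < j")
    df <- df[df$j - df$i >= 5, , drop = FALSE]
    df <- df[df$ppv > min_ppv, , drop = FALSE]
    if (nrow(df)) {
      # duplicates keep the highest ppv
      df <- df[order(df$i, df$j, -df$ppv), , drop = FALSE]
      df <- df[!duplicated(df[, c("i", "j")]), , drop = FALSE]
      df <- df[order(-df$ppv, df$i, df$j), , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  structure(list(records = df, L = L %||% NA_integer_),
            class = "contact_list")
}

#' @export
print.contact_list <- function(x, ...) {
  cat("<contact_list> ", nrow(x$records), " contacts, L = ", x$L, "\n",
      sep = "")
  if (nrow(x$records)) print(head(x$records, 5))
  invisible(x)
}

#' Top-k*L contacts by descending ppv
#'
#' @param contacts A `contact_list` with known `L`.
#' @param k Multiplier of the chain length (default 1: top-L).
#' @return A `contact_list` restricted to the first `min(round(k*L), n)`
#'   records.
#' @export
top_l <- function(contacts, k = 1) {
  L <- contacts$L
  if (is.na(L)) stop("contact list has no chain length; set L")
  n <- min(round(k * L), nrow(contacts$records))
  contact_list(contacts$records[seq_len(n), , drop = FALSE], L = L)
}

#' Contact range class from sequence separation
#'
#' Short range: separation 5-9; mid range: 10-23; long range: > 23.
#'
#' @param sep Integer vector of sequence separations (`j - i`).
#' @return Factor with levels `short`, `mid`, `long`.
#' @export
contact_range <- function(sep) {
  if (any(sep < 5)) stop("separations below 5 are not classified")
  cut(sep, breaks = c(4, 9, 23, Inf), labels = c("short", "mid", "long"))
}

#' Contact pseudo-energy of one predicted contact
#'
#' Square well with exponential decay: inside the well (`d <= d_con`) the
#' energy is `-P`; beyond it the attraction decays exponentially and turns
#' into a penalty approaching `+P`, so unsatisfied contacts are penalized
#' proportionally to their predicted probability:
#' \deqn{E(d) = -P, \quad d \le d_{con};\qquad
#'       E(d) = P\,(1 - 2 e^{-(d - d_{con})/\lambda}), \quad d > d_{con}.}
#' The form is continuous at `d_con` and strictly increasing beyond it.
#'
#' @param ppv Contact probability in (0, 1].
#' @param d Current CB-CB distance (CA-CA for glycine) in Angstrom.
#' @param d_con Contact distance bound (default 8 A).
#' @param decay Decay length `lambda` (default 4 A).
#' @return Energy value (dimensionless, kT units).
#' @export
rrcon_energy <- function(ppv, d, d_con = 8, decay = 4) {
  if (any(ppv <= 0)) stop("contact ppv must be positive")
  ifelse(d <= d_con, -ppv, ppv * (1 - 2 * exp(-(d - d_con) / decay)))
}

#' Total contact pseudo-energy of a model
#'
#' Sum of [rrcon_energy()] over the contacts whose sequence separation does
#' not exceed `max_sep` (all contacts when `max_sep = NULL`). Distances are
#' CB-CB (CA for glycine).
#'
#' @param model A `conformation`.
#' @param contacts A `contact_list` (1-based indices within the model).
#' @param max_sep Active-schedule separation bound, or NULL for all.
#' @param d_con,decay Passed to [rrcon_energy()].
#' @return Total energy.
#' @export
rrcon_total <- function(model, contacts, max_sep = NULL, d_con = 8,
                        decay = 4) {
  df <- contacts$records
  if (!nrow(df)) return(0)
  L <- n_res(model)
  if (any(df$j > L) || any(df$i < 1)) stop("contact index out of range")
  if (!is.null(max_sep)) df <- df[df$j - df$i <= max_sep, , drop = FALSE]
  if (!nrow(df)) return(0)
  cb <- contact_coords(model)
  d <- sqrt(rowSums((cb[df$i, , drop = FALSE] - cb[df$j, , drop = FALSE])^2))
  sum(rrcon_energy(df$ppv, d, d_con, decay))
}

#' Maximum active separation under the sequential schedule
#'
#' At cycle `t` of `T`, contacts with separation up to
#' `round(s0 + (L - 1 - s0) * t / T)` are active (round-half-up): only
#' short-range contacts at the start, everything at the end, increasing
#' linearly with each cycle.
#'
#' @param t Current cycle, `0 <= t <= T`.
#' @param T Total cycles; `T = 0` activates all contacts.
#' @param L Chain length.
#' @param s0 Starting separation bound (default 9, the end of the
#'   short-range class).
#' @return Integer separation bound.
#' @export
schedule_max_separation <- function(t, T, L, s0 = 9) {
  if (T == 0) return(L - 1L)
  stopifnot(t >= 0, t <= T)
  as.integer(floor(s0 + (L - 1 - s0) * t / T + 0.5))
}

#' Predicted contact order
#'
#' Mean sequence separation of the top-`k*L` predicted contacts divided by
#' the chain length, in percent.
#'
#' @param contacts A `contact_list` with known `L`.
#' @param k Top-list multiplier (default 1).
#' @return Contact order in percent.
#' @export
contact_order <- function(contacts, k = 1) {
  tl <- top_l(contacts, k)$records
  if (!nrow(tl)) stop("no contacts in top-", k, "L")
  100 * mean(tl$j - tl$i) / contacts$L
}

#' Per-range contact satisfaction statistics
#'
#' A predicted contact is satisfied when the model's CB-CB distance (CA for
#' glycine) is at most `d_con`. When a native structure is supplied,
#' predictions are additionally split into true contacts (native distance
#' `<= d_con`) and false ones, with satisfied fractions reported for each
#' group.
#'
#' @param model A `conformation`.
#' @param contacts A `contact_list`.
#' @param native Optional native `conformation` of the same length.
#' @param k Top-list multiplier applied before scoring (default 1; use
#'   `Inf` for the full list).
#' @param d_con Contact distance bound (default 8 A).
#' @return Data frame with one row per range class (`short`, `mid`, `long`)
#'   plus `overall`: columns `n_predicted`, `n_satisfied`, `fraction` and,
#'   with a native, `n_true`, `n_true_satisfied`, `n_false`,
#'   `n_false_satisfied`.
#' @export
satisfaction_stats <- function(model, contacts, native = NULL, k = 1,
                               d_con = 8) {
  df <- if (is.finite(k)) top_l(contacts, k)$records else contacts$records
  cb <- contact_coords(model)
  if (nrow(df)) {
    d <- sqrt(rowSums((cb[df$i, , drop = FALSE] -
                       cb[df$j, , drop = FALSE])^2))
    sat <- d <= d_con
    rng <- contact_range(df$j - df$i)
  } else {
    sat <- logical(0)
    rng <- contact_range(integer(0))
  }
  have_native <- !is.null(native)
  if (have_native) {
    if (n_res(native) != n_res(model)) stop("native length mismatch")
    ncb <- contact_coords(native)
    nd <- if (nrow(df))
      sqrt(rowSums((ncb[df$i, , drop = FALSE] -
                    ncb[df$j, , drop = FALSE])^2)) else numeric(0)
    truth <- nd <= d_con
  }
  one <- function(idx) {
    n <- length(idx)
    row <- data.frame(n_predicted = n, n_satisfied = sum(sat[idx]),
                      fraction = if (n) sum(sat[idx]) / n else NA_real_)
    if (have_native) {
      tr <- truth[idx]
      row$n_true <- sum(tr)
      row$n_true_satisfied <- sum(sat[idx] & tr)
      row$true_fraction <- if (any(tr)) sum(sat[idx] & tr) / sum(tr)
                           else NA_real_
      row$n_false <- sum(!tr)
      row$n_false_satisfied <- sum(sat[idx] & !tr)
      row$false_fraction <- if (any(!tr)) sum(sat[idx] & !tr) / sum(!tr)
                            else NA_real_
    }
    row
  }
  out <- do.call(rbind, lapply(levels(rng), function(cl) one(which(rng == cl))))
  out <- rbind(out, one(seq_along(sat)))
  cbind(range = c(levels(rng), "overall"), out)
}

#' Write a satisfaction report as TSV
#' @param stats Output of [satisfaction_stats()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_satisfaction <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL
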