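# Fragment library construction and per-position shortlists: fixed-length
# torsion fragments plus supersecondary (element-loop-element) fragments
# mined from source structures, with sequence-based decontamination against
# the target.

new_fragment <- function(kind, torsions, ss, source, offset) {
  structure(list(kind = kind, length = nrow(torsions), torsions = torsions,
                 ss = ss, source = source, offset = offset),
            class = "fragment")
}

#' Build a fragment library from source structures
#'
#' Fixed fragments are every contiguous `fixed_len` window with complete
#' torsions inside one chain segment. Supersecondary fragments span two
#' secondary-structure elements (H or E runs of at least `min_element`
#' residues, assigned geometrically from backbone torsions) joined by a loop
#' of at most `max_loop` residues, giving the kinds `H-loop-H`, `E-loop-E`,
#' `H-loop-E` and `E-loop-H`.
#'
#' To keep benchmark folding blind, windows whose sequence identity to any
#' equal-length window of `exclude_target` reaches `max_identity` are
#' dropped.
#'
#' @param sources List of `conformation` objects (each may carry a `source`
#'   id attribute; list names are used otherwise).
#' @param fixed_len Fixed fragment length (default 9).
#' @param exclude_target Target sequence (string or `list(id, sequence)`)
#'   for decontamination, or NULL.
#' @param max_identity Identity threshold for exclusion (default 0.35).
#' @param min_element,max_loop Supersecondary pattern bounds.
#' @return A `fragment_library`.
#' @export
build_library <- function(sources, fixed_len = 9, exclude_target = NULL,
                          max_identity = 0.35, min_element = 4,
                          max_loop = 8) {
  if (!length(sources)) stop("no source structures")
  if (is.null(names(sources)))
    names(sources) <- sprintf("src%03d", seq_along(sources))
  tgt <- NULL
  if (!is.null(exclude_target)) {
    tgt <- if (is.list(exclude_target)) exclude_target$sequence
           else exclude_target
    tgt <- seq_to_vec(tgt)
  }
  frags <- list()
  for (nm in names(sources)) {
    conf <- sources[[nm]]
    tor <- conf$torsions
    L <- n_res(conf)
    ok <- !apply(is.na(tor), 1, any)
    segs <- conf$segments
    ss <- ss_from_torsions(conf)
    window_ok <- function(a, b) {
      all(ok[a:b]) && segs[a] == segs[b]
    }
    contaminated <- function(a, b) {
      if (is.null(tgt)) return(FALSE)
      w <- conf$aa[a:b]; n <- length(w)
      if (length(tgt) < n) return(FALSE)
      for (s in 1:(length(tgt) - n + 1)) {
        if (sum(w == tgt[s:(s + n - 1)]) / n >= max_identity) return(TRUE)
      }
      FALSE
    }
    # fixed-length windows
    if (L >= fixed_len) {
      for (a in 1:(L - fixed_len + 1)) {
        b <- a + fixed_len - 1
        if (!window_ok(a, b) || contaminated(a, b)) next
        frags[[length(frags) + 1L]] <-
          new_fragment("fixed", tor[a:b, , drop = FALSE],
                       paste(ss[a:b], collapse = ""), nm, a)
      }
    }
    # supersecondary: consecutive element pairs with a short connecting loop
    r <- rle(ss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    el <- which(r$values %in% c("H", "E") & r$lengths >= min_element)
    if (length(el) >= 2) {
      for (q in 1:(length(el) - 1)) {
        e1 <- el[q]; e2 <- el[q + 1]
        gap <- if (e2 == e1 + 1) 0 else
          sum(r$lengths[(e1 + 1):(e2 - 1)])
        if (gap < 1 || gap > max_loop) next
        a <- starts[e1]; b <- ends[e2]
        if (!window_ok(a, b) || contaminated(a, b)) next
        kind <- paste0(r$values[e1], "-loop-", r$values[e2])
        frags[[length(frags) + 1L]] <-
          new_fragment(kind, tor[a:b, , drop = FALSE],
                       paste(ss[a:b], collapse = ""), nm, a)
      }
    }
  }
  if (!length(frags)) stop("fragment library is empty after filtering")
  structure(list(fragments = frags), class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  kinds <- table(vapply(x$fragments, `[[`, "", "kind"))
  cat("<fragment_library> ", length(x$fragments), " fragments (",
      paste(names(kinds), kinds, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

ss_agreement <- function(frag_ss, pred_states, pred_conf, pos) {
  n <- nchar(frag_ss)
  idx <- pos:(pos + n - 1)
  fs <- strsplit(frag_ss, "")[[1]]
  w <- pred_conf[cbind(idx, match(pred_states[idx], colnames(pred_conf)))]
  sum(w * (fs == pred_states[idx])) / sum(w)
}

threading_score <- function(frag, target_aa, pos, pair_table) {
  # target residues mounted on the fragment's local geometry; SR/LR pair
  # energies within the window
  conf <- build_chain(target_aa[pos:(pos + frag$length - 1)], frag$torsions)
  cb <- contact_coords(conf)
  cls <- aa_class(conf$aa)
  n <- frag$length
  e <- 0
  if (n >= 6) {
    for (a in 1:(n - 5)) for (b in (a + 5):n) {
      d <- sqrt(sum((cb[a, ] - cb[b, ])^2))
      if (d >= pair_table$dmax) next
      bin <- min(pair_table$nbin, floor(d / pair_table$bw) + 1)
      tab <- if (b - a <= 10) pair_table$sr else pair_table$lr
      e <- e + tab[cls[a], cls[b], bin]
    }
  }
  e
}

#' Per-position fragment shortlist
#'
#' Filters library fragments that fit at `position`, agree with the
#' predicted secondary structure at 70% of positions or more
#' (confidence-weighted), and ranks survivors by threading score (the pair
#' potential of the target residues mounted on the fragment geometry,
#' ascending). When no fragment passes the filter the best `K` by agreement
#' alone are returned with a warning. Ties break by source id then offset.
#'
#' @param lib A `fragment_library`.
#' @param position 1-based start position in the target.
#' @param ss_pred `ss2_prediction` for the target.
#' @param target Target sequence (string or `list(id, sequence)`).
#' @param pair_table A `pair_table` for the threading score.
#' @param K Shortlist size (default 25).
#' @param min_agreement Secondary-structure agreement threshold.
#' @return List of `fragment` objects (possibly fewer than `K`).
#' @export
shortlist <- function(lib, position, ss_pred, target, pair_table, K = 25,
                      min_agreement = 0.7) {
  aa <- seq_to_vec(if (is.list(target)) target$sequence else target)
  L <- length(aa)
  fits <- Filter(function(f) position + f$length - 1 <= L, lib$fragments)
  if (!length(fits)) return(list())
  agr <- vapply(fits, function(f)
    ss_agreement(f$ss, ss_pred$states, ss_pred$conf, position), 0)
  pass <- agr >= min_agreement
  if (!any(pass)) {
    warning("no fragment meets the secondary-structure filter at position ",
            position, "; falling back to agreement ranking")
    ord <- order(-agr, vapply(fits, `[[`, "", "source"),
                 vapply(fits, `[[`, 0, "offset"))
    return(fits[head(ord, K)])
  }
  cand <- fits[pass]
  sc <- vapply(cand, threading_score, 0, target_aa = aa, pos = position,
               pair_table = pair_table)
  ord <- order(sc, vapply(cand, `[[`, "", "source"),
               vapply(cand, `[[`, 0, "offset"))
  cand[head(ord, K)]
}

#' Shortlists for every start position of a target
#'
#' @inheritParams shortlist
#' @return List of length `L`: element `p` is the shortlist at position `p`
#'   (empty where nothing fits or passes).
#' @export
shortlists_for_target <- function(lib, ss_pred, target, pair_table, K = 25,
                                  min_agreement = 0.7) {
  aa <- seq_to_vec(if (is.list(target)) target$sequence else target)
  lapply(seq_along(aa), function(p)
    tryCatch(
      suppressWarnings(shortlist(lib, p, ss_pred, target, pair_table, K,
                                 min_agreement)),
      error = function(e) list()))
}

#' Serialize a fragment library to TSV
#'
#' One row per fragment: kind, source, offset, length, ss and the flattened
#' torsion triplets (`phi1:psi1:omega1|...`).
#'
#' @param lib A `fragment_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  rows <- do.call(rbind, lapply(lib$fragments, function(f) {
    data.frame(kind = f$kind, source = f$source, offset = f$offset,
               length = f$length, ss = f$ss,
               torsions = paste(apply(round(f$torsions, 3), 1, paste,
                                      collapse = ":"), collapse = "|"))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment library written by [write_library()]
#' @param path TSV file.
#' @return A `fragment_library`.
#' @export
read_library <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  frags <- lapply(seq_len(nrow(df)), function(k) {
    tor <- do.call(rbind, lapply(strsplit(df$torsions[k], "\\|")[[1]],
                                 function(s) as.numeric(strsplit(s, ":")[[1]])))
    colnames(tor) <- c("phi", "psi", "omega")
    new_fragment(df$kind[k], tor, df$ss[k], df$source[k], df$offset[k])
  })
  structure(list(fragments = frags), class = "fragment_library")
}
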