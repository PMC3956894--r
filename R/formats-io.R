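# Readers/writers for FASTA, PSIPRED ss2, CASP RR and PDB, plus the MSA
# preprocessing filters applied to folding input alignments.
#
# Residue indices are 1-based in every file format and inside all exported
# objects; 0-based conversion happens only at the C++ boundary.

#' Read sequences or alignments from FASTA
#'
#' @param path FASTA file. May contain gaps (alignments).
#' @return A list of records, each `list(id, sequence)`; class
#'   `fasta_records`.
#' @export
read_fasta <- function(path) {
  fa <- bio3d::read.fasta(path, rm.dup = FALSE)
  recs <- lapply(seq_len(nrow(fa$ali)), function(i) {
    list(id = rownames(fa$ali)[i],
         sequence = paste(toupper(fa$ali[i, ]), collapse = ""))
  })
  structure(recs, class = "fasta_records")
}

#' Write sequences to FASTA
#' @param records List of `list(id, sequence)` (or a single such record).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!is.null(records$id)) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    c(paste0(">", r$id), gsub("(.{60})", "\\1\n", r$sequence)) }))
  writeLines(sub("\n$", "", lines), path)
  invisible(path)
}

#' Read a predicted-contact list (CASP RR dialect)
#'
#' Accepts the CASP RR body format (`i j d_low d_high prob`) as well as bare
#' two-column (`i j`, probability 1) and three-column (`i j prob`) lists.
#' Header lines (`PFRMAT`, `TARGET`, `AUTHOR`, `METHOD`, `MODEL`, `END`) and
#' blank lines are ignored. The d_low/d_high columns are ignored: the well
#' bound of the contact energy is the model's `d_con`, not the file's.
#'
#' Records are normalized to `i < j`; pairs with sequence separation
#' `j - i < 5` are dropped (shorter separations are never scored); duplicate
#' `(i, j)` pairs keep the highest probability. Only records with
#' `ppv > min_ppv` are kept (strict, so the default keeps exactly the
#' positive-probability contacts).
#'
#' @param path RR file.
#' @param L Target length (stored on the result; needed for top-L selection).
#' @param min_ppv Strict lower bound on accepted probabilities (default 0).
#' @return A [contact_list()] sorted by descending ppv.
#' @export
read_contacts <- function(path, L = NULL, min_ppv = 0) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|REMARK|MODEL|END)", lines,
           ignore.case = TRUE)
  idx <- which(keep)
  if (!length(idx)) return(contact_list(data.frame(i = integer(), j = integer(),
                                                   ppv = numeric()), L = L))
  rows <- lapply(idx, function(k) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    n <- length(tok)
    vals <- suppressWarnings(as.numeric(tok))
    if (!(n %in% c(2L, 3L, 5L)) || anyNA(vals))
      stop("malformed contact record at line ", k, ": '", lines[k], "'")
    ppv <- if (n == 2L) 1.0 else vals[n]
    c(vals[1], vals[2], ppv)
  })
  m <- do.call(rbind, rows)
  df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                   ppv = m[, 3])
  swap <- df$i > df$j
  if (any(swap)) df[swap, c("i", "j")] <- df[swap, c("j", "i")]
  if (any(df$i == df$j)) {
    bad <- which(df$i == df$j)
    warning("rejected ", length(bad), " self-contact record(s) at line(s) ",
            paste(idx[bad], collapse = ", "))
    df <- df[-bad, ]
  }
  contact_list(df, L = L, min_ppv = min_ppv)
}

#' Write a contact list in CASP RR body format
#' @param contacts A [contact_list()].
#' @param path Output file.
#' @param d_low,d_high Distance bounds written per record (informational).
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path, d_low = 0, d_high = 8) {
  df <- contacts$records
  writeLines(sprintf("%d %d %g %g %.6f", df$i, df$j, d_low, d_high, df$ppv),
             path)
  invisible(path)
}

#' Read a PSIPRED ss2 secondary-structure prediction
#'
#' Parses the standard VFORMAT: one line per residue with index, residue,
#' state (C/H/E) and the three state probabilities in column order C, H, E.
#' Confidence triplets that do not sum to 1 within 0.01 are renormalized with
#' a warning (PSIPRED rounds to three decimals).
#'
#' @param path ss2 file.
#' @param sequence Optional sequence to validate length against.
#' @return List with `states` (character vector in H/E/C), `conf`
#'   (`L x 3` matrix, columns H, E, C) and `residues`; class `ss2_prediction`.
#' @export
read_ss2 <- function(path, sequence = NULL) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(body)) stop("empty ss2 file: ", path)
  tok <- strsplit(trimws(body), "\\s+")
  if (any(lengths(tok) < 6)) stop("malformed ss2 line in ", path)
  m <- do.call(rbind, tok)
  states <- m[, 3]
  if (!all(states %in% c("C", "H", "E"))) stop("unknown ss2 state in ", path)
  conf <- cbind(H = as.numeric(m[, 5]), E = as.numeric(m[, 6]),
                C = as.numeric(m[, 4]))
  sums <- rowSums(conf)
  off <- abs(sums - 1) > 0.01
  if (any(off)) {
    warning(sum(off), " ss2 confidence triplet(s) did not sum to 1; ",
            "renormalized")
    conf[off, ] <- conf[off, ] / sums[off]
  }
  if (!is.null(sequence)) {
    aa <- seq_to_vec(sequence)
    if (length(aa) != nrow(conf))
      stop("ss2 length (", nrow(conf), ") does not match sequence length (",
           length(aa), ")")
  }
  structure(list(states = states, conf = conf, residues = m[, 2]),
            class = "ss2_prediction")
}

#' Write a PSIPRED-style ss2 file
#' @param ss An `ss2_prediction` (or list with `states`, `conf`, `residues`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(ss, path) {
  lines <- c("# PSIPRED VFORMAT (contactfold)", "")
  lines <- c(lines, sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                            seq_along(ss$states), ss$residues, ss$states,
                            ss$conf[, "C"], ss$conf[, "H"], ss$conf[, "E"]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein chain from a PDB file
#'
#' Extracts per-residue N, CA, C, O, CB coordinates for one chain using
#' \pkg{bio3d}. Alternate locations other than `'A'`/blank are discarded and
#' insertion codes collapse into sequential numbering. A missing CB is
#' synthesized at the ideal tetrahedral position; a missing O is rebuilt from
#' backbone geometry. Residues missing any of N/CA/C are dropped and
#' terminate a fragment-extractable segment, as do chain breaks
#' (consecutive CA-CA > 4.5 A); segment ids are stored on the result.
#'
#' @param path PDB file.
#' @param chain Chain identifier (default: first chain in the file).
#' @param model Model number for multi-MODEL files (default 1).
#' @return A `conformation` with torsions derived from the coordinates
#'   (NA across segment boundaries and termini).
#' @export
read_structure <- function(path, chain = NULL, model = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", ]
  if (nrow(at) == 0) stop("no parseable ATOM records in ", path)
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  chain <- chain %||% at$chain[1]
  at <- at[at$chain == chain, ]
  if (nrow(at) == 0) stop("no residues for chain '", chain, "' in ", path)
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model)
      stop("model ", model, " not present in ", path)
    xyz_m <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    sel <- match(rownames(at), rownames(pdb$atom))
    at[, c("x", "y", "z")] <- xyz_m[sel, ]
  }
  key <- paste(at$resno, at$insert %||% "", sep = "_")
  res_keys <- unique(key)
  aa <- character(0); rows <- list()
  for (k in res_keys) {
    sub <- at[key == k, ]
    nm <- sub$elety
    if (!all(c("N", "CA", "C") %in% nm)) next
    get <- function(a) as.numeric(sub[match(a, nm), c("x", "y", "z")])
    xyz <- rbind(N = get("N"), CA = get("CA"), C = get("C"),
                 O = if ("O" %in% nm) get("O") else c(NA, NA, NA),
                 CB = if ("CB" %in% nm) get("CB") else c(NA, NA, NA))
    rows[[length(rows) + 1L]] <- xyz
    aa[length(aa) + 1L] <- aa321_safe(sub$resid[1])
  }
  if (!length(rows)) stop("no residues with complete N/CA/C backbone in ", path)
  L <- length(rows)
  xyz <- array(NA_real_, c(L, 5, 3),
               dimnames = list(NULL, ATOM_NAMES, c("x", "y", "z")))
  for (i in seq_len(L)) xyz[i, , ] <- rows[[i]]
  # synthesize missing O and CB from ideal geometry
  for (i in seq_len(L)) {
    if (anyNA(xyz[i, "CB", ]))
      xyz[i, "CB", ] <- ideal_cb(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ])
    if (anyNA(xyz[i, "O", ])) {
      psi <- if (i < L) dihedral(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                                 xyz[i + 1, "N", ]) else 0
      xyz[i, "O", ] <- nerf_r(xyz[i, "N", ], xyz[i, "CA", ], xyz[i, "C", ],
                              1.231, 120.8, psi + 180)
    }
  }
  segs <- integer(L); seg <- 1L
  for (i in seq_len(L)) {
    if (i > 1) {
      gap <- sqrt(sum((xyz[i, "CA", ] - xyz[i - 1, "CA", ])^2))
      if (gap > 4.5) seg <- seg + 1L
    }
    segs[i] <- seg
  }
  conf <- new_conformation(aa, matrix(NA_real_, L, 3), xyz, segments = segs)
  tor <- extract_torsions(conf)
  tor[c(FALSE, segs[-1] != segs[-L]), ] <- NA  # no torsions across breaks
  conf$torsions <- tor
  conf
}

aa321_safe <- function(resid) {
  one <- bio3d::aa321(resid)
  ifelse(one %in% AA1, one, "X")
}

ideal_cb <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- pracma_cross(b, cc)
  ca - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
}

nerf_r <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- (c - b) / sqrt(sum((c - b)^2))
  n <- pracma_cross(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  c + (-r * cos(th)) * bc + (r * sin(th) * cos(ch)) * m +
    (-r * sin(th) * sin(ch)) * n
}

#' Write a conformation as a PDB file
#'
#' Emits ATOM records for N, CA, C, O, CB (no CB for glycine) with
#' occupancy 1 and B-factor 0. Optional REMARK lines are written first.
#'
#' @param conf A `conformation`.
#' @param path Output file.
#' @param chain Chain id (default "A").
#' @param remarks Character vector of REMARK payloads (optional).
#' @param append Append to an existing file (used by the ensemble writer).
#' @return `path`, invisibly.
#' @export
write_structure <- function(conf, path, chain = "A", remarks = NULL,
                            append = FALSE) {
  serial0 <- 0L
  if (append && file.exists(path)) {
    prev <- grep("^ATOM", readLines(path), value = TRUE)
    if (length(prev))
      serial0 <- max(as.integer(substr(prev, 7, 11)), 0L)
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (!is.null(remarks))
    writeLines(sprintf("REMARK   9 %s", remarks), con)
  writeLines(structure_atom_lines(conf, chain, serial0), con)
  writeLines("TER", con)
  invisible(path)
}

structure_atom_lines <- function(conf, chain = "A", serial0 = 0L) {
  L <- n_res(conf)
  lines <- character(0); serial <- serial0
  aa3 <- bio3d::aa123(conf$aa)
  for (i in seq_len(L)) {
    atoms <- if (conf$aa[i] == "G") ATOM_NAMES[1:4] else ATOM_NAMES
    for (a in atoms) {
      serial <- serial + 1L
      x <- conf$xyz[i, a, ]
      el <- substr(a, 1, 1)
      # strict PDB columns: name 13-16, altLoc 17, resName 18-20, chain 22
      lines[length(lines) + 1L] <- sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", a), aa3[i], chain, i, x[1], x[2], x[3], 1, 0, el)
    }
  }
  lines
}

#' Write a decoy ensemble as a multi-MODEL PDB
#'
#' Each decoy becomes one MODEL block carrying `REMARK   9 ENERGY` (total)
#' and `REMARK   9 TERMS` (the seven raw term values) lines.
#'
#' @param ensemble An `ensemble` (see [generate_ensemble()]) or list of
#'   decoys.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  decoys <- if (inherits(ensemble, "ensemble")) ensemble$decoys else ensemble
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(decoys)) {
    d <- decoys[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK   9 ENERGY %.6f", d$energy), con)
    writeLines(sprintf("REMARK   9 TERMS %s",
                       paste(sprintf("%.6f", d$terms), collapse = " ")), con)
    writeLines(sprintf("REMARK   9 MODE %s SEED %d", d$mode, d$seed), con)
    writeLines(structure_atom_lines(d$conformation), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a decoy ensemble written by [write_ensemble()]
#' @param path Multi-MODEL PDB file.
#' @return List of decoys (`conformation`, `energy`, `terms`, `mode`,
#'   `seed`).
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) != length(ends)) stop("malformed ensemble file")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    energy <- as.numeric(sub("REMARK   9 ENERGY ", "",
                             grep("REMARK   9 ENERGY", block, value = TRUE)[1]))
    terms_ln <- grep("REMARK   9 TERMS", block, value = TRUE)
    terms <- if (length(terms_ln))
      as.numeric(strsplit(sub("REMARK   9 TERMS ", "", terms_ln[1]),
                          " ")[[1]]) else NULL
    meta <- grep("REMARK   9 MODE", block, value = TRUE)
    mode <- seedv <- NA
    if (length(meta)) {
      tk <- strsplit(meta[1], "\\s+")[[1]]
      mode <- tk[4]; seedv <- as.integer(tk[6])
    }
    writeLines(block[grepl("^(ATOM|TER)", block)], tmp)
    list(conformation = read_structure(tmp), energy = energy, terms = terms,
         mode = mode, seed = seedv)
  })
}

#' Filter a folding input alignment
#'
#' Applies, in order: removal of duplicate rows, deletion of columns gapped
#' in the query (the first row), and removal of rows whose sequence identity
#' to the query is below `min_identity`. Identity is the number of matching
#' positions divided by the number of non-gap query columns.
#'
#' @param aln Alignment: a character matrix (rows = sequences) or a
#'   `fasta_records` list of aligned sequences; the first row is the query.
#' @param min_identity Identity threshold in `[0, 1]` (default 0.30).
#' @return Filtered alignment as a character matrix with row names.
#' @export
filter_msa <- function(aln, min_identity = 0.30) {
  m <- as_alignment_matrix(aln)
  if (nrow(m) < 1) stop("empty alignment")
  # duplicates (first occurrence kept; query row always kept)
  seqs <- apply(m, 1, paste, collapse = "")
  m <- m[!duplicated(seqs), , drop = FALSE]
  # drop columns gapped in the query
  gapchr <- c("-", ".")
  keep_col <- !(m[1, ] %in% gapchr)
  m <- m[, keep_col, drop = FALSE]
  # identity filter against the query
  query <- m[1, ]
  ident <- apply(m, 1, function(r) sum(r == query) / length(query))
  keep <- ident >= min_identity
  keep[1] <- TRUE
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0 || ncol(m) == 0) stop("alignment empty after filtering")
  m
}

as_alignment_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (inherits(aln, "fasta_records") || is.list(aln)) {
    seqs <- vapply(aln, function(r) r$sequence, "")
    if (length(unique(nchar(seqs))) != 1)
      stop("alignment rows must have equal length")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- vapply(aln, function(r) r$id, "")
    return(m)
  }
  stop("cannot interpret alignment input")
}
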