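# Molecular graph construction: SMILES / SDF V2000 readers, SMILES writer.
# The package works on hydrogen-suppressed 2D topology only; attached
# hydrogens are resolved to per-atom counts at parse time.

SUPPORTED_ELEMENTS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                        "Si", "Se", "As",
                        # common counter-ion elements (parseable so salt
                        # records load; descriptors reject them by name)
                        "Na", "K", "Li", "Ca", "Mg", "Zn")

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# default valence sets used to resolve implicit hydrogens
DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = c(2, 4, 6), As = c(3, 5),
  Na = 1, K = 1, Li = 1, Ca = 2, Mg = 2, Zn = 2
)

# implicit hydrogens for an atom given its explicit bond-order sum
# (aromatic bonds count 1.5; the sum is ceiled before valence lookup)
.impliedH <- function(element, aromatic, bond_order_sum) {
  v <- DEFAULT_VALENCE[[element]]
  if (is.null(v)) return(0L)
  total <- as.integer(ceiling(bond_order_sum - 1e-9))
  v_ok <- v[v >= total]
  if (!length(v_ok)) return(0L)
  as.integer(v_ok[1] - total)
}

.bondOrderNum <- function(order) {
  c("1" = 1, "2" = 2, "3" = 3, "ar" = 1.5)[order]
}

.newMolecule <- function(id, atoms, bonds, source) {
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  new("Molecule", id = as.character(id), atoms = atoms, bonds = bonds,
      source = as.character(source))
}

.emptyBonds <- function() {
  data.frame(i = integer(), j = integer(), order = character(),
             stringsAsFactors = FALSE)
}

#' Parse a SMILES string into a Molecule
#'
#' Accepts organic-subset SMILES with aromatic lowercase notation,
#' bracket atoms (charge and explicit H count), branches, ring closures
#' (including \code{\%nn}) and dot-separated fragments. Aromatic atoms
#' must sit in an aromatic ring system (every aromatic atom needs at
#' least two aromatic bonds); otherwise parsing fails rather than
#' guessing a Kekule structure.
#'
#' Multi-fragment records (salts) keep the largest connected fragment
#' with a warning, unless \code{keepAllFragments = TRUE} (used e.g. by
#' additivity test harnesses).
#'
#' @param smiles a single SMILES string.
#' @param id compound label (defaults to the SMILES itself).
#' @param keepAllFragments logical; retain disconnected fragments.
#' @return a [Molecule-class] object.
#' @export
#' @examples
#' parseSmiles("CCO", id = "ethanol")
parseSmiles <- function(smiles, id = smiles, keepAllFragments = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  s <- trimws(smiles)
  if (!nzchar(s)) stop("empty SMILES string")
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  el <- character(); chg <- integer(); arom <- logical()
  nH <- integer(); explicitH <- logical()
  bi <- integer(); bj <- integer(); bord <- character()

  prev <- NA_integer_
  pending_bond <- NA_character_
  branch_stack <- integer()
  ring_open <- list()   # digit -> list(atom, bond)

  fail <- function(msg, pos) {
    stop(sprintf("SMILES parse error in '%s' at position %d: %s",
                 s, pos, msg), call. = FALSE)
  }

  add_atom <- function(element, aromatic, charge, hcount, h_explicit) {
    if (!element %in% SUPPORTED_ELEMENTS) {
      stop(sprintf("unsupported element '%s' in SMILES '%s'", element, s),
           call. = FALSE)
    }
    el[length(el) + 1L] <<- element
    arom[length(arom) + 1L] <<- aromatic
    chg[length(chg) + 1L] <<- charge
    nH[length(nH) + 1L] <<- hcount
    explicitH[length(explicitH) + 1L] <<- h_explicit
    length(el)
  }

  add_bond <- function(a, b, order) {
    bi[length(bi) + 1L] <<- min(a, b)
    bj[length(bj) + 1L] <<- max(a, b)
    bord[length(bord) + 1L] <<- order
  }

  bond_for <- function(a, b, sym) {
    if (!is.na(sym)) return(sym)
    if (arom[a] && arom[b]) "ar" else "1"
  }

  connect <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, bond_for(prev, idx, pending_bond))
    pending_bond <<- NA_character_
    prev <<- idx
  }

  close_ring <- function(key, pos) {
    if (is.na(prev)) fail("ring closure before any atom", pos)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      ring_open[[key]] <<- NULL
      sym <- pending_bond
      if (!is.na(op$bond) && !is.na(sym) && op$bond != sym) {
        fail(sprintf("conflicting ring-closure bonds for '%s'", key), pos)
      }
      if (is.na(sym)) sym <- op$bond
      add_bond(op$atom, prev, bond_for(op$atom, prev, sym))
      pending_bond <<- NA_character_
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- NA_character_
    }
  }

  k <- 1L
  while (k <= n) {
    ch <- chars[k]
    if (ch == "[") {
      close_pos <- k
      while (close_pos <= n && chars[close_pos] != "]") close_pos <- close_pos + 1L
      if (close_pos > n) fail("unterminated bracket atom", k)
      body <- paste(chars[(k + 1L):(close_pos - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2}H?[0-9]*)((?:\\+{1,3}|-{1,3}|[+-][0-9]+)?)(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) fail(sprintf("cannot parse bracket atom [%s]", body), k)
      sym <- m[3]
      aromatic <- sym == tolower(sym)
      element <- paste0(toupper(substr(sym, 1, 1)),
                        substring(sym, 2))
      hpart <- m[4]
      hc <- 0L
      hm <- regmatches(hpart, regexec("H([0-9]*)", hpart))[[1]]
      if (length(hm)) hc <- if (nzchar(hm[2])) as.integer(hm[2]) else 1L
      cpart <- m[5]
      charge <- 0L
      if (nzchar(cpart)) {
        if (grepl("^[+-][0-9]+$", cpart)) {
          charge <- as.integer(cpart)
        } else {
          charge <- nchar(cpart) * (if (substr(cpart, 1, 1) == "+") 1L else -1L)
        }
      }
      idx <- add_atom(element, aromatic, charge, hc, TRUE)
      connect(idx)
      k <- close_pos + 1L
    } else if (k < n && paste0(ch, chars[k + 1L]) %in% c("Cl", "Br")) {
      idx <- add_atom(paste0(ch, chars[k + 1L]), FALSE, 0L, 0L, FALSE)
      connect(idx)
      k <- k + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- add_atom(ch, FALSE, 0L, 0L, FALSE)
      connect(idx)
      k <- k + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE, 0L, 0L, FALSE)
      connect(idx)
      k <- k + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- "1"; k <- k + 1L
    } else if (ch == "=") {
      pending_bond <- "2"; k <- k + 1L
    } else if (ch == "#") {
      pending_bond <- "3"; k <- k + 1L
    } else if (ch == ":") {
      pending_bond <- "ar"; k <- k + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom", k)
      branch_stack <- c(branch_stack, prev)
      k <- k + 1L
    } else if (ch == ")") {
      if (!length(branch_stack)) fail("unmatched ')'", k)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      k <- k + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, k)
      k <- k + 1L
    } else if (ch == "%") {
      if (k + 2L > n) fail("truncated %nn ring closure", k)
      close_ring(paste0("%", chars[k + 1L], chars[k + 2L]), k)
      k <- k + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
      k <- k + 1L
    } else {
      fail(sprintf("unexpected character '%s'", ch), k)
    }
  }
  if (length(branch_stack)) fail("unclosed branch", n)
  if (length(ring_open)) fail("unclosed ring bond", n)
  if (!length(el)) stop(sprintf("SMILES '%s' contains no atoms", s))

  # implicit hydrogens for organic-subset atoms
  bsum <- numeric(length(el))
  if (length(bi)) {
    ords <- .bondOrderNum(bord)
    for (b in seq_along(bi)) {
      bsum[bi[b]] <- bsum[bi[b]] + ords[b]
      bsum[bj[b]] <- bsum[bj[b]] + ords[b]
    }
  }
  for (a in seq_along(el)) {
    if (!explicitH[a]) {
      nH[a] <- .impliedH(el[a], arom[a], bsum[a])
    }
  }

  # aromatic sanity: every aromatic atom must carry >= 2 aromatic bonds
  if (any(arom)) {
    ar_deg <- integer(length(el))
    sel <- which(bord == "ar")
    for (b in sel) {
      ar_deg[bi[b]] <- ar_deg[bi[b]] + 1L
      ar_deg[bj[b]] <- ar_deg[bj[b]] + 1L
    }
    bad <- which(arom & ar_deg < 2L)
    if (length(bad)) {
      stop(sprintf(
        "aromatic system in SMILES '%s' could not be resolved (atom %s outside an aromatic ring)",
        s, paste(bad, collapse = ",")), call. = FALSE)
    }
  }

  atoms <- data.frame(element = el, charge = chg, aromatic = arom, nH = nH,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = bord, stringsAsFactors = FALSE)
  mol <- .newMolecule(id, atoms, bonds, s)
  if (!keepAllFragments) mol <- .largestFragment(mol)
  validObject(mol)
  mol
}

# connected-component split; keep the largest fragment (ties -> first)
.components <- function(nAtoms, bonds) {
  comp <- seq_len(nAtoms)
  if (nrow(bonds)) {
    repeat {
      changed <- FALSE
      for (b in seq_len(nrow(bonds))) {
        ci <- comp[bonds$i[b]]; cj <- comp[bonds$j[b]]
        if (ci != cj) {
          comp[comp == max(ci, cj)] <- min(ci, cj)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  match(comp, unique(comp))
}

.largestFragment <- function(mol) {
  comp <- .components(nrow(mol@atoms), mol@bonds)
  if (max(comp) == 1L) return(mol)
  sizes <- tabulate(comp)
  keep <- which.max(sizes)
  warning(sprintf(
    "molecule '%s': %d disconnected fragments; keeping largest (%d atoms)",
    mol@id, max(comp), sizes[keep]), call. = FALSE)
  sel <- which(comp == keep)
  remap <- match(seq_len(nrow(mol@atoms)), sel)
  b <- mol@bonds[comp[mol@bonds$i] == keep, , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  .newMolecule(mol@id, mol@atoms[sel, , drop = FALSE], b, mol@source)
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one record per line, \code{"SMILES[whitespace]name"};
#' blank lines and lines starting with \code{#} are skipped. SDF files
#' are V2000 connection tables. An unparsable record raises an error
#' naming its line (SMILES) or record (SDF) number.
#'
#' @param path file to read.
#' @param format \code{"smiles"} or \code{"sdf"}; default guessed from
#'   the file extension (.sdf/.mol vs anything else).
#' @return a list of [Molecule-class] objects in file order.
#' @export
readMolecules <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(sdf|mol)$", path, ignore.case = TRUE))
      "sdf" else "smiles"
  }
  if (format == "smiles") .readSmilesFile(path) else .readSdfFile(path)
}

.readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt) || startsWith(txt, "#")) next
    parts <- strsplit(txt, "[[:space:]]+")[[1]]
    id <- if (length(parts) >= 2L) paste(parts[-1], collapse = " ") else parts[1]
    mol <- tryCatch(parseSmiles(parts[1], id = id),
                    error = function(e) {
                      stop(sprintf("line %d of '%s': %s", ln, path,
                                   conditionMessage(e)), call. = FALSE)
                    })
    mols[[length(mols) + 1L]] <- mol
  }
  if (!length(mols)) warning("no molecule records in '", path, "'")
  mols
}

SDF_CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                     `5` = -1L, `6` = -2L, `7` = -3L)

.readSdfFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split records on $$$$
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  mols <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (!any(nzchar(trimws(rec)))) next
    mol <- tryCatch(.parseSdfRecord(rec, r),
                    error = function(e) {
                      stop(sprintf("SDF record %d of '%s': %s", r, path,
                                   conditionMessage(e)), call. = FALSE)
                    })
    mols[[length(mols) + 1L]] <- mol
  }
  if (!length(mols)) warning("no molecule records in '", path, "'")
  mols
}

.parseSdfRecord <- function(rec, recno) {
  if (length(rec) < 4L) stop("truncated record")
  id <- trimws(rec[1])
  if (!nzchar(id)) id <- sprintf("record_%d", recno)
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("malformed counts line")
  if (length(rec) < 4L + na + nb) stop("truncated atom/bond block")
  atom_lines <- rec[5:(4 + na)]
  el <- trimws(substr(atom_lines, 32, 34))
  ccode <- trimws(substr(atom_lines, 37, 39))
  chg <- SDF_CHARGE_CODE[ifelse(ccode %in% names(SDF_CHARGE_CODE), ccode, "0")]
  chg <- as.integer(chg)
  bi <- integer(nb); bj <- integer(nb); bo <- integer(nb)
  if (nb > 0L) {
    bond_lines <- rec[(5 + na):(4 + na + nb)]
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    bo <- as.integer(substr(bond_lines, 7, 9))
    if (anyNA(bi) || anyNA(bj) || anyNA(bo)) stop("malformed bond block")
  }
  # M CHG property lines override the atom-block charge column
  for (pl in grep("^M  CHG", rec, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", pl)),
                                "[[:space:]]+")[[1]])
    npairs <- toks[1]
    chg[seq_len(na)] <- replace(chg, integer(0), integer(0))
    if (!is.na(npairs) && npairs > 0) {
      for (p in seq_len(npairs)) {
        chg[toks[2 * p]] <- toks[2 * p + 1]
      }
    }
  }
  bad <- !el %in% c(SUPPORTED_ELEMENTS, "H")
  if (any(bad)) {
    stop(sprintf("unsupported element(s): %s",
                 paste(unique(el[bad]), collapse = ", ")))
  }
  order_chr <- as.character(bo)
  order_chr[bo == 4L] <- "ar"
  if (!all(order_chr %in% c("1", "2", "3", "ar"))) {
    stop("unsupported bond order in record")
  }
  arom <- logical(na)
  for (b in which(order_chr == "ar")) {
    arom[bi[b]] <- TRUE; arom[bj[b]] <- TRUE
  }
  # suppress explicit hydrogens into neighbour counts
  hsel <- which(el == "H")
  nH_explicit <- integer(na)
  bsum <- numeric(na)
  ords <- .bondOrderNum(order_chr)
  for (b in seq_len(nb)) {
    bsum[bi[b]] <- bsum[bi[b]] + ords[b]
    bsum[bj[b]] <- bsum[bj[b]] + ords[b]
    if (el[bi[b]] == "H") nH_explicit[bj[b]] <- nH_explicit[bj[b]] + 1L
    if (el[bj[b]] == "H") nH_explicit[bi[b]] <- nH_explicit[bi[b]] + 1L
  }
  keep <- setdiff(seq_len(na), hsel)
  remap <- match(seq_len(na), keep)
  nH <- integer(length(keep))
  for (k in seq_along(keep)) {
    a <- keep[k]
    nH[k] <- .impliedH(el[a], arom[a], bsum[a]) + nH_explicit[a]
  }
  bkeep <- which(el[bi] != "H" & el[bj] != "H")
  atoms <- data.frame(element = el[keep], charge = chg[keep],
                      aromatic = arom[keep], nH = nH,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = pmin(remap[bi[bkeep]], remap[bj[bkeep]]),
                      j = pmax(remap[bi[bkeep]], remap[bj[bkeep]]),
                      order = order_chr[bkeep], stringsAsFactors = FALSE)
  mol <- .newMolecule(id, atoms, bonds, sprintf("sdf:record:%d", recno))
  mol <- .largestFragment(mol)
  validObject(mol)
  mol
}

#' Heavy-atom count
#'
#' Number of non-hydrogen atoms of a molecule (the HA of ligand
#' efficiency calculations).
#'
#' @param mol a [Molecule-class].
#' @return integer count.
#' @export
heavyAtomCount <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  nrow(mol@atoms)
}

#' Write a Molecule back to a SMILES string
#'
#' Deterministic depth-first writer. Returns the SMILES and the order in
#' which the molecule's atoms were emitted, so a re-parse can be compared
#' atom-by-atom under the known mapping.
#'
#' @param mol a [Molecule-class].
#' @return list with elements \code{smiles} (string) and \code{order}
#'   (integer vector: original atom index of each emitted atom).
#' @export
moleculeToSmiles <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  a <- mol@atoms
  nA <- nrow(a)
  nB <- nrow(mol@bonds)
  adj <- vector("list", nA)
  for (b in seq_len(nB)) {
    i <- mol@bonds$i[b]; j <- mol@bonds$j[b]
    adj[[i]] <- rbind(adj[[i]], c(j, b))
    adj[[j]] <- rbind(adj[[j]], c(i, b))
  }
  border <- mol@bonds$order
  ords <- .bondOrderNum(border)
  bsum <- numeric(nA)
  for (b in seq_len(nB)) {
    bsum[mol@bonds$i[b]] <- bsum[mol@bonds$i[b]] + ords[b]
    bsum[mol@bonds$j[b]] <- bsum[mol@bonds$j[b]] + ords[b]
  }

  # DFS spanning tree from atom 1; remaining edges become ring closures
  visited <- logical(nA)
  edge_seen <- logical(nB)
  parent_edge <- integer(nA)
  dfs_children <- vector("list", nA)
  back_edges <- integer(0)
  walk <- function(v) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]; be <- nb[r, 2]
      if (edge_seen[be]) next
      edge_seen[be] <<- TRUE
      if (!visited[w]) {
        dfs_children[[v]] <<- c(dfs_children[[v]], w)
        parent_edge[w] <<- be
        walk(w)
      } else {
        back_edges <<- c(back_edges, be)
      }
    }
  }
  walk(1L)
  if (!all(visited)) stop("cannot write SMILES for a disconnected molecule")

  digit_lookup <- list()
  for (idx in seq_along(back_edges)) {
    digit_lookup[[as.character(back_edges[idx])]] <-
      if (idx <= 9L) as.character(idx) else sprintf("%%%02d", idx)
  }
  remaining <- new.env(parent = emptyenv())
  for (be in back_edges) assign(as.character(be), 2L, envir = remaining)

  bond_sym <- function(be, from, to) {
    o <- border[be]
    if (o == "2") return("=")
    if (o == "3") return("#")
    if (o == "ar") {
      return(if (a$aromatic[from] && a$aromatic[to]) "" else ":")
    }
    if (a$aromatic[from] && a$aromatic[to]) return("-")
    ""
  }
  atom_token <- function(v) {
    element <- a$element[v]
    sym <- if (a$aromatic[v]) tolower(element) else element
    implied <- .impliedH(element, a$aromatic[v], bsum[v])
    if (element %in% ORGANIC_SUBSET && a$charge[v] == 0L &&
        a$nH[v] == implied) {
      return(sym)
    }
    h <- if (a$nH[v] == 0L) "" else if (a$nH[v] == 1L) "H"
         else paste0("H", a$nH[v])
    ch <- a$charge[v]
    cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else sprintf("%+d", ch)
    paste0("[", sym, h, cs, "]")
  }

  emitted <- integer(0)
  emit <- function(v) {
    out <- atom_token(v)
    emitted <<- c(emitted, v)
    nb <- adj[[v]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        be <- nb[r, 2]
        key <- as.character(be)
        d <- digit_lookup[[key]]
        if (!is.null(d)) {
          left <- get0(key, envir = remaining, ifnotfound = 0L)
          if (left > 0L) {
            sym <- if (left == 2L) bond_sym(be, v, nb[r, 1]) else ""
            out <- paste0(out, sym, d)
            assign(key, left - 1L, envir = remaining)
          }
        }
      }
    }
    kids <- dfs_children[[v]]
    if (length(kids)) {
      for (ki in seq_along(kids)) {
        w <- kids[ki]
        piece <- paste0(bond_sym(parent_edge[w], v, w), emit(w))
        if (ki < length(kids)) piece <- paste0("(", piece, ")")
        out <- paste0(out, piece)
      }
    }
    out
  }
  smiles <- emit(1L)
  list(smiles = smiles, order = emitted)
}

#' Write molecules to a SMILES (.smi) file
#'
#' One \code{"SMILES name"} record per line; optional comment header
#' lines are prefixed with \code{#}.
#'
#' @param mols list of [Molecule-class] objects.
#' @param path output file.
#' @param header optional character vector of comment lines.
#' @return invisibly, the path.
#' @export
writeMolecules <- function(mols, path, header = NULL) {
  recs <- vapply(mols, function(m) {
    paste(moleculeToSmiles(m)$smiles, m@id)
  }, character(1))
  out <- c(if (length(header)) paste0("# ", header), recs)
  writeLines(out, path)
  invisible(path)
}
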