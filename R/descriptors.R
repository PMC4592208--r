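# Topological descriptor calculators. All descriptors operate on the
# hydrogen-suppressed graph; attached hydrogens enter only through the
# per-atom counts (polarizability, MW, logP hydrogen terms, HBD).

.adjList <- function(mol) {
  adj <- vector("list", nrow(mol@atoms))
  for (b in seq_len(nrow(mol@bonds))) {
    i <- mol@bonds$i[b]; j <- mol@bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# all-pairs topological distances by repeated BFS (all bonds length 1)
.distMatrix <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- .adjList(mol)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep.int(Inf, n)
    d[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- d
  }
  D
}

# per-atom bond-context summary used by the atom-typing schemes
.bondContext <- function(mol) {
  n <- nrow(mol@atoms)
  ctx <- data.frame(
    s = integer(n), d = integer(n), t = integer(n), ar = integer(n)
  )
  dbl_to_O <- logical(n)   # atom has a double bond to oxygen
  nbr_carbonyl <- logical(n) # atom neighbours a C or S double-bonded to O
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    col <- switch(b$order[k], "1" = "s", "2" = "d", "3" = "t", "ar" = "ar")
    ctx[[col]][i] <- ctx[[col]][i] + 1L
    ctx[[col]][j] <- ctx[[col]][j] + 1L
    if (b$order[k] == "2") {
      if (mol@atoms$element[j] == "O") dbl_to_O[i] <- TRUE
      if (mol@atoms$element[i] == "O") dbl_to_O[j] <- TRUE
    }
  }
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    ei <- mol@atoms$element[i]; ej <- mol@atoms$element[j]
    if (dbl_to_O[i] && ei %in% c("C", "S")) nbr_carbonyl[j] <- TRUE
    if (dbl_to_O[j] && ej %in% c("C", "S")) nbr_carbonyl[i] <- TRUE
  }
  ctx$dbl_to_O <- dbl_to_O
  ctx$nbr_carbonyl <- nbr_carbonyl
  ctx
}

#' Balaban distance-connectivity index J
#'
#' \deqn{J = \frac{M}{\mu + 1} \sum_{(i,j) \in E} (s_i s_j)^{-1/2}}
#' where \eqn{M} is the number of heavy-atom bonds, \eqn{\mu = M - N + 1}
#' the cyclomatic number, and \eqn{s_i} the sum of topological distances
#' from atom \eqn{i} to all heavy atoms (all bonds length 1, no
#' bond-order weighting).
#'
#' @param mol a [Molecule-class]; must be connected with at least two
#'   heavy atoms.
#' @return the unitless index (positive for any connected graph with at
#'   least one bond).
#' @export
#' @examples
#' balabanIndex(parseSmiles("CCC"))   # 2 * 2/sqrt(6) ~ 1.633
balabanIndex <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  n <- nrow(mol@atoms)
  M <- nrow(mol@bonds)
  if (n < 2L || M < 1L) {
    stop(sprintf("Balaban index undefined for molecule '%s': fewer than 2 bonded heavy atoms",
                 mol@id))
  }
  D <- .distMatrix(mol)
  if (any(is.infinite(D))) {
    stop(sprintf("Balaban index undefined for molecule '%s': disconnected graph",
                 mol@id))
  }
  s <- rowSums(D)
  mu <- M - n + 1L
  terms <- 1 / sqrt(s[mol@bonds$i] * s[mol@bonds$j])
  M / (mu + 1) * sum(terms)
}

# resolve the TPSA environment key of a polar atom
.tpsaKey <- function(el, charge, aromatic, nH, ctx_row) {
  s <- ctx_row$s; d <- ctx_row$d; t <- ctx_row$t; ar <- ctx_row$ar
  if (el == "N") {
    if (aromatic) {
      if (nH >= 1L) return("N_ar2_H1")
      if (ar >= 3L) return("N_ar3")
      if (s >= 1L) return("N_ar2_1s")
      return("N_ar2")
    }
    if (charge > 0L) {
      if (nH == 0L && s == 4L) return("N+_4s")
      if (nH == 1L && s == 3L) return("N+_H1_3s")
      if (nH == 2L && s == 2L) return("N+_H2_2s")
      if (nH == 3L && s == 1L) return("N+_H3_1s")
      if (d == 1L) return("N+_2s1d")
      return(NA_character_)
    }
    if (charge != 0L) return(NA_character_)
    if (nH == 0L) {
      if (t == 1L) return("N_1t")
      if (d == 1L && s == 1L) return("N_1s1d")
      if (d == 1L && s == 2L) return("N_2s1d")
      if (s == 3L) return("N_3s")
      return(NA_character_)
    }
    if (nH == 1L) {
      if (d == 1L) return("N_H1_1s1d")
      if (s == 2L) return("N_H1_2s")
      return(NA_character_)
    }
    if (nH == 2L && s == 1L) return("N_H2_1s")
    return(NA_character_)
  }
  if (el == "O") {
    if (aromatic) return("O_ar2")
    if (charge < 0L) return("O-_1s")
    if (charge != 0L) return(NA_character_)
    if (d == 1L) return("O_1d")
    if (nH >= 1L) return("O_H1_1s")
    if (s == 2L) return("O_2s")
    return(NA_character_)
  }
  NA_character_
}

#' Topological polar surface area (TPSA)
#'
#' Fragment-additive sum of N/O-centred polar contributions from the
#' package's frozen Ertl-type table. Carbon-only molecules score 0.
#' Polar environments outside the table fall back to the generic N/O
#' contribution with a message.
#'
#' @param mol a [Molecule-class].
#' @return TPSA in square Angstroms (>= 0).
#' @export
#' @examples
#' tpsa(parseSmiles("CCO"))       # hydroxyl contribution, 20.23
#' tpsa(parseSmiles("c1ccccc1"))  # 0
tpsa <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  a <- mol@atoms
  ctx <- .bondContext(mol)
  total <- 0
  for (k in seq_len(nrow(a))) {
    el <- a$element[k]
    if (!el %in% c("N", "O")) next
    key <- .tpsaKey(el, a$charge[k], a$aromatic[k], a$nH[k], ctx[k, ])
    if (!is.na(key) && key %in% names(TPSA_CONTRIB)) {
      total <- total + TPSA_CONTRIB[[key]]
    } else {
      message(sprintf(
        "tpsa: molecule '%s' atom %d (%s) in an environment outside the table; using generic contribution",
        mol@id, k, el))
      total <- total + TPSA_GENERIC[[el]]
    }
  }
  total
}

#' Hydrogen-bond acceptor count
#'
#' Default (\code{rule = "lipinski"}): number of N and O atoms not
#' carrying a positive formal charge. The stricter \code{"lone_pair"}
#' rule additionally excludes pyrrole-type aromatic N-H and amide
#' nitrogens, whose lone pairs are delocalised.
#'
#' @param mol a [Molecule-class].
#' @param rule acceptor convention.
#' @return integer count.
#' @export
hbaCount <- function(mol, rule = c("lipinski", "lone_pair")) {
  rule <- match.arg(rule)
  a <- mol@atoms
  acc <- a$element %in% c("N", "O") & a$charge <= 0L
  if (rule == "lone_pair") {
    ctx <- .bondContext(mol)
    pyrrole <- a$element == "N" & a$aromatic & a$nH >= 1L
    amide <- a$element == "N" & !a$aromatic & ctx$nbr_carbonyl
    acc <- acc & !pyrrole & !amide
  }
  sum(acc)
}

#' Hydrogen-bond donor count
#'
#' Default convention counts each N/O heteroatom bearing at least one
#' hydrogen once, regardless of hydrogen multiplicity (Rule-of-Five
#' usage); \code{perHydrogen = TRUE} counts every polar hydrogen.
#'
#' @param mol a [Molecule-class].
#' @param perHydrogen logical; count individual polar hydrogens instead
#'   of donor heteroatoms.
#' @return integer count.
#' @export
hbdCount <- function(mol, perHydrogen = FALSE) {
  a <- mol@atoms
  don <- a$element %in% c("N", "O") & a$nH >= 1L
  if (perHydrogen) sum(a$nH[don]) else sum(don)
}

# resolve the frozen logP atom type of a heavy atom
.clogpKey <- function(el, aromatic, ctx_row) {
  if (el == "C") {
    if (aromatic) return("C_ar")
    if (ctx_row$dbl_to_O) return("C_carbonyl")
    return("C_aliph")
  }
  if (el == "N") {
    if (aromatic) return("N_ar")
    if (ctx_row$nbr_carbonyl) return("N_amide")
    return("N_aliph")
  }
  if (el == "O") {
    if (aromatic) return("O_ar")
    if (ctx_row$d >= 1L) return("O_carbonyl")
    if (ctx_row$nH_hint) return("O_hydroxyl")
    return("O_ether")
  }
  paste0(el, "_any")
}

#' Calculated logP (atom-additive, Crippen-type)
#'
#' Sums the package's frozen atom-typed contributions (including
#' per-hydrogen terms) over all atoms. Deterministic for a given
#' molecule; an atom type outside the table falls back to its
#' element-level contribution with a warning.
#'
#' Pipeline stages accept externally supplied clogP values that override
#' this estimate (see [efficiencyTable()], [runPipeline()]), since
#' published activity models are typically fitted against other logP
#' implementations.
#'
#' @param mol a [Molecule-class].
#' @return unitless logP estimate.
#' @export
clogp <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  a <- mol@atoms
  ctx <- .bondContext(mol)
  total <- 0
  for (k in seq_len(nrow(a))) {
    row <- ctx[k, ]
    row$nH_hint <- a$nH[k] >= 1L
    key <- .clogpKey(a$element[k], a$aromatic[k], row)
    if (key %in% names(CLOGP_CONTRIB)) {
      total <- total + CLOGP_CONTRIB[[key]]
    } else {
      warning(sprintf(
        "clogp: molecule '%s' atom %d type '%s' outside table; using element fallback",
        mol@id, k, key), call. = FALSE)
      total <- total + CLOGP_ELEMENT_FALLBACK[[a$element[k]]]
    }
    hkey <- if (a$element[k] == "C") "H_on_C" else "H_on_hetero"
    total <- total + a$nH[k] * CLOGP_CONTRIB[[hkey]]
  }
  total
}

#' Molar polarizability (element-additive)
#'
#' Sum over all atoms, including attached hydrogens, of the frozen
#' element polarizability contributions.
#'
#' @param mol a [Molecule-class].
#' @return polarizability in cubic Angstroms.
#' @export
#' @examples
#' molarPolarizability(parseSmiles("CC"))  # 2*1.76 + 6*0.667 = 7.522
molarPolarizability <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  a <- mol@atoms
  missing_el <- setdiff(unique(a$element), names(ATOMIC_POLARIZABILITY))
  if (length(missing_el)) {
    stop("no polarizability contribution for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  sum(ATOMIC_POLARIZABILITY[a$element]) +
    sum(a$nH) * ATOMIC_POLARIZABILITY[["H"]]
}

#' Molecular weight
#'
#' @param mol a [Molecule-class].
#' @return MW in g/mol, including attached hydrogens.
#' @export
molecularWeight <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  a <- mol@atoms
  sum(ATOMIC_WEIGHTS[a$element]) + sum(a$nH) * ATOMIC_WEIGHTS[["H"]]
}

#' Assemble the full descriptor vector of a molecule
#'
#' Computes the five activity-model descriptors (molar polarizability,
#' logP, TPSA, H-bond acceptor count, Balaban J) plus HBD, heavy-atom
#' count and molecular weight. The vector is complete for any
#' successfully parsed connected molecule; component errors propagate
#' with the compound id attached.
#'
#' @param mol a [Molecule-class].
#' @return a one-row data.frame with columns \code{id},
#'   \code{mol_polarizability}, \code{logp}, \code{tpsa}, \code{hba},
#'   \code{hbd}, \code{balaban_j}, \code{ha}, \code{mw}.
#' @export
descriptorVector <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  res <- tryCatch(
    data.frame(
      id = mol@id,
      mol_polarizability = molarPolarizability(mol),
      logp = clogp(mol),
      tpsa = tpsa(mol),
      hba = hbaCount(mol),
      hbd = hbdCount(mol),
      balaban_j = balabanIndex(mol),
      ha = heavyAtomCount(mol),
      mw = molecularWeight(mol),
      stringsAsFactors = FALSE
    ),
    error = function(e) {
      stop(sprintf("descriptor computation failed for compound '%s': %s",
                   mol@id, conditionMessage(e)), call. = FALSE)
    }
  )
  res
}

#' Descriptor table for a list of molecules
#'
#' @param mols list of [Molecule-class] objects.
#' @return data.frame with one [descriptorVector()] row per molecule.
#' @export
descriptorTable <- function(mols) {
  stopifnot(is.list(mols))
  if (!length(mols)) {
    return(descriptorVector(parseSmiles("C"))[0, , drop = FALSE])
  }
  do.call(rbind, lapply(mols, descriptorVector))
}

#' Write a descriptor table as CSV
#'
#' Fixed column order (id, mol_polarizability, logp, tpsa, hba, hbd,
#' balaban_j, ha, mw); numeric columns optionally rounded to two
#' decimals for report-style output.
#'
#' @param tab data.frame from [descriptorTable()].
#' @param path output file.
#' @param round2 logical; round numeric columns to 2 decimals.
#' @return invisibly, the path.
#' @export
writeDescriptorCSV <- function(tab, path, round2 = FALSE) {
  cols <- c("id", "mol_polarizability", "logp", "tpsa", "hba", "hbd",
            "balaban_j", "ha", "mw")
  tab <- tab[, cols, drop = FALSE]
  if (round2) {
    for (cn in setdiff(cols, "id")) tab[[cn]] <- round2dp(tab[[cn]])
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
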