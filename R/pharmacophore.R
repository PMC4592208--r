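# 2D feature-count pharmacophore surrogate: rule-based feature
# perception, merged shared-feature model over training actives, and
# query-fit ranking of library molecules.
#
# This is a deliberately topological stand-in for 3D pharmacophore
# alignment: features are counted, not placed in space, so the model is
# a multiset of required feature counts and the fit score is the
# fraction of requirements a molecule satisfies.

FEATURE_KINDS <- c("HBD", "HBA", "aromatic_ring", "hydrophobic",
                   "pos_ionizable", "neg_ionizable")

#' Load the versioned pharmacophore perception rules
#'
#' @param path YAML rule file; defaults to the package's shipped
#'   \code{pharmacophore_rules.yaml}.
#' @return named list of rule settings.
#' @export
pharmacophoreRules <- function(path = system.file("extdata",
                                                  "pharmacophore_rules.yaml",
                                                  package = "hdacScreen")) {
  if (!nzchar(path) || !file.exists(path)) stop("rule file not found")
  yaml::read_yaml(path)
}

# neighbours of each atom together with element/context lookups
.neighbourIdx <- function(mol) {
  adj <- .adjList(mol)
  lapply(seq_len(nrow(mol@atoms)), function(i) {
    if (i <= length(adj) && !is.null(adj[[i]])) adj[[i]] else integer(0)
  })
}

#' Perceive 2D pharmacophore features of a molecule
#'
#' Rule-based perception over the annotated graph:
#' \itemize{
#'   \item HBD: N/O atoms bearing at least one hydrogen.
#'   \item HBA: N/O atoms without positive formal charge.
#'   \item aromatic_ring: independent rings of the aromatic-bond
#'     subgraph (one feature per ring; ring count per connected
#'     aromatic component is its cyclomatic number).
#'   \item hydrophobic: maximal carbon-only connected subgraphs of at
#'     least \code{min_atoms} atoms none of which neighbours a charged
#'     atom.
#'   \item neg_ionizable: carboxylic/sulfonic acid groups and
#'     sulfonamide N-H.
#'   \item pos_ionizable: non-amide, non-sulfonamide aliphatic amines
#'     (or any positively charged N).
#' }
#' Rule families are toggled by the versioned config
#' (\code{pharmacophore_rules.yaml}).
#'
#' @param mol a [Molecule-class].
#' @param rules rule list from [pharmacophoreRules()].
#' @return data.frame with columns \code{kind} and \code{atoms}
#'   (list-column of atom index vectors), zero rows if featureless.
#' @export
perceiveFeatures <- function(mol, rules = pharmacophoreRules()) {
  stopifnot(is(mol, "Molecule"))
  a <- mol@atoms
  n <- nrow(a)
  ctx <- .bondContext(mol)
  nbrs <- .neighbourIdx(mol)
  feats_kind <- character(0)
  feats_atoms <- list()
  add <- function(kind, atoms) {
    feats_kind[length(feats_kind) + 1L] <<- kind
    feats_atoms[[length(feats_atoms) + 1L]] <<- as.integer(atoms)
  }
  fr <- rules$features
  on <- function(kind) isTRUE(fr[[kind]]$enabled)

  is_NO <- a$element %in% c("N", "O")
  if (on("HBD")) {
    for (i in which(is_NO & a$nH >= 1L)) add("HBD", i)
  }
  if (on("HBA")) {
    for (i in which(is_NO & a$charge <= 0L)) add("HBA", i)
  }

  if (on("aromatic_ring") && any(a$aromatic)) {
    arb <- mol@bonds[mol@bonds$order == "ar", , drop = FALSE]
    if (nrow(arb)) {
      sub_atoms <- sort(unique(c(arb$i, arb$j)))
      remap <- match(seq_len(n), sub_atoms)
      comp <- .components(length(sub_atoms),
                          data.frame(i = remap[arb$i], j = remap[arb$j]))
      for (cid in seq_len(max(comp))) {
        atoms_c <- sub_atoms[comp == cid]
        edges_c <- sum(comp[remap[arb$i]] == cid)
        nrings <- edges_c - length(atoms_c) + 1L
        if (nrings >= 1L) {
          for (r in seq_len(nrings)) add("aromatic_ring", atoms_c)
        }
      }
    }
  }

  if (on("hydrophobic")) {
    min_atoms <- fr$hydrophobic$min_atoms
    if (is.null(min_atoms)) min_atoms <- 3L
    charged <- which(a$charge != 0L)
    ok_c <- which(a$element == "C" &
                    !vapply(nbrs, function(nb) any(nb %in% charged),
                            logical(1)))
    if (length(ok_c)) {
      remap <- match(seq_len(n), ok_c)
      bsub <- mol@bonds[mol@bonds$i %in% ok_c & mol@bonds$j %in% ok_c, ,
                        drop = FALSE]
      comp <- .components(length(ok_c),
                          data.frame(i = remap[bsub$i], j = remap[bsub$j]))
      for (cid in seq_len(max(comp))) {
        atoms_c <- ok_c[comp == cid]
        if (length(atoms_c) >= min_atoms) add("hydrophobic", atoms_c)
      }
    }
  }

  sulfonyl_S <- which(a$element == "S" & ctx$d >= 2L & ctx$dbl_to_O)
  if (on("neg_ionizable")) {
    pats <- unlist(fr$neg_ionizable$patterns)
    if ("carboxylic_acid" %in% pats) {
      single_bond <- function(i, x) {
        any(mol@bonds$order == "1" &
              pmin(mol@bonds$i, mol@bonds$j) == min(i, x) &
              pmax(mol@bonds$i, mol@bonds$j) == max(i, x))
      }
      for (i in which(a$element == "C" & ctx$dbl_to_O & !a$aromatic)) {
        nb <- nbrs[[i]]
        o_acid <- nb[a$element[nb] == "O" &
                       (a$nH[nb] >= 1L | a$charge[nb] < 0L) &
                       vapply(nb, single_bond, logical(1), i = i)]
        if (length(o_acid)) add("neg_ionizable", c(i, o_acid[1]))
      }
    }
    if ("sulfonic_acid" %in% pats) {
      for (s in sulfonyl_S) {
        oh <- nbrs[[s]][a$element[nbrs[[s]]] == "O" &
                          (a$nH[nbrs[[s]]] >= 1L | a$charge[nbrs[[s]]] < 0L)]
        if (length(oh)) add("neg_ionizable", c(s, oh[1]))
      }
    }
    if ("sulfonamide_nh" %in% pats) {
      for (s in sulfonyl_S) {
        nh <- nbrs[[s]][a$element[nbrs[[s]]] == "N" & a$nH[nbrs[[s]]] >= 1L]
        for (nn in nh) add("neg_ionizable", c(s, nn))
      }
    }
  }

  if (on("pos_ionizable")) {
    for (i in which(a$element == "N" & !a$aromatic)) {
      if (a$charge[i] > 0L) { add("pos_ionizable", i); next }
      if (ctx$d[i] > 0L || ctx$t[i] > 0L) next
      nb <- nbrs[[i]]
      if (ctx$nbr_carbonyl[i]) next              # amide-type
      if (any(nb %in% sulfonyl_S)) next          # sulfonamide N
      add("pos_ionizable", i)
    }
  }

  data.frame(kind = feats_kind,
             atoms = I(feats_atoms),
             stringsAsFactors = FALSE)
}

#' Feature counts per kind
#'
#' @param mol a [Molecule-class].
#' @param rules rule list from [pharmacophoreRules()].
#' @return named integer vector over all feature kinds.
#' @export
featureCounts <- function(mol, rules = pharmacophoreRules()) {
  f <- perceiveFeatures(mol, rules)
  counts <- stats::setNames(integer(length(FEATURE_KINDS)), FEATURE_KINDS)
  if (nrow(f)) {
    tb <- table(factor(f$kind, levels = FEATURE_KINDS))
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

#' Merge a shared-feature pharmacophore model from training actives
#'
#' For each feature kind, the required count is the largest count
#' supported by at least a fraction \code{f} of the training molecules
#' (\code{f = 1} reduces to the per-kind minimum, i.e. the intersection
#' of feature multisets). Raising \code{f} never increases a required
#' count.
#'
#' @param training list of at least two [Molecule-class] objects.
#' @param f consensus fraction in (0, 1]; default 1.
#' @param rules perception rules.
#' @return a [PharmacophoreModel-class].
#' @export
mergeFeatureModel <- function(training, f = 1.0,
                              rules = pharmacophoreRules()) {
  stopifnot(is.list(training), length(training) >= 2L, f > 0, f <= 1)
  counts <- t(vapply(training, featureCounts, integer(length(FEATURE_KINDS)),
                     rules = rules))
  m <- nrow(counts)
  support_needed <- as.integer(ceiling(f * m))
  required <- apply(counts, 2, function(col) {
    sorted <- sort(col, decreasing = TRUE)
    sorted[support_needed]
  })
  required <- stats::setNames(as.integer(required), FEATURE_KINDS)
  if (sum(required) < 1L) {
    stop("empty consensus: no feature kind is shared by a fraction f = ", f,
         " of the training set; lower f")
  }
  new("PharmacophoreModel",
      required = required,
      training_ids = vapply(training, function(m) m@id, character(1)),
      consensus_fraction = f)
}

#' Query fit of a molecule against a pharmacophore model
#'
#' \deqn{fit = \sum_k \min(c_k, r_k) / \sum_k r_k}
#' over feature kinds with required count \eqn{r_k > 0}; 1 iff every
#' requirement is met, 0 for a featureless molecule.
#'
#' @param model a [PharmacophoreModel-class].
#' @param mol a [Molecule-class].
#' @param rules perception rules.
#' @return score in [0, 1].
#' @export
queryFit <- function(model, mol, rules = pharmacophoreRules()) {
  stopifnot(is(model, "PharmacophoreModel"))
  validObject(model)
  counts <- featureCounts(mol, rules)
  req <- model@required
  sum(pmin(counts, req)) / sum(req)
}

#' Screen a molecule library against a pharmacophore model
#'
#' Scores every library molecule with [queryFit()], drops entries below
#' \code{min_fit}, and returns the survivors ranked by descending fit
#' (ties keep input order).
#'
#' @param model a [PharmacophoreModel-class].
#' @param library non-empty list of [Molecule-class] objects.
#' @param min_fit retention threshold in [0, 1] (default 0: keep all).
#' @param rules perception rules.
#' @return data.frame with columns \code{id}, \code{query_fit}, ranked.
#' @export
screenLibrary <- function(model, library, min_fit = 0,
                          rules = pharmacophoreRules()) {
  stopifnot(is.list(library), length(library) >= 1L)
  fits <- vapply(library, function(m) queryFit(model, m, rules), numeric(1))
  ids <- vapply(library, function(m) m@id, character(1))
  keep <- fits >= min_fit
  out <- data.frame(id = ids[keep], query_fit = fits[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$query_fit, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a pharmacophore model as plain structured text
#'
#' @param model a [PharmacophoreModel-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePharmacophoreModel <- function(model, path) {
  lines <- c(
    sprintf("consensus_fraction\t%.17g", model@consensus_fraction),
    sprintf("training_ids\t%s", paste(model@training_ids, collapse = ",")),
    vapply(names(model@required), function(k)
      sprintf("required.%s\t%d", k, model@required[[k]]), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a pharmacophore model written by [writePharmacophoreModel()]
#'
#' @param path serialized model file.
#' @return a [PharmacophoreModel-class].
#' @export
readPharmacophoreModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  req <- stats::setNames(integer(length(FEATURE_KINDS)), FEATURE_KINDS)
  for (k in FEATURE_KINDS) {
    sel <- keys == paste0("required.", k)
    if (any(sel)) req[k] <- as.integer(vals[sel][1])
  }
  new("PharmacophoreModel",
      required = req,
      training_ids = strsplit(vals[keys == "training_ids"][1], ",")[[1]],
      consensus_fraction = as.numeric(vals[keys == "consensus_fraction"][1]))
}
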