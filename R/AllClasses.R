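#' @import methods
#' @importFrom stats lm pf rnorm rbinom setNames coef residuals pf sd
#' @importFrom utils read.csv write.csv head packageVersion
#' @importFrom yaml read_yaml
NULL

#' Molecule: an annotated hydrogen-suppressed molecular graph
#'
#' Central container for a small molecule as a 2D topological graph.
#' Atoms are the non-hydrogen atoms of the structure; attached hydrogens
#' are stored as a per-atom count (resolved at parse time from implicit
#' valence rules or explicit bracket counts).
#'
#' @slot id character label for the compound.
#' @slot atoms data.frame with one row per heavy atom and columns
#'   \code{element} (symbol), \code{charge} (integer formal charge, e),
#'   \code{aromatic} (logical), \code{nH} (attached hydrogen count).
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, \code{i < j}) and \code{order} (one of \code{"1"},
#'   \code{"2"}, \code{"3"}, \code{"ar"}).
#' @slot source character; the originating SMILES string or SDF record
#'   reference.
#'
#' @seealso [readMolecules()], [parseSmiles()], [heavyAtomCount()]
#' @export
setClass("Molecule",
  representation(
    id = "character",
    atoms = "data.frame",
    bonds = "data.frame",
    source = "character"
  )
)

setValidity("Molecule", function(object) {
  msgs <- character()
  a <- object@atoms
  b <- object@bonds
  need_a <- c("element", "charge", "aromatic", "nH")
  need_b <- c("i", "j", "order")
  if (!all(need_a %in% names(a))) {
    return(paste("atoms must have columns", paste(need_a, collapse = ", ")))
  }
  if (!all(need_b %in% names(b))) {
    return(paste("bonds must have columns", paste(need_b, collapse = ", ")))
  }
  if (nrow(a) == 0L) msgs <- c(msgs, "molecule has no heavy atoms")
  if ("H" %in% a$element) {
    msgs <- c(msgs, "hydrogen-suppressed graph must not contain H atoms")
  }
  bad <- !a$element %in% SUPPORTED_ELEMENTS
  if (any(bad)) {
    msgs <- c(msgs, paste0("unsupported element(s): ",
                           paste(unique(a$element[bad]), collapse = ", ")))
  }
  if (nrow(b) > 0L) {
    if (any(b$i < 1L | b$j < 1L | b$i > nrow(a) | b$j > nrow(a))) {
      msgs <- c(msgs, "bond endpoint out of range")
    }
    if (any(b$i == b$j)) msgs <- c(msgs, "self-bond (i == j) not allowed")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond")
    if (!all(b$order %in% c("1", "2", "3", "ar"))) {
      msgs <- c(msgs, "bond order must be one of 1, 2, 3, ar")
    }
  }
  if (any(a$nH < 0L)) msgs <- c(msgs, "negative hydrogen count")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn Molecule compact one-line display
#' @param object a \code{Molecule}
#' @export
setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d heavy atoms, %d bonds (%d aromatic atoms)\n",
              object@id, nrow(object@atoms), nrow(object@bonds),
              sum(object@atoms$aromatic)))
  cat("  source:", object@source, "\n")
})

#' QSARModel: a fitted or frozen multiple-linear-regression activity model
#'
#' Holds an intercept plus per-descriptor coefficients (with standard
#' errors) mapping a descriptor vector to pIC50, together with the usual
#' goodness-of-fit statistics.
#'
#' @slot coefficients named numeric; first element \code{"(Intercept)"}.
#' @slot se named numeric standard errors, same layout as coefficients.
#' @slot n integer training-set size.
#' @slot r2,adj_r2 numeric; coefficient of determination and its
#'   degrees-of-freedom-adjusted form.
#' @slot see numeric standard error of the estimate (residual SD).
#' @slot f_stat numeric overall regression F statistic.
#' @slot p_value numeric p-value of the overall F test.
#' @slot residuals numeric per-training-compound residuals (may be
#'   length 0 for a frozen literature model).
#'
#' @seealso [fitMLR()], [publishedModel()], [predictPic50()]
#' @export
setClass("QSARModel",
  representation(
    coefficients = "numeric",
    se = "numeric",
    n = "integer",
    r2 = "numeric",
    adj_r2 = "numeric",
    see = "numeric",
    f_stat = "numeric",
    p_value = "numeric",
    residuals = "numeric"
  )
)

setValidity("QSARModel", function(object) {
  msgs <- character()
  if (is.null(names(object@coefficients)) ||
      names(object@coefficients)[1] != "(Intercept)") {
    msgs <- c(msgs, "coefficients must be named, intercept first")
  }
  if (length(object@se) != length(object@coefficients)) {
    msgs <- c(msgs, "se and coefficients must align")
  }
  if (!is.na(object@r2) && (object@r2 < -1e-9 || object@r2 > 1 + 1e-9)) {
    msgs <- c(msgs, "r2 outside [0, 1]")
  }
  if (!is.na(object@r2) && !is.na(object@adj_r2) &&
      object@adj_r2 > object@r2 + 1e-9) {
    msgs <- c(msgs, "adjusted r2 exceeds r2")
  }
  if (!is.na(object@see) && object@see < 0) msgs <- c(msgs, "see < 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn QSARModel display the model equation and fit statistics
#' @param object a \code{QSARModel}
#' @export
setMethod("show", "QSARModel", function(object) {
  co <- object@coefficients
  terms <- sprintf("%+.4g*%s", co[-1], names(co)[-1])
  cat("QSARModel: pIC50 =", sprintf("%.4g", co[1]),
      paste(terms, collapse = " "), "\n")
  cat(sprintf("  n = %d, R2 = %.3g, adj R2 = %.3g, SEE = %.3g, F = %.3g, p = %.3g\n",
              object@n, object@r2, object@adj_r2, object@see,
              object@f_stat, object@p_value))
})

#' ScreenCounts: raw counts from an active/decoy screening experiment
#'
#' @slot D integer; total compounds in the dataset.
#' @slot A integer; known actives in the dataset.
#' @slot Ht integer; total hits retrieved by the screen.
#' @slot Ha integer; actives among the hits.
#'
#' @seealso [tallyScreen()], [screenMetrics()]
#' @export
setClass("ScreenCounts",
  representation(D = "integer", A = "integer", Ht = "integer", Ha = "integer")
)

setValidity("ScreenCounts", function(object) {
  D <- object@D; A <- object@A; Ht <- object@Ht; Ha <- object@Ha
  msgs <- character()
  if (any(c(D, A, Ht, Ha) < 0L)) msgs <- c(msgs, "counts must be non-negative")
  if (A > D) msgs <- c(msgs, "A > D")
  if (Ht > D) msgs <- c(msgs, "Ht > D")
  if (Ha > min(Ht, A)) msgs <- c(msgs, "Ha > min(Ht, A)")
  if ((D - A) - (Ht - Ha) < 0L) msgs <- c(msgs, "implied true negatives < 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn ScreenCounts display counts and the implied confusion cells
#' @param object a \code{ScreenCounts}
#' @export
setMethod("show", "ScreenCounts", function(object) {
  cat(sprintf("ScreenCounts: D = %d, A = %d, Ht = %d, Ha = %d (TN = %d)\n",
              object@D, object@A, object@Ht, object@Ha,
              (object@D - object@A) - (object@Ht - object@Ha)))
})

#' ScreenMetrics: derived validation statistics of a screen
#'
#' Undefined ratios (e.g. percent yield with zero hits) are stored as
#' \code{NA} and flagged in \code{undefined}, never as silent \code{NaN}.
#'
#' @slot sensitivity,specificity fractions in [0, 1].
#' @slot percent_yield percent of retrieved hits that are active.
#' @slot enrichment_factor unitless enrichment over the base active rate.
#' @slot gh_score Guner-Henry composite in [0, 1].
#' @slot undefined character vector naming metrics that were undefined.
#'
#' @seealso [screenMetrics()]
#' @export
setClass("ScreenMetrics",
  representation(
    sensitivity = "numeric", specificity = "numeric",
    percent_yield = "numeric", enrichment_factor = "numeric",
    gh_score = "numeric", undefined = "character"
  )
)

#' @describeIn ScreenMetrics one-line metric display
#' @param object a \code{ScreenMetrics}
#' @export
setMethod("show", "ScreenMetrics", function(object) {
  cat(sprintf(
    "ScreenMetrics: sens = %.3f, spec = %.3f, %%Y = %.1f, EF = %.3f, GH = %.3f\n",
    object@sensitivity, object@specificity, object@percent_yield,
    object@enrichment_factor, object@gh_score))
  if (length(object@undefined)) {
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
  }
})

#' PharmacophoreModel: shared-feature requirements learned from actives
#'
#' A 2D surrogate of a merged-feature pharmacophore: for each feature
#' kind, the number of occurrences a molecule must present to fully fit
#' the model.
#'
#' @slot required named integer vector of required counts per feature
#'   kind (names from the supported kind set).
#' @slot training_ids character; compound ids the model was merged from.
#' @slot consensus_fraction numeric in (0, 1]; fraction of training
#'   molecules that must support a count for it to be required.
#'
#' @seealso [mergeFeatureModel()], [queryFit()], [screenLibrary()]
#' @export
setClass("PharmacophoreModel",
  representation(
    required = "integer",
    training_ids = "character",
    consensus_fraction = "numeric"
  )
)

setValidity("PharmacophoreModel", function(object) {
  msgs <- character()
  if (any(object@required < 0L)) msgs <- c(msgs, "negative required count")
  if (sum(object@required) < 1L) {
    msgs <- c(msgs, "model must require at least one feature")
  }
  if (object@consensus_fraction <= 0 || object@consensus_fraction > 1) {
    msgs <- c(msgs, "consensus_fraction must lie in (0, 1]")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn PharmacophoreModel display required feature counts
#' @param object a \code{PharmacophoreModel}
#' @export
setMethod("show", "PharmacophoreModel", function(object) {
  req <- object@required[object@required > 0L]
  cat("PharmacophoreModel (f =", object@consensus_fraction, "):",
      paste(sprintf("%s x%d", names(req), req), collapse = ", "), "\n")
  cat("  trained on", length(object@training_ids), "molecules\n")
})
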