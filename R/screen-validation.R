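# Active/decoy screen validation statistics (Guner-Henry suite).

#' Tally screening counts from labels and a hit set
#'
#' @param labels named character vector or data.frame (columns
#'   \code{compound_id}, \code{label}) mapping every library compound to
#'   \code{"active"} or \code{"decoy"}.
#' @param hits character vector of retrieved compound ids; every id must
#'   appear in \code{labels}.
#' @return a [ScreenCounts-class] with D (library size), A (actives),
#'   Ht (hits), Ha (active hits).
#' @export
tallyScreen <- function(labels, hits) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("compound_id", "label") %in% names(labels)))
    labels <- stats::setNames(labels$label, labels$compound_id)
  }
  if (!all(labels %in% c("active", "decoy"))) {
    stop("labels must be 'active' or 'decoy'")
  }
  hits <- unique(as.character(hits))
  unknown <- setdiff(hits, names(labels))
  if (length(unknown)) {
    stop("hit id(s) not present in labels: ", paste(unknown, collapse = ", "))
  }
  new("ScreenCounts",
      D = length(labels),
      A = sum(labels == "active"),
      Ht = length(hits),
      Ha = sum(labels[hits] == "active"))
}

#' Screen validation metrics from counts
#'
#' With D compounds, A actives, Ht hits and Ha active hits
#' (TN = (D-A) - (Ht-Ha)):
#' \itemize{
#'   \item sensitivity = Ha/A
#'   \item specificity = TN/(D-A)
#'   \item percent yield \%Y = 100 Ha/Ht
#'   \item enrichment factor EF = (Ha/Ht)/(A/D)
#'   \item Guner-Henry score GH = [Ha(3A+Ht)/(4 Ht A)] [1 - (Ht-Ha)/(D-A)]
#' }
#' Division-by-zero cases (A = 0, Ht = 0, or A = D for specificity) are
#' reported as \code{NA} and named in the \code{undefined} slot.
#'
#' @param counts a [ScreenCounts-class].
#' @return a [ScreenMetrics-class].
#' @export
screenMetrics <- function(counts) {
  stopifnot(is(counts, "ScreenCounts"))
  validObject(counts)
  D <- counts@D; A <- counts@A; Ht <- counts@Ht; Ha <- counts@Ha
  undef <- character(0)
  sens <- if (A > 0L) Ha / A else { undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if (D - A > 0L) ((D - A) - (Ht - Ha)) / (D - A) else {
    undef <- c(undef, "specificity"); NA_real_
  }
  py <- if (Ht > 0L) 100 * Ha / Ht else {
    undef <- c(undef, "percent_yield"); NA_real_
  }
  ef <- if (Ht > 0L && A > 0L && D > 0L) (Ha / Ht) / (A / D) else {
    undef <- c(undef, "enrichment_factor"); NA_real_
  }
  gh <- if (Ht > 0L && A > 0L && D - A > 0L) {
    (Ha * (3 * A + Ht) / (4 * Ht * A)) * (1 - (Ht - Ha) / (D - A))
  } else { undef <- c(undef, "gh_score"); NA_real_ }
  new("ScreenMetrics", sensitivity = sens, specificity = spec,
      percent_yield = py, enrichment_factor = ef, gh_score = gh,
      undefined = undef)
}

#' Screen metrics as a one-row data.frame
#'
#' Convenience accessor for CSV emission.
#'
#' @param metrics a [ScreenMetrics-class].
#' @return one-row data.frame.
#' @export
metricsAsRow <- function(metrics) {
  stopifnot(is(metrics, "ScreenMetrics"))
  data.frame(sensitivity = metrics@sensitivity,
             specificity = metrics@specificity,
             percent_yield = metrics@percent_yield,
             enrichment_factor = metrics@enrichment_factor,
             gh_score = metrics@gh_score)
}

#' Read an active/decoy label CSV
#'
#' Columns \code{compound_id}, \code{label}.
#'
#' @param path CSV file.
#' @return named character vector of labels.
#' @export
readLabels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "label") %in% names(tab)))
  stats::setNames(tab$label, tab$compound_id)
}
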