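# Ligand-efficiency prioritization suite: LE, LEScale, LipE, FQ,
# optimality flags and Rule-of-Five filtering.

#' Round half away from zero at 2 decimals
#'
#' Report-style rounding used throughout the efficiency tables (avoids
#' IEEE round-half-to-even surprises on printed values).
#'
#' @param x numeric.
#' @return x rounded to 2 decimal places, halves away from zero.
#' @export
round2dp <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5) / 100
}

#' Ligand efficiency
#'
#' \deqn{LE = (1.37 / HA) \cdot pIC50}
#' in pIC50 units per heavy atom (the 1.37 factor converts to the
#' conventional kcal/mol-per-atom scale at 300 K, neutral pH, 1 M
#' standard state).
#'
#' @param pic50 activity.
#' @param ha heavy-atom count, >= 1.
#' @return LE at full precision (reports round to 2 decimals).
#' @export
#' @examples
#' round2dp(ligandEfficiency(12.5, 26))  # 0.66
ligandEfficiency <- function(pic50, ha) {
  if (any(ha < 1)) stop("heavy-atom count must be >= 1")
  (1.37 / ha) * pic50
}

#' Lipophilic efficiency
#'
#' \deqn{LipE = pIC50 - clogP}
#'
#' @param pic50 activity.
#' @param clogp calculated logP.
#' @return LipE in pIC50 units.
#' @export
lipophilicEfficiency <- function(pic50, clogp) {
  pic50 - clogp
}

#' Size-dependent ligand-efficiency scale
#'
#' \deqn{LEScale = 0.104 + 0.65\, e^{-0.037\, HA}}
#' the empirical maximal-LE reference curve; decreases monotonically
#' with heavy-atom count towards the 0.104 asymptote.
#'
#' @param ha heavy-atom count, >= 1.
#' @return LEScale at full precision.
#' @export
#' @examples
#' round2dp(leScale(25))  # 0.36
leScale <- function(ha) {
  if (any(ha < 1)) stop("heavy-atom count must be >= 1")
  0.104 + 0.65 * exp(-0.037 * ha)
}

#' Fit quality
#'
#' \deqn{FQ = LE / LEScale}
#' In reproduction mode (default) the inputs are first rounded to two
#' decimals and the ratio is rounded again, matching how published
#' tables are assembled from their printed intermediates; full-precision
#' mode divides the raw values.
#'
#' @param le ligand efficiency.
#' @param le_scale the size-dependent scale; must be positive.
#' @param mode \code{"reproduction"} (rounded intermediates and result)
#'   or \code{"full"} (raw ratio).
#' @return FQ.
#' @export
#' @examples
#' fitQuality(0.66, 0.35)  # 1.89
fitQuality <- function(le, le_scale, mode = c("reproduction", "full")) {
  mode <- match.arg(mode)
  if (any(le_scale <= 0)) stop("le_scale must be positive")
  if (mode == "reproduction") {
    round2dp(round2dp(le) / round2dp(le_scale))
  } else {
    le / le_scale
  }
}

#' Ligand-efficiency profile table
#'
#' Builds the full prioritization report from per-compound (id, pIC50,
#' HA, clogP) inputs: LE, LEScale, LipE and FQ plus optimality flags
#' (\code{clogp_lt_3}, \code{lipe_gt_5}, \code{fq_near_1}) and, when a
#' descriptor table is supplied, the Rule-of-Five verdict. A summary
#' attribute counts compounds with LipE > 5. Rows that fail their
#' preconditions are collected as errors while good rows are still
#' emitted.
#'
#' @param compounds data.frame with columns \code{id}, \code{pic50},
#'   \code{ha}, \code{clogp}. Supplied clogP values are authoritative
#'   (they override any computed estimate upstream).
#' @param fq_mode passed to [fitQuality()].
#' @param fq_tol half-width of the "FQ close to 1" band (default 0.25).
#' @param descriptors optional data.frame (columns \code{id}, \code{mw},
#'   \code{hbd}, \code{hba}, and \code{logp} if clogp is absent) used
#'   for the \code{rof_pass} flag.
#' @return data.frame with columns id, pic50, ha, clogp, le, le_scale,
#'   lipe, fq, clogp_lt_3, lipe_gt_5, fq_near_1, rof_pass; attributes
#'   \code{n_lipe_gt_5} and \code{row_errors}.
#' @export
efficiencyTable <- function(compounds, fq_mode = c("reproduction", "full"),
                            fq_tol = 0.25, descriptors = NULL) {
  fq_mode <- match.arg(fq_mode)
  stopifnot(is.data.frame(compounds),
            all(c("id", "pic50", "ha", "clogp") %in% names(compounds)))
  rows <- list()
  errors <- character(0)
  for (k in seq_len(nrow(compounds))) {
    row <- compounds[k, ]
    res <- tryCatch({
      le <- ligandEfficiency(row$pic50, row$ha)
      ls <- leScale(row$ha)
      lipe <- lipophilicEfficiency(row$pic50, row$clogp)
      fq <- fitQuality(le, ls, mode = fq_mode)
      if (fq_mode == "reproduction") {
        le <- round2dp(le); ls <- round2dp(ls); lipe <- round2dp(lipe)
      }
      rof <- NA
      if (!is.null(descriptors) && row$id %in% descriptors$id) {
        dv <- descriptors[match(row$id, descriptors$id), ]
        if (!"logp" %in% names(dv)) dv$logp <- row$clogp
        rof <- ruleOfFive(dv)$pass
      }
      data.frame(id = row$id, pic50 = row$pic50, ha = row$ha,
                 clogp = row$clogp, le = le, le_scale = ls, lipe = lipe,
                 fq = fq,
                 clogp_lt_3 = row$clogp < 3,
                 lipe_gt_5 = lipe > 5,
                 fq_near_1 = abs(fq - 1) <= fq_tol,
                 rof_pass = rof,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      errors <<- c(errors, sprintf("row %d (id %s): %s", k,
                                   as.character(row$id),
                                   conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), pic50 = numeric(), ha = numeric(),
               clogp = numeric(), le = numeric(), le_scale = numeric(),
               lipe = numeric(), fq = numeric(), clogp_lt_3 = logical(),
               lipe_gt_5 = logical(), fq_near_1 = logical(),
               rof_pass = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_lipe_gt_5") <- sum(out$lipe_gt_5)
  attr(out, "row_errors") <- errors
  out
}

#' Self-check a printed efficiency table against the equations
#'
#' Recomputes LE, LEScale, LipE and FQ from the (pIC50, HA, clogP)
#' columns of a published-style table and reports, per cell, whether the
#' printed value matches the equation at 2-decimal reproduction
#' rounding. Useful for spotting transcription errata in literature
#' tables.
#'
#' @param printed data.frame with columns id, pic50, ha, clogp, le,
#'   le_scale, lipe, fq (the printed values).
#' @return data.frame of logical match columns \code{le_ok},
#'   \code{le_scale_ok}, \code{lipe_ok}, \code{fq_ok} plus
#'   \code{fq_from_printed_ok} (FQ recomputed from the *printed*
#'   LE/LEScale columns).
#' @export
checkEfficiencyTable <- function(printed) {
  need <- c("id", "pic50", "ha", "clogp", "le", "le_scale", "lipe", "fq")
  stopifnot(all(need %in% names(printed)))
  comp <- efficiencyTable(printed[, c("id", "pic50", "ha", "clogp")])
  data.frame(
    id = printed$id,
    le_ok = comp$le == round2dp(printed$le),
    le_scale_ok = comp$le_scale == round2dp(printed$le_scale),
    lipe_ok = comp$lipe == round2dp(printed$lipe),
    fq_ok = comp$fq == round2dp(printed$fq),
    fq_from_printed_ok =
      fitQuality(printed$le, printed$le_scale) == round2dp(printed$fq),
    stringsAsFactors = FALSE
  )
}

#' Rule-of-Five drug-likeness filter
#'
#' Pass iff MW <= 500, clogP <= 5, HBD <= 5 and HBA <= 10
#' (zero-violation convention by default; set \code{max_violations} to
#' relax).
#'
#' @param d a descriptor vector: named list / one-row data.frame with
#'   \code{mw}, \code{logp}, \code{hbd}, \code{hba}.
#' @param max_violations violations tolerated while still passing
#'   (default 0).
#' @return list with \code{pass} (logical), \code{violations}
#'   (character vector naming failed criteria) and \code{detail}
#'   (named logical vector of per-criterion passes).
#' @export
ruleOfFive <- function(d, max_violations = 0L) {
  d <- as.list(d)
  need <- c("mw", "logp", "hbd", "hba")
  if (!all(need %in% names(d))) {
    stop("descriptor vector must provide: ", paste(need, collapse = ", "))
  }
  detail <- c(mw = d$mw <= 500, logp = d$logp <= 5,
              hbd = d$hbd <= 5, hba = d$hba <= 10)
  violations <- names(detail)[!detail]
  list(pass = length(violations) <= max_violations,
       violations = violations,
       detail = detail)
}
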