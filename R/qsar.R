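# Activity handling and multiple-linear-regression machinery for
# descriptor -> pIC50 models, including the frozen published model and
# classical forward/backward/stepwise descriptor selection.

#' Convert IC50 (nM) to pIC50
#'
#' Molar-based convention: \code{pIC50 = 9 - log10(IC50/nM)}, so 1 nM
#' maps to 9.0 and 1000 nM to 6.0.
#'
#' @param ic50 IC50 in nanomolar; must be positive.
#' @return pIC50 (vectorised).
#' @export
pic50FromIC50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 must be positive and finite (nM)")
  }
  9 - log10(ic50)
}

#' Convert pIC50 back to IC50 (nM)
#'
#' Inverse of [pic50FromIC50()]: \code{IC50 = 10^(9 - pIC50)}.
#'
#' @param pic50 pIC50 value(s).
#' @return IC50 in nM.
#' @export
ic50FromPic50 <- function(pic50) {
  10^(9 - pic50)
}

#' Average per-isoform pIC50 values of one compound
#'
#' Activities are converted isoform-by-isoform before averaging
#' (arithmetic mean of pIC50, i.e. geometric-mean behaviour on IC50).
#'
#' @param records data.frame with columns \code{compound_id} and
#'   \code{ic50_nM} (an \code{isoform} column may be present); all rows
#'   must belong to a single compound.
#' @return the mean pIC50.
#' @export
meanPic50 <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("compound_id", "ic50_nM") %in% names(records)))
  if (nrow(records) < 1L) stop("no activity records")
  if (length(unique(records$compound_id)) != 1L) {
    stop("meanPic50 expects records for a single compound; got: ",
         paste(unique(records$compound_id), collapse = ", "))
  }
  mean(pic50FromIC50(records$ic50_nM))
}

#' Classify a compound as active or decoy by its IC50
#'
#' Compounds with \code{IC50 < threshold} are active; at or above the
#' threshold they are decoys (the boundary resolves to decoy).
#'
#' @param ic50 IC50 in nM (vectorised); must be positive.
#' @param threshold activity cutoff in nM (default 2500).
#' @return character vector of \code{"active"} / \code{"decoy"}.
#' @export
classifyActivity <- function(ic50, threshold = 2500) {
  if (any(ic50 <= 0)) stop("IC50 must be positive (nM)")
  ifelse(ic50 < threshold, "active", "decoy")
}

#' Read an activity table
#'
#' CSV with columns \code{compound_id}, \code{isoform}, \code{ic50_nM};
#' a \code{pic50} column is derived.
#'
#' @param path CSV file.
#' @return data.frame with the derived \code{pic50} column appended.
#' @export
readActivities <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "ic50_nM")
  if (!all(need %in% names(tab))) {
    stop("activity CSV must have columns: ", paste(need, collapse = ", "))
  }
  tab$pic50 <- pic50FromIC50(tab$ic50_nM)
  tab
}

.asModelMatrix <- function(X) {
  X <- as.data.frame(X)
  nm <- names(X)
  M <- as.matrix(X)
  if (!is.numeric(M)) stop("descriptor table must be numeric")
  colnames(M) <- nm
  M
}

#' Fit a multiple linear regression pIC50 model
#'
#' Ordinary least squares with intercept via \code{stats::lm}, packaged
#' with coefficient standard errors, \eqn{R^2}, adjusted \eqn{R^2}
#' (\eqn{1 - (1-R^2)(n-1)/(n-p-1)}), the standard error of the estimate,
#' and the overall F test.
#'
#' @param X data.frame or matrix of descriptors (n rows, p columns).
#' @param y numeric response (pIC50), length n.
#' @return a [QSARModel-class].
#' @export
fitMLR <- function(X, y) {
  M <- .asModelMatrix(X)
  n <- nrow(M); p <- ncol(M)
  stopifnot(length(y) == n)
  if (n <= p + 1L) stop("need n > p + 1 observations to fit ", p,
                        " descriptors (got n = ", n, ")")
  qx <- qr(cbind(1, M))
  if (qx$rank < p + 1L) {
    piv <- qx$pivot[seq_len(qx$rank)]
    dropped <- setdiff(seq_len(p + 1L), piv) - 1L
    stop("descriptor matrix is rank deficient; offending column(s): ",
         paste(colnames(M)[dropped], collapse = ", "))
  }
  df <- data.frame(y = y, M, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  co <- stats::coef(sm)
  fs <- sm$fstatistic
  pval <- if (is.null(fs)) NA_real_ else
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  r2 <- sm$r.squared
  new("QSARModel",
      coefficients = stats::setNames(co[, 1], rownames(co)),
      se = stats::setNames(co[, 2], rownames(co)),
      n = as.integer(n),
      r2 = r2,
      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
      see = sm$sigma,
      f_stat = if (is.null(fs)) NA_real_ else unname(fs[1]),
      p_value = unname(pval),
      residuals = unname(stats::residuals(fit)))
}

#' Adjusted R-squared
#'
#' \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#'
#' @param r2 coefficient of determination.
#' @param n observations.
#' @param p predictors (excluding intercept).
#' @return adjusted R-squared.
#' @export
adjustedR2 <- function(r2, n, p) {
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' The frozen published five-descriptor pIC50 model
#'
#' Returns the literature regression
#' \deqn{pIC50 = 14.48 - 0.13\,P + 0.06\,logP + 0.17\,TPSA - 2.54\,HBA - 2.57\,J}
#' (P = molar polarizability, J = Balaban index) with its printed
#' coefficient standard errors and fit statistics (n = 10, R^2 = 0.93,
#' adjusted R^2 = 0.84, SEE = 0.24, p = 0.02). The F statistic is the
#' one implied by R^2 with (5, 4) degrees of freedom.
#'
#' @return a [QSARModel-class] with coefficients named
#'   \code{mol_polarizability}, \code{logp}, \code{tpsa}, \code{hba},
#'   \code{balaban_j}.
#' @export
publishedModel <- function() {
  co <- c("(Intercept)" = 14.48, mol_polarizability = -0.13, logp = 0.06,
          tpsa = 0.17, hba = -2.54, balaban_j = -2.57)
  se <- c("(Intercept)" = 3.8, mol_polarizability = 0.06, logp = 0.04,
          tpsa = 0.04, hba = 0.5, balaban_j = 1.21)
  r2 <- 0.93
  f <- (r2 / 5) / ((1 - r2) / 4)
  new("QSARModel", coefficients = co, se = se, n = 10L,
      r2 = r2, adj_r2 = 0.84, see = 0.24,
      f_stat = f, p_value = 0.02, residuals = numeric(0))
}

#' Predict pIC50 from a descriptor vector
#'
#' \eqn{\beta_0 + \sum_k \beta_k d_k}; every model descriptor must be
#' present in \code{d}.
#'
#' @param model a [QSARModel-class].
#' @param d named numeric vector, one-row data.frame (e.g. from
#'   [descriptorVector()]) or multi-row data.frame of descriptor values.
#' @return predicted pIC50 (one per row of \code{d}).
#' @export
predictPic50 <- function(model, d) {
  stopifnot(is(model, "QSARModel"))
  co <- model@coefficients
  terms <- names(co)[-1]
  if (is.data.frame(d)) {
    missing_terms <- setdiff(terms, names(d))
    if (length(missing_terms)) {
      stop("descriptor(s) missing from input: ",
           paste(missing_terms, collapse = ", "))
    }
    M <- as.matrix(d[, terms, drop = FALSE])
  } else {
    d <- unlist(d)
    missing_terms <- setdiff(terms, names(d))
    if (length(missing_terms)) {
      stop("descriptor(s) missing from input: ",
           paste(missing_terms, collapse = ", "))
    }
    M <- matrix(d[terms], nrow = 1, dimnames = list(NULL, terms))
  }
  if (anyNA(M)) stop("descriptor values contain NA")
  unname(co[1] + drop(M %*% co[-1]))
}

#' Externally validate a model against observed activities
#'
#' Computes per-compound predictions and residuals
#' (observed - predicted), the external \eqn{R^2 = 1 - SSE/SST} (SST
#' about the mean of the observed values), and flags residuals whose
#' magnitude exceeds \code{max_residual}.
#'
#' @param model a [QSARModel-class].
#' @param X descriptor table (columns covering the model terms).
#' @param y_observed observed pIC50 values, one per row of \code{X}.
#' @param max_residual flagging threshold on |residual| (default 0.5).
#' @return list with \code{table} (data.frame: observed, predicted,
#'   residual, flagged), \code{external_r2}, \code{max_abs_residual},
#'   \code{n_flagged}.
#' @export
externalValidate <- function(model, X, y_observed, max_residual = 0.5) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y_observed)) {
    stop("X has ", nrow(X), " rows but y_observed has length ",
         length(y_observed))
  }
  pred <- predictPic50(model, X)
  resid <- y_observed - pred
  sse <- sum(resid^2)
  sst <- sum((y_observed - mean(y_observed))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  tab <- data.frame(observed = y_observed, predicted = pred,
                    residual = resid,
                    flagged = abs(resid) > max_residual)
  list(table = tab,
       external_r2 = r2,
       max_abs_residual = max(abs(resid)),
       n_flagged = sum(tab$flagged))
}

# p-value of each non-intercept coefficient of an lm-style fit on the
# given columns; returns named vector
.coefPvalues <- function(X, y, cols) {
  df <- data.frame(y = y, as.data.frame(X)[, cols, drop = FALSE],
                   check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  co <- stats::coef(summary(fit))
  pv <- co[-1, 4]
  stats::setNames(pv, cols)
}

#' Classical descriptor selection (forward, backward, stepwise)
#'
#' p-value-driven selection as implemented in classical statistics
#' packages: forward selection (FS) repeatedly adds the candidate with
#' the smallest partial p-value below \code{alpha_enter}; backward
#' elimination (BE) starts from the full model and drops the largest
#' p-value above \code{alpha_remove}; stepwise selection (SS) alternates
#' a forward step with backward checks. Deterministic given column
#' order; p-value ties resolve to the earlier column.
#'
#' @param X full candidate descriptor table.
#' @param y response (pIC50).
#' @param method \code{"FS"}, \code{"BE"} or \code{"SS"}.
#' @param alpha_enter entry threshold (default 0.05).
#' @param alpha_remove removal threshold (default 0.10).
#' @return list with \code{selected} (character vector of column names,
#'   possibly empty) and \code{model} (a [QSARModel-class]; intercept-only
#'   models are returned as NULL with a warning).
#' @export
selectDescriptors <- function(X, y, method = c("FS", "BE", "SS"),
                              alpha_enter = 0.05, alpha_remove = 0.10) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  cols <- names(X)
  selected <- if (method == "BE") cols else character(0)

  forward_step <- function(selected) {
    cand <- setdiff(cols, selected)
    if (!length(cand)) return(NULL)
    best <- NULL; best_p <- Inf
    for (cn in cand) {
      pv <- .coefPvalues(X, y, c(selected, cn))[[cn]]
      if (is.finite(pv) && pv < best_p - 1e-15) { best <- cn; best_p <- pv }
    }
    if (!is.null(best) && best_p < alpha_enter) best else NULL
  }
  backward_step <- function(selected) {
    if (!length(selected)) return(NULL)
    pv <- .coefPvalues(X, y, selected)
    worst <- which.max(pv)   # ties resolve to earlier column
    if (pv[worst] > alpha_remove) names(pv)[worst] else NULL
  }

  if (method == "FS") {
    repeat {
      add <- forward_step(selected)
      if (is.null(add)) break
      selected <- c(selected, add)
    }
  } else if (method == "BE") {
    repeat {
      drop_col <- backward_step(selected)
      if (is.null(drop_col)) break
      selected <- setdiff(selected, drop_col)
    }
  } else {
    repeat {
      add <- forward_step(selected)
      if (is.null(add)) break
      selected <- c(selected, add)
      repeat {
        drop_col <- backward_step(selected)
        if (is.null(drop_col)) break
        selected <- setdiff(selected, drop_col)
      }
    }
  }

  if (!length(selected)) {
    warning("no descriptor passed the entry criterion; intercept-only model")
    return(list(selected = character(0), model = NULL))
  }
  list(selected = selected,
       model = fitMLR(X[, selected, drop = FALSE], y))
}

#' Overall regression significance (ANOVA F test)
#'
#' The overall F statistic of a fitted model,
#' \eqn{F = (R^2/p) / ((1-R^2)/(n-p-1))}, with its p-value from the F
#' distribution on \eqn{(p, n-p-1)} degrees of freedom.
#'
#' @param model a fitted [QSARModel-class].
#' @return list with elements \code{F} and \code{p}.
#' @export
anovaSignificance <- function(model) {
  stopifnot(is(model, "QSARModel"))
  p <- length(model@coefficients) - 1L
  n <- model@n
  if (n - p - 1L <= 0L) stop("degenerate degrees of freedom (n - p - 1 <= 0)")
  r2 <- model@r2
  if (r2 >= 1) {
    return(list(F = Inf, p = 0))
  }
  f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  list(F = f, p = stats::pf(f, p, n - p - 1, lower.tail = FALSE))
}

#' Serialize a QSARModel as flat key-value text
#'
#' Round-trips bit-exactly through [readQSARModel()] (values written
#' with full double precision).
#'
#' @param model a [QSARModel-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeQSARModel <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("terms\t", paste(names(model@coefficients), collapse = ",")),
    paste0("coefficients\t", paste(num(model@coefficients), collapse = ",")),
    paste0("se\t", paste(num(model@se), collapse = ",")),
    paste0("n\t", model@n),
    paste0("r2\t", num(model@r2)),
    paste0("adj_r2\t", num(model@adj_r2)),
    paste0("see\t", num(model@see)),
    paste0("f_stat\t", num(model@f_stat)),
    paste0("p_value\t", num(model@p_value)),
    paste0("residuals\t", paste(num(model@residuals), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a QSARModel written by [writeQSARModel()]
#'
#' @param path file written by [writeQSARModel()].
#' @return a [QSARModel-class].
#' @export
readQSARModel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) if (length(x) > 1) x[2] else ""),
                          vapply(kv, `[`, character(1), 1))
  split_num <- function(s) if (nzchar(s)) as.numeric(strsplit(s, ",")[[1]]) else numeric(0)
  terms <- strsplit(vals$terms, ",")[[1]]
  new("QSARModel",
      coefficients = stats::setNames(split_num(vals$coefficients), terms),
      se = stats::setNames(split_num(vals$se), terms),
      n = as.integer(vals$n),
      r2 = as.numeric(vals$r2),
      adj_r2 = as.numeric(vals$adj_r2),
      see = as.numeric(vals$see),
      f_stat = as.numeric(vals$f_stat),
      p_value = as.numeric(vals$p_value),
      residuals = split_num(vals$residuals))
}
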