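# Orchestration: library in, ranked prioritized leads out.

#' Published hit table fixture
#'
#' The packaged per-compound literature values (pIC50, heavy atoms,
#' clogP and the printed efficiency columns) for the ten prioritized
#' hits C1-C10, as shipped in \code{extdata/table4_hits.csv}.
#'
#' @return data.frame with columns id, pic50, ha, clogp, le, le_scale,
#'   lipe, fq.
#' @export
publishedHitTable <- function() {
  path <- system.file("extdata", "table4_hits.csv", package = "hdacScreen")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' @param library a list of [Molecule-class] objects or a path readable
#'   by [readMolecules()].
#' @param model \code{"published"}, a [QSARModel-class], or a path to a
#'   serialized model.
#' @param pharmacophore \code{NULL} (skip the screening stage), a
#'   [PharmacophoreModel-class], a path to a serialized model, or a
#'   list of training [Molecule-class] objects to merge one from.
#' @param min_query_fit retention threshold of the screening stage.
#' @param consensus_fraction f for model merging when training
#'   molecules are supplied.
#' @param rof logical; apply the Rule-of-Five filter.
#' @param min_pred_pic50 drop compounds predicted below this activity.
#' @param clogp_overrides optional data.frame (id, clogp) of
#'   authoritative logP values overriding the computed estimate.
#' @param fq_mode FQ rounding convention (see [fitQuality()]).
#' @param timestamp logical; include a run timestamp in the report
#'   metadata (disable for byte-identical reruns).
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(library, model = "published",
                           pharmacophore = NULL, min_query_fit = 0,
                           consensus_fraction = 1.0, rof = FALSE,
                           min_pred_pic50 = -Inf, clogp_overrides = NULL,
                           fq_mode = "reproduction", timestamp = FALSE) {
  structure(list(library = library, model = model,
                 pharmacophore = pharmacophore,
                 min_query_fit = min_query_fit,
                 consensus_fraction = consensus_fraction,
                 rof = rof, min_pred_pic50 = min_pred_pic50,
                 clogp_overrides = clogp_overrides,
                 fq_mode = fq_mode, timestamp = timestamp),
            class = "PipelineConfig")
}

.resolveModel <- function(model) {
  if (is(model, "QSARModel")) return(model)
  if (identical(model, "published")) return(publishedModel())
  if (is.character(model) && file.exists(model)) return(readQSARModel(model))
  stop("pipeline stage 'model': cannot resolve model specification")
}

.resolvePharmacophore <- function(ph, f) {
  if (is.null(ph)) return(NULL)
  if (is(ph, "PharmacophoreModel")) return(ph)
  if (is.character(ph) && file.exists(ph)) return(readPharmacophoreModel(ph))
  if (is.list(ph) && length(ph) && is(ph[[1]], "Molecule")) {
    return(mergeFeatureModel(ph, f = f))
  }
  stop("pipeline stage 'screen': cannot resolve pharmacophore specification")
}

#' Run the full screening and prioritization pipeline
#'
#' Stages, in order: read the library; pharmacophore screening (if a
#' model is configured); descriptor computation; pIC50 prediction;
#' filtering (Rule of Five, minimum predicted activity); ligand
#' efficiency profiling; ranking by predicted pIC50 (descending), then
#' LipE (descending), then input order. Any stage error aborts with a
#' stage-named message; no partial report is returned.
#'
#' @param config a [pipelineConfig()].
#' @return a list of class \code{"PipelineReport"} with elements
#'   \code{table} (ranked per-compound report), \code{stage_counts}
#'   (compounds surviving each stage) and \code{meta}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  mols <- stage("read", {
    if (is.character(config$library)) readMolecules(config$library)
    else config$library
  })
  stage_counts <- c(read = length(mols))
  empty_report <- function() {
    warning("pipeline produced an empty report", call. = FALSE)
    structure(list(table = data.frame(), stage_counts = stage_counts,
                   meta = .pipelineMeta(config)),
              class = "PipelineReport")
  }
  if (!length(mols)) return(empty_report())

  qf <- NULL
  ph_model <- stage("screen",
                    .resolvePharmacophore(config$pharmacophore,
                                          config$consensus_fraction))
  if (!is.null(ph_model)) {
    ranked <- stage("screen",
                    screenLibrary(ph_model, mols, config$min_query_fit))
    ids <- vapply(mols, function(m) m@id, character(1))
    mols <- mols[match(ranked$id, ids)]
    qf <- stats::setNames(ranked$query_fit, ranked$id)
  }
  stage_counts["screen"] <- length(mols)
  if (!length(mols)) return(empty_report())

  desc <- stage("descriptors", descriptorTable(mols))
  if (!is.null(config$clogp_overrides)) {
    ov <- config$clogp_overrides
    hit <- match(desc$id, ov$id)
    desc$logp[!is.na(hit)] <- ov$clogp[hit[!is.na(hit)]]
  }

  model <- stage("model", .resolveModel(config$model))
  pred <- stage("predict", predictPic50(model, desc))
  desc$pred_pic50 <- pred

  keep <- rep(TRUE, nrow(desc))
  if (config$rof) {
    keep <- keep & vapply(seq_len(nrow(desc)), function(k)
      ruleOfFive(desc[k, ])$pass, logical(1))
  }
  keep <- keep & desc$pred_pic50 >= config$min_pred_pic50
  desc <- desc[keep, , drop = FALSE]
  stage_counts["filter"] <- nrow(desc)
  if (!nrow(desc)) return(empty_report())

  eff <- stage("efficiency", efficiencyTable(
    data.frame(id = desc$id, pic50 = desc$pred_pic50, ha = desc$ha,
               clogp = desc$logp, stringsAsFactors = FALSE),
    fq_mode = config$fq_mode))

  tab <- cbind(desc, eff[match(desc$id, eff$id),
                         c("le", "le_scale", "lipe", "fq",
                           "clogp_lt_3", "lipe_gt_5", "fq_near_1")])
  if (!is.null(qf)) tab$query_fit <- unname(qf[tab$id])
  ord <- order(-tab$pred_pic50, -tab$lipe, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  stage_counts["rank"] <- nrow(tab)

  structure(list(table = tab, stage_counts = stage_counts,
                 meta = .pipelineMeta(config)),
            class = "PipelineReport")
}

.pipelineMeta <- function(config) {
  cfg_echo <- config
  cfg_echo$library <- if (is.character(config$library)) config$library
                      else sprintf("<%d molecules>", length(config$library))
  cfg_echo$pharmacophore <- if (is.null(config$pharmacophore)) "none"
                            else "<model>"
  cfg_echo$model <- if (is.character(config$model)) config$model
                    else "<QSARModel>"
  meta <- list(
    package_version = as.character(utils::packageVersion("hdacScreen")),
    config = cfg_echo,
    note = paste("fully automated funnel: every retention step is a",
                 "declared quantitative filter (no docking, no manual",
                 "inspection)")
  )
  if (isTRUE(config$timestamp)) meta$timestamp <- format(Sys.time())
  meta
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport:", nrow(x$table), "compounds retained\n")
  cat("  stages:", paste(sprintf("%s=%d", names(x$stage_counts),
                                 x$stage_counts), collapse = " -> "), "\n")
  if (nrow(x$table)) {
    utils::head(x$table[, intersect(c("rank", "id", "pred_pic50", "lipe",
                                      "fq", "query_fit"), names(x$table))],
                10)
  }
  invisible(x)
}

#' Write a pipeline report as CSV
#'
#' @param report a \code{PipelineReport} from [runPipeline()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePipelineReport <- function(report, path) {
  stopifnot(inherits(report, "PipelineReport"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# hdacScreen pipeline report (package %s)",
            report$meta$package_version),
    sprintf("# stages: %s", paste(sprintf("%s=%d",
                                          names(report$stage_counts),
                                          report$stage_counts),
                                  collapse = " ")),
    sprintf("# %s", report$meta$note),
    if (!is.null(report$meta$timestamp))
      sprintf("# timestamp: %s", report$meta$timestamp)
  ), con)
  utils::write.csv(report$table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
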