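# Seeded synthetic compound libraries and activity data with the
# statistical structure the screening analysis assumes: molecules are
# assembled from a capping group, a linker and a zinc-binding group
# (the canonical HDAC-inhibitor architecture), and activities follow a
# linear descriptor model with Gaussian noise, thresholded into
# actives and decoys.

# curated fragment sets; strings are designed so that plain
# concatenation cap+linker+zbg is a valid SMILES (each non-terminal
# fragment ends at an open-valence chain atom)
FRAGMENT_SETS <- list(
  default = list(
    cap = c(
      "c1ccccc1C",            # benzyl
      "c1ccc2ccccc2c1C",      # naphthylmethyl
      "CC(C)C",               # isobutyl
      "c1ccncc1C",            # pyridylmethyl
      "COc1ccccc1C",          # methoxyphenyl
      "Oc1ccc(cc1)C",         # phenol
      "c1ccsc1C",             # thienylmethyl
      "CN(C)c1ccc(cc1)C",     # dimethylaminophenyl
      "Cc1ccc(cc1)C",         # tolyl
      "CC(C)(C)c1ccc(cc1)C"   # tert-butylphenyl
    ),
    linker = c(
      "CCCC",                 # butylene
      "CCCCC",                # pentylene
      "CC=CC",                # butenylene
      "COCC",                 # ether
      "CNC(=O)C",             # amide
      "Cc2ccc(cc2)C",         # phenylene
      "CCOCC",                # ethoxy
      "CC(C)CC",              # branched
      "Cc2ccsc2C",            # thienylene
      "CC#CC"                 # alkynylene
    ),
    zbg = c(
      "C(=O)NO",              # hydroxamic acid
      "C(=O)O",               # carboxylic acid
      "C(=O)N",               # carboxamide
      "C(=O)Nc3ccccc3N",      # 2-aminoanilide (benzamide class)
      "S(=O)(=O)N",           # sulfonamide
      "C(=O)NS(=O)(=O)C",     # acylsulfonamide
      "C(=O)NN",              # hydrazide
      "CS"                    # thiol
    )
  )
)

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic generators. Defaults mirror the
#' study conditions the package targets: true coefficients from the
#' frozen published activity model, Gaussian pIC50 noise with SD 0.24
#' (the model's standard error of estimate), and the 2500 nM
#' active/decoy threshold.
#'
#' @param n_compounds library size (>= 1).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output (Mersenne-Twister / inversion, fixed by the generators).
#' @param coefficients named numeric: intercept first, then descriptor
#'   coefficients (defaults to [publishedModel()]'s).
#' @param noise_sd Gaussian pIC50 noise SD (>= 0), default 0.24.
#' @param active_threshold active/decoy IC50 cutoff in nM, default 2500.
#' @param fragment_set id of a built-in fragment set.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_compounds = 50L, seed = 1L,
                             coefficients = publishedModel()@coefficients,
                             noise_sd = 0.24, active_threshold = 2500,
                             fragment_set = "default") {
  stopifnot(n_compounds >= 1L, noise_sd >= 0, active_threshold > 0,
            fragment_set %in% names(FRAGMENT_SETS),
            names(coefficients)[1] == "(Intercept)")
  structure(list(n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed),
                 coefficients = coefficients,
                 noise_sd = noise_sd,
                 active_threshold = active_threshold,
                 fragment_set = fragment_set),
            class = "SimulationConfig")
}

# run expr with a locally seeded, algorithm-pinned RNG, restoring the
# caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion"))
  expr
}

#' Generate a synthetic compound library
#'
#' Each molecule is assembled by a seeded uniform choice of one capping
#' fragment, one linker and one zinc-binding fragment from the
#' configured fragment set, then parsed through the molecules module
#' (so every output is a valid [Molecule-class]).
#'
#' @param cfg a [simulationConfig()].
#' @return list of [Molecule-class] objects with ids \code{SYN0001...}.
#' @export
generateLibrary <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  fs <- FRAGMENT_SETS[[cfg$fragment_set]]
  .withSeed(cfg$seed, {
    cap <- sample.int(length(fs$cap), cfg$n_compounds, replace = TRUE)
    lnk <- sample.int(length(fs$linker), cfg$n_compounds, replace = TRUE)
    zbg <- sample.int(length(fs$zbg), cfg$n_compounds, replace = TRUE)
    lapply(seq_len(cfg$n_compounds), function(k) {
      smi <- paste0(fs$cap[cap[k]], fs$linker[lnk[k]], fs$zbg[zbg[k]])
      parseSmiles(smi, id = sprintf("SYN%04d", k))
    })
  })
}

#' Simulate activities for a library from a linear descriptor model
#'
#' pIC50 = (true model applied to the computed descriptors) +
#' Normal(0, noise_sd); IC50 = 10^(9 - pIC50) nM; labels from the
#' configured active/decoy threshold. Compounds whose descriptors fail
#' are skipped with a warning.
#'
#' @param library list of [Molecule-class] objects.
#' @param cfg a [simulationConfig()]; noise is seeded with
#'   \code{cfg$seed + 1} so library assembly and noise are independent
#'   streams.
#' @return data.frame with columns id, true_pic50, pic50, ic50_nM,
#'   label, plus the descriptor columns used.
#' @export
simulateActivities <- function(library, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  desc <- list()
  for (m in library) {
    d <- tryCatch(descriptorVector(m), error = function(e) {
      warning("skipping compound '", m@id, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(d)) desc[[length(desc) + 1L]] <- d
  }
  if (!length(desc)) stop("no compound yielded a descriptor vector")
  desc <- do.call(rbind, desc)
  co <- cfg$coefficients
  terms <- names(co)[-1]
  missing_terms <- setdiff(terms, names(desc))
  if (length(missing_terms)) {
    stop("config coefficients name unknown descriptors: ",
         paste(missing_terms, collapse = ", "))
  }
  true_pic50 <- co[1] + drop(as.matrix(desc[, terms, drop = FALSE]) %*% co[-1])
  noise <- .withSeed(cfg$seed + 1L,
                     stats::rnorm(nrow(desc), 0, cfg$noise_sd))
  pic50 <- true_pic50 + noise
  ic50 <- ic50FromPic50(pic50)
  data.frame(id = desc$id, true_pic50 = unname(true_pic50),
             pic50 = unname(pic50), ic50_nM = unname(ic50),
             label = classifyActivity(ic50, cfg$active_threshold),
             desc[, setdiff(names(desc), "id"), drop = FALSE],
             stringsAsFactors = FALSE)
}

#' Generate a labelled screen scenario with planted retrieval
#'
#' Builds an active/decoy label set (A actives, n_decoys decoys) and a
#' hit set containing exactly \code{round(planted_sensitivity * A)}
#' seeded-sampled actives plus \code{decoy_hits} decoys (seeded
#' binomial draw with rate 0.2 when not given), so the expected screen
#' metrics are known in closed form from the counts.
#'
#' @param A number of actives.
#' @param n_decoys number of decoys.
#' @param planted_sensitivity fraction of actives placed in the hit set
#'   (in [0, 1]).
#' @param seed RNG seed.
#' @param decoy_hits decoys placed in the hit set; \code{NULL} for a
#'   seeded draw.
#' @return list with \code{labels} (named character vector) and
#'   \code{hits} (character vector of ids).
#' @export
generateScreenScenario <- function(A, n_decoys, planted_sensitivity, seed,
                                   decoy_hits = NULL) {
  stopifnot(A >= 0L, n_decoys >= 0L,
            planted_sensitivity >= 0, planted_sensitivity <= 1)
  act_ids <- sprintf("ACT%03d", seq_len(A))
  dec_ids <- sprintf("DEC%03d", seq_len(n_decoys))
  labels <- stats::setNames(c(rep("active", A), rep("decoy", n_decoys)),
                            c(act_ids, dec_ids))
  .withSeed(seed, {
    n_active_hits <- round(planted_sensitivity * A)
    if (is.null(decoy_hits)) decoy_hits <- stats::rbinom(1, n_decoys, 0.2)
    stopifnot(decoy_hits <= n_decoys)
    hits <- c(sample(act_ids, n_active_hits),
              sample(dec_ids, decoy_hits))
    list(labels = labels, hits = hits)
  })
}

#' Write a simulated activity table with a config header
#'
#' Standard activity CSV schema preceded by structured comment lines
#' echoing the generating configuration.
#'
#' @param activities data.frame from [simulateActivities()].
#' @param cfg the generating [simulationConfig()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeActivityCSV <- function(activities, cfg, path) {
  hdr <- c(
    sprintf("# simulationConfig: n_compounds=%d seed=%d noise_sd=%g active_threshold=%g fragment_set=%s",
            cfg$n_compounds, cfg$seed, cfg$noise_sd, cfg$active_threshold,
            cfg$fragment_set),
    "# rng: Mersenne-Twister / Inversion",
    sprintf("# coefficients: %s",
            paste(sprintf("%s=%g", names(cfg$coefficients),
                          cfg$coefficients), collapse = " "))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(activities, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
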