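#' Configuration for a full analysis run
#'
#' Collects every tunable of the end-to-end analysis with its default, so a
#' run is reproducible from the config alone. `input` may be a plant-record
#' data frame, a `sim_trial`, or a path to a plant-level CSV.
#'
#' @param input Plant records (data frame, `sim_trial`, or CSV path); when
#'   `NULL`, a trial is simulated from `sim_config`.
#' @param output_dir Directory for the report bundle; created if absent.
#' @param treatments Family-structured treatments to analyse.
#' @param traits Traits to analyse where available.
#' @param index_traits The two traits combined in the Smith-Hazel index.
#' @param pressures Selection pressures for gain and ranking tables.
#' @param parental_control Parental control factor `c` (0.5 for half-sib
#'   families).
#' @param weights Index weights, one per `index_traits` entry.
#' @param seed Seed for any simulation performed by the run.
#' @param sim_config Generator config used when `input` is `NULL`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("rhizoQG_run_"),
                       treatments = c("TA1", "NPLUS"),
                       traits = c("shoot_dm", "root_dm", "rsr", "shoot_sp",
                                  "root_sp"),
                       index_traits = c("shoot_dm", "shoot_sp"),
                       pressures = c(0.05, 0.10, 0.20),
                       parental_control = 0.5,
                       weights = c(1, 1),
                       seed = 1,
                       sim_config = NULL) {
  if (any(pressures <= 0 | pressures >= 1)) {
    stop("run_config: pressures must lie in (0, 1)", call. = FALSE)
  }
  structure(list(input = input, output_dir = output_dir,
                 treatments = treatments, traits = traits,
                 index_traits = index_traits, pressures = pressures,
                 parental_control = parental_control, weights = weights,
                 seed = as.integer(seed), sim_config = sim_config),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Scalar fields override the [run_config()] defaults; unknown fields are
#' rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("read_run_config: the 'yaml' package is needed for YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("read_run_config: unknown fields: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, raw)
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[rhizoQG] ", sprintf(...))
}

#' Run the full analysis and write a report bundle
#'
#' Chains the analysis stages: trait derivation, per-trait REML fits
#' (components, heritabilities, BLUPs), genetic and phenotypic
#' correlations, predicted gains at the configured pressures, Smith-Hazel
#' index ranking, single- vs multi-trait selection overlap, and pattern
#' analysis. Every table is written as CSV under `config$output_dir`
#' together with a machine-readable `summary.json`; the function returns
#' the bundle invisibly. Stages whose inputs are unavailable (e.g.
#' symbiotic potential without an `NPLUS` arm) are skipped with a logged
#' warning while the remaining stages complete.
#'
#' @param config A [run_config()] (or a path accepted by
#'   [read_run_config()]).
#' @param verbose Log each stage and every resolved parameter to standard
#'   error.
#' @return (Invisibly) a list with all computed objects and `files`, the
#'   written paths.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  pipeline_log(verbose,
               "run: seed=%d pressures=%s c=%.2f weights=%s traits=%s",
               config$seed, paste(config$pressures, collapse = ","),
               config$parental_control,
               paste(config$weights, collapse = ","),
               paste(config$traits, collapse = ","))

  plants <- config$input
  if (is.null(plants)) {
    sc <- config$sim_config %||% simulation_config(seed = config$seed)
    pipeline_log(verbose, "simulating trial (seed %d)", sc$seed)
    plants <- simulate_trial(sc)$plants
  } else if (is.character(plants)) {
    pipeline_log(verbose, "reading plant table %s", plants)
    plants <- read_plant_table(plants)
  } else if (inherits(plants, "sim_trial")) {
    plants <- plants$plants
  }

  pipeline_log(verbose, "deriving plot-level traits")
  plots <- withCallingHandlers(
    derive_trait_table(plants),
    warning = function(w) {
      pipeline_log(verbose, "warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  n_rep <- length(unique(plots$replicate))

  files <- character()
  logged <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      pipeline_log(verbose, "warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  out <- function(name) file.path(config$output_dir, name)
  emit <- function(df, name) {
    write.csv(df, out(name), row.names = FALSE, quote = FALSE)
    files[[name]] <<- out(name)
    pipeline_log(verbose, "wrote %s", out(name))
  }

  comp_rows <- list()
  h2_rows <- list()
  blup_rows <- list()
  fits <- list()
  for (trt in intersect(config$treatments, unique(plots$treatment))) {
    for (tr in intersect(config$traits, unique(plots$trait))) {
      sub <- plots[plots$treatment == trt & plots$trait == tr &
                     !is.na(plots$value), , drop = FALSE]
      if (nrow(sub) < 4) next
      fit <- withCallingHandlers(
        fit_reml(sub),
        warning = function(w) {
          pipeline_log(verbose, "fit %s/%s: %s", trt, tr, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      fits[[paste(trt, tr, sep = ".")]] <- fit
      cc <- fit$components
      cc$treatment <- trt
      cc$trait <- tr
      comp_rows[[paste(trt, tr)]] <- cc
      h2 <- heritability_from_fit(fit, n_rep)
      h2_rows[[paste(trt, tr)]] <- data.frame(
        treatment = trt, trait = tr, h2 = h2$h2, se = h2$se)
      blup_rows[[paste(trt, tr)]] <- data.frame(
        treatment = trt, trait = tr,
        family = names(fit$adjusted_means),
        blup = unname(fit$blups$family),
        adjusted_mean = unname(fit$adjusted_means))
      pipeline_log(verbose, "fitted %s/%s: logL %.3f, h2 %.3f", trt, tr,
                   fit$logLik, h2$h2)
    }
  }
  if (!length(fits)) stop("run_pipeline: no trait/treatment combination could be fitted",
                          call. = FALSE)
  emit(do.call(rbind, comp_rows), "components.csv")
  emit(do.call(rbind, h2_rows), "heritability.csv")
  emit(do.call(rbind, blup_rows), "blups.csv")

  # genetic correlations within the first treatment with >= 2 fitted traits
  gmat <- NULL
  for (trt in intersect(config$treatments, unique(plots$treatment))) {
    avail <- intersect(config$traits,
                       unique(plots$trait[plots$treatment == trt &
                                            !is.na(plots$value)]))
    if (length(avail) >= 2) {
      pipeline_log(verbose, "genetic correlations (%s): %s", trt,
                   paste(avail, collapse = ","))
      gmat <- withCallingHandlers(
        genetic_correlation_matrix(plots, avail, treatment = trt),
        warning = function(w) {
          pipeline_log(verbose, "genetic correlations: %s",
                       conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      g <- as.data.frame(gmat$rA)
      g <- cbind(trait = rownames(gmat$rA), g)
      emit(g, "genetic_correlations.csv")
      break
    }
  }

  # phenotypic correlations and the trait matrix of the primary treatment
  primary <- intersect(config$treatments, unique(plots$treatment))[1]
  avail <- intersect(config$traits,
                     unique(plots$trait[plots$treatment == primary &
                                          !is.na(plots$value)]))
  tm <- blup_trait_matrix(plots, avail, treatment = primary)
  pheno <- logged(phenotypic_correlations(tm))
  emit(cbind(trait = rownames(pheno$r), as.data.frame(pheno$r)),
       "phenotypic_r.csv")
  emit(cbind(trait = rownames(pheno$p), as.data.frame(pheno$p)),
       "phenotypic_p.csv")

  # predicted gains
  gain_rows <- list()
  for (trt in unique(vapply(strsplit(names(fits), ".", fixed = TRUE),
                            `[`, "", 1))) {
    for (tr in avail) {
      fit <- fits[[paste(trt, tr, sep = ".")]]
      if (is.null(fit)) next
      sf <- fit_component(fit, "family")
      spf <- family_phenotypic_sd(sf, fit_component(fit, "fam_rep"),
                                  fit_component(fit, "residual"), n_rep)
      mu <- fit$mu
      if (spf <= 0 || mu == 0) next
      for (p in config$pressures) {
        plan <- selection_plan(p, parental_control = config$parental_control)
        g <- predicted_gain(plan, sf, spf, mu)
        g$treatment <- trt
        g$trait <- tr
        gain_rows[[paste(trt, tr, p)]] <- g
      }
    }
  }
  if (length(gain_rows)) emit(do.call(rbind, gain_rows), "gains.csv")

  # Smith-Hazel index on the configured trait pair, plus selection overlap
  index <- NULL
  overlap <- NULL
  it <- intersect(config$index_traits, colnames(tm))
  if (length(it) == length(config$index_traits) && !is.null(gmat) &&
      all(it %in% gmat$traits)) {
    Pm <- index_phenotypic_matrix(gmat, it, n_rep)
    Am <- gmat$covA[it, it, drop = FALSE]
    b <- tryCatch(smith_hazel_coefficients(Pm, Am, config$weights),
                  error = function(e) {
                    pipeline_log(verbose, "index skipped: %s",
                                 conditionMessage(e))
                    NULL
                  })
    if (!is.null(b)) {
      index <- suppressWarnings(index_scores(b, tm[, it, drop = FALSE]))
      emit(index, "index.csv")
      sel <- list()
      p0 <- min(config$pressures)
      for (tr in it) {
        v <- setNames(tm[, tr], rownames(tm))
        sel[[tr]] <- suppressWarnings(select_top(v[!is.na(v)], p0))
      }
      sel$smith_hazel <- suppressWarnings(
        select_top(setNames(index$score, index$family), p0))
      overlap <- selection_overlap(sel)
      jsonlite::write_json(overlap, out("overlap.json"), auto_unbox = TRUE,
                           digits = NA)
      files[["overlap.json"]] <- out("overlap.json")
      pipeline_log(verbose, "wrote %s", out("overlap.json"))
    }
  } else {
    pipeline_log(verbose,
                 "index skipped: traits %s not all available",
                 paste(config$index_traits, collapse = ","))
  }

  # pattern analysis of the primary-treatment trait matrix
  pattern <- NULL
  tm_cc <- tm[complete.cases(tm), , drop = FALSE]
  if (nrow(tm_cc) >= 3 && ncol(tm_cc) >= 2) {
    pattern <- logged(pattern_analysis(tm_cc))
    emit(data.frame(entry = names(pattern$clusters$assignments),
                    group = unname(pattern$clusters$assignments)),
         "clusters.csv")
    emit(cbind(entry = rownames(pattern$pca$scores),
               as.data.frame(pattern$pca$scores[, 1:2, drop = FALSE])),
         "biplot_scores.csv")
    emit(cbind(trait = rownames(pattern$pca$loadings),
               as.data.frame(pattern$pca$loadings)),
         "biplot_loadings.csv")
    emit(data.frame(component = seq_along(pattern$pca$variance_proportions),
                    proportion = pattern$pca$variance_proportions),
         "scree.csv")
  }

  summary <- list(
    seed = config$seed,
    pressures = config$pressures,
    parental_control = config$parental_control,
    weights = config$weights,
    n_replicates = n_rep,
    n_families = length(unique(plots$family)),
    fitted = names(fits),
    fit_reports = lapply(fits, function(f) {
      list(logLik = f$logLik, iterations = f$iterations,
           converged = f$converged,
           dropped_terms = as.list(f$dropped_terms))
    }),
    pattern_k = if (!is.null(pattern)) pattern$k else NULL,
    files = as.list(files)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  files[["summary.json"]] <- out("summary.json")

  invisible(list(plots = plots, fits = fits,
                 heritability = do.call(rbind, h2_rows),
                 genetic = gmat, phenotypic = pheno, trait_matrix = tm,
                 gains = if (length(gain_rows)) do.call(rbind, gain_rows),
                 index = index, overlap = overlap, pattern = pattern,
                 files = files, config = config))
}

# Among-family phenotypic (co)variance matrix for the Smith-Hazel index:
# family variances plus interaction-and-residual (co)variances shrunk by
# the replicate count, assembled from the pairwise component covariances.
index_phenotypic_matrix <- function(gmat, traits, n_rep) {
  p <- length(traits)
  Pm <- matrix(0, p, p, dimnames = list(traits, traits))
  cc <- gmat$component_cov
  for (i in seq_len(p)) {
    for (j in i:p) {
      fam <- cc$family[traits[i], traits[j]]
      fr <- if (!is.null(cc$fam_rep)) cc$fam_rep[traits[i], traits[j]] else 0
      res <- cc$residual[traits[i], traits[j]]
      if (is.na(fr)) fr <- 0
      Pm[i, j] <- Pm[j, i] <- fam + fr / n_rep + res / n_rep
    }
  }
  Pm
}
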