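#' Configuration for a simulated half-sib symbiosis trial
#'
#' Assembles and validates all parameters of the trial generator. The
#' defaults emulate the study conditions the package is built around: 120
#' half-sib families grown in two environmental replicates (growth rooms),
#' 16 plants per family x replicate quadrant, two family-structured treatment
#' arms (Rhizobium-inoculated `TA1` and a mineral-N positive control
#' `NPLUS`) of 30 containers per replicate each, plus a family-bulked
#' negative control (`NEG`, no Rhizobium and no N) of 4 containers per
#' replicate. Variance components are specified at the analysis scale
#' (family x replicate plot means); an optional plant-level residual can be
#' layered on top and is averaged back into the quadrant means.
#'
#' Per treatment and trait the component vector holds, in squared trait
#' units: `family`, `replicate`, `fam_rep` (family x replicate interaction),
#' `row`, `column` (room-grid effects nested in replicate) and `residual`
#' (plot-scale). Family effects are shared genetics: one underlying standard
#' normal score per family and trait (shoot/root scores correlated by
#' `trait_genetic_correlation`) is scaled by each treatment's family
#' standard deviation, so the same families are good in both arms.
#'
#' @param n_families,n_replicates,plants_per_quadrant,containers_per_replicate
#'   Design counts; all must be >= 1.
#' @param treatment_means Named list `treatment -> c(shoot_dm=, root_dm=)`
#'   in mg per plant. Treatments must be a subset of `TA1`, `NPLUS`.
#' @param true_components Named list `treatment -> trait -> component
#'   vector` (see Details); all entries must be non-negative.
#' @param trait_genetic_correlation Correlation of the underlying family
#'   scores for shoot vs root dry matter, in `[-1, 1]`.
#' @param negative_control List with `n_containers`, `bulk_mean`
#'   (`c(shoot_dm=, root_dm=)`, mg) and `bulk_sd` (same shape, mg).
#' @param plant_sd Named list `treatment -> trait -> sd` of the optional
#'   plant-level residual (mg); defaults to 0 everywhere.
#' @param missing_rate Probability in `[0, 1]` that a plant record is lost
#'   completely at random.
#' @param seed Integer seed; the simulation is a pure function of the
#'   config including this seed.
#'
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_families = 120,
                              n_replicates = 2,
                              plants_per_quadrant = 16,
                              containers_per_replicate = 30,
                              treatment_means = list(
                                TA1 = c(shoot_dm = 11.4, root_dm = 5.03),
                                NPLUS = c(shoot_dm = 25.1, root_dm = 9.00)
                              ),
                              true_components = list(
                                TA1 = list(
                                  shoot_dm = c(family = 13.5, replicate = 1.0,
                                               fam_rep = 4.7, row = 0.5,
                                               column = 0.5, residual = 49.6),
                                  root_dm = c(family = 2.2, replicate = 0.5,
                                              fam_rep = 0.9, row = 0.2,
                                              column = 0.2, residual = 10.2)
                                ),
                                NPLUS = list(
                                  shoot_dm = c(family = 23.3, replicate = 2.0,
                                               fam_rep = 23.6, row = 1.0,
                                               column = 1.0, residual = 220.6),
                                  root_dm = c(family = 3.4, replicate = 0.5,
                                              fam_rep = 2.6, row = 0.2,
                                              column = 0.2, residual = 30.7)
                                )
                              ),
                              trait_genetic_correlation = 0.97,
                              negative_control = list(
                                n_containers = 4,
                                bulk_mean = c(shoot_dm = 2.15, root_dm = 1.59),
                                bulk_sd = c(shoot_dm = 0.5, root_dm = 0.4)
                              ),
                              plant_sd = NULL,
                              missing_rate = 0,
                              seed = 1) {
  cfg <- list(
    n_families = as.integer(n_families),
    n_replicates = as.integer(n_replicates),
    plants_per_quadrant = as.integer(plants_per_quadrant),
    containers_per_replicate = as.integer(containers_per_replicate),
    treatment_means = treatment_means,
    true_components = true_components,
    trait_genetic_correlation = trait_genetic_correlation,
    negative_control = negative_control,
    plant_sd = plant_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_families, cfg$n_replicates, cfg$plants_per_quadrant,
              cfg$containers_per_replicate)
  if (any(counts < 1L)) stop("config error: all design counts must be >= 1",
                             call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    stop("config error: missing_rate must lie in [0, 1]", call. = FALSE)
  }
  trt <- names(cfg$treatment_means)
  if (!all(trt %in% c("TA1", "NPLUS"))) {
    stop("config error: family-structured treatments must be within {TA1, NPLUS}",
         call. = FALSE)
  }
  if (!all(trt %in% names(cfg$true_components))) {
    stop("config error: every treatment needs a true_components entry",
         call. = FALSE)
  }
  needed <- c("family", "replicate", "fam_rep", "row", "column", "residual")
  for (t in trt) {
    for (tr in names(cfg$true_components[[t]])) {
      comp <- cfg$true_components[[t]][[tr]]
      if (!all(needed %in% names(comp))) {
        stop(sprintf("config error: components for %s/%s must name %s",
                     t, tr, paste(needed, collapse = ", ")), call. = FALSE)
      }
      if (any(comp < 0)) {
        stop(sprintf("config error: negative variance in %s/%s", t, tr),
             call. = FALSE)
      }
    }
  }
  if (abs(cfg$trait_genetic_correlation) > 1) {
    stop("config error: trait_genetic_correlation must lie in [-1, 1]",
         call. = FALSE)
  }
  if (!is.null(cfg$negative_control)) {
    if (any(cfg$negative_control$bulk_sd < 0) ||
        cfg$negative_control$n_containers < 1) {
      stop("config error: invalid negative-control block", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Simulate a half-sib symbiosis trial with known truth
#'
#' Generates plant-level records under the additive random-effects trial
#' model: a plot (family x replicate quadrant) mean is the treatment mean
#' plus family, replicate, family x replicate, row, column and plot residual
#' effects, each drawn from a zero-mean normal with its configured variance;
#' plant values add an optional plant-level residual on top. Negative-control
#' containers are a family bulk (mean and sd only, no family labels).
#' Records are dropped completely at random at `missing_rate`. The output is
#' byte-identical for identical configs (including seed).
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `sim_trial`: a list with `plants` (data frame
#'   with columns `family`, `replicate`, `container`, `quadrant`, `row`,
#'   `column`, `treatment`, `shoot_dm_mg`, `root_dm_mg`) and `truth` (the
#'   realised effects per treatment and trait plus the config echo, the
#'   oracle for parameter-recovery tests).
#' @examples
#' trial <- simulate_trial(simulation_config(n_families = 8,
#'   containers_per_replicate = 2, plants_per_quadrant = 2, seed = 42))
#' head(trial$plants)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_preserved_seed(config$seed, simulate_trial_impl(config))
}

simulate_trial_impl <- function(cfg) {
  nf <- cfg$n_families
  nrep <- cfg$n_replicates
  npl <- cfg$plants_per_quadrant
  treatments <- names(cfg$treatment_means)
  traits <- c("shoot_dm", "root_dm")

  # shared family genetics: one standard-normal score per family and trait,
  # shoot/root scores correlated
  rg <- cfg$trait_genetic_correlation
  z <- matrix(rnorm(nf * 2L), nf, 2L,
              dimnames = list(NULL, traits))
  z[, "root_dm"] <- rg * z[, "shoot_dm"] + sqrt(max(0, 1 - rg^2)) * z[, "root_dm"]

  truth <- list(config = cfg, family_scores = z, effects = list())
  blocks <- list()

  for (trt in treatments) {
    design <- make_design(nf, nrep, cfg$containers_per_replicate)
    eff <- list()
    plot_values <- matrix(0, nrow(design), length(traits),
                          dimnames = list(NULL, traits))
    for (tr in traits) {
      comp <- cfg$true_components[[trt]][[tr]]
      fam_eff <- sqrt(comp[["family"]]) * z[, tr]
      rep_eff <- rnorm(nrep, 0, sqrt(comp[["replicate"]]))
      fr_eff <- matrix(rnorm(nf * nrep, 0, sqrt(comp[["fam_rep"]])), nf, nrep)
      n_rows <- max(design$row)
      n_cols <- max(design$column)
      row_eff <- matrix(rnorm(n_rows * nrep, 0, sqrt(comp[["row"]])),
                        n_rows, nrep)
      col_eff <- matrix(rnorm(n_cols * nrep, 0, sqrt(comp[["column"]])),
                        n_cols, nrep)
      plot_res <- rnorm(nrow(design), 0, sqrt(comp[["residual"]]))
      mu <- cfg$treatment_means[[trt]][[tr]]
      plot_values[, tr] <- mu +
        fam_eff[design$family] +
        rep_eff[design$replicate] +
        fr_eff[cbind(design$family, design$replicate)] +
        row_eff[cbind(design$row, design$replicate)] +
        col_eff[cbind(design$column, design$replicate)] +
        plot_res
      eff[[tr]] <- list(family = fam_eff, replicate = rep_eff,
                        fam_rep = fr_eff, row = row_eff, column = col_eff,
                        plot_residual = plot_res)
    }
    truth$effects[[trt]] <- eff

    idx <- rep(seq_len(nrow(design)), each = npl)
    plants <- design[idx, , drop = FALSE]
    for (tr in traits) {
      psd <- 0
      if (!is.null(cfg$plant_sd)) {
        psd <- cfg$plant_sd[[trt]][[tr]] %||% 0
      }
      dev <- if (psd > 0) rnorm(nrow(plants), 0, psd) else 0
      plants[[paste0(tr, "_mg")]] <- plot_values[idx, tr] + dev
    }
    plants$treatment <- trt
    blocks[[trt]] <- plants
  }

  # negative control: family bulk, no family structure
  if (!is.null(cfg$negative_control)) {
    nc <- cfg$negative_control
    n_neg <- nc$n_containers * 4L * npl * nrep
    neg <- data.frame(
      family = NA_integer_,
      replicate = rep(seq_len(nrep), each = nc$n_containers * 4L * npl),
      container = rep(rep(seq_len(nc$n_containers), each = 4L * npl),
                      times = nrep),
      quadrant = rep(rep(1:4, each = npl),
                     times = nrep * nc$n_containers),
      row = NA_integer_,
      column = NA_integer_,
      shoot_dm_mg = rnorm(n_neg, nc$bulk_mean[["shoot_dm"]],
                          nc$bulk_sd[["shoot_dm"]]),
      root_dm_mg = rnorm(n_neg, nc$bulk_mean[["root_dm"]],
                         nc$bulk_sd[["root_dm"]]),
      treatment = "NEG"
    )
    blocks$NEG <- neg
  }

  cols <- c("family", "replicate", "container", "quadrant", "row", "column",
            "treatment", "shoot_dm_mg", "root_dm_mg")
  plants <- do.call(rbind, lapply(blocks, function(b) b[, cols]))
  rownames(plants) <- NULL
  if (cfg$missing_rate > 0) {
    keep <- runif(nrow(plants)) >= cfg$missing_rate
    plants <- plants[keep, , drop = FALSE]
    rownames(plants) <- NULL
  }
  structure(list(plants = plants, truth = truth), class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "Simulated half-sib trial: %d families x %d replicates, %d plants/quadrant\n",
    cfg$n_families, cfg$n_replicates, cfg$plants_per_quadrant))
  cat(sprintf("  %d plant records across treatments: %s\n",
              nrow(x$plants),
              paste(unique(x$plants$treatment), collapse = ", ")))
  invisible(x)
}

#' Write and read plant-level trial tables
#'
#' `write_plant_table()` writes the plant records as a UTF-8 comma-separated
#' file with header `family,replicate,container,quadrant,row,column,
#' treatment,shoot_dm_mg,root_dm_mg`; for a full `sim_trial` it also writes
#' the realised-truth sidecar as JSON next to it. `read_plant_table()` reads
#' the CSV back.
#'
#' @param x A `sim_trial` object or a plant-record data frame.
#' @param path Output CSV path.
#' @param truth_path Optional path for the truth JSON sidecar (defaults to
#'   `path` with a `_truth.json` suffix when `x` carries truth).
#' @return `write_plant_table()` returns `path` invisibly;
#'   `read_plant_table()` returns the plant data frame.
#' @export
write_plant_table <- function(x, path, truth_path = NULL) {
  plants <- if (inherits(x, "sim_trial")) x$plants else x
  write.csv(plants, path, row.names = FALSE, quote = FALSE)
  if (inherits(x, "sim_trial")) {
    if (is.null(truth_path)) {
      truth_path <- sub("\\.csv$", "", path)
      truth_path <- paste0(truth_path, "_truth.json")
    }
    truth <- x$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_plant_table
#' @export
read_plant_table <- function(path) {
  need <- c("family", "replicate", "container", "quadrant", "row", "column",
            "treatment", "shoot_dm_mg", "root_dm_mg")
  plants <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(plants))
  if (length(missing_cols)) {
    stop("plant table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  plants
}
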