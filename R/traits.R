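#' Root to shoot dry-matter ratio
#'
#' Biomass-partitioning indicator: root dry matter divided by shoot dry
#' matter for the same plant. Dimensionless; vectorised.
#'
#' @param root_dm,shoot_dm Dry matter in mg; `shoot_dm` must be positive.
#' @return `root_dm / shoot_dm`.
#' @examples
#' compute_rsr(5.03, 11.4)
#' @export
compute_rsr <- function(root_dm, shoot_dm) {
  ok <- !is.na(shoot_dm)
  if (any(shoot_dm[ok] <= 0)) {
    stop("compute_rsr: shoot_dm must be positive", call. = FALSE)
  }
  root_dm / shoot_dm
}

#' Mean of the uninoculated negative-control bulk
#'
#' The negative control (no Rhizobium, no mineral N) is planted as a
#' balanced bulk of all families, so its mean measures growth from seed
#' reserves alone and carries no family labels.
#'
#' @param records Plant-record data frame (see [read_plant_table()] for the
#'   schema).
#' @param organ `"shoot"` or `"root"`.
#' @return Arithmetic mean dry matter (mg) of the negative-control plants.
#' @export
negative_control_mean <- function(records, organ = c("shoot", "root")) {
  organ <- match.arg(organ)
  col <- paste0(organ, "_dm_mg")
  v <- records[[col]][records$treatment == "NEG"]
  v <- v[!is.na(v)]
  if (!length(v)) {
    stop("negative_control_mean: no negative-control (NEG) records present",
         call. = FALSE)
  }
  mean(v)
}

#' Symbiotic potential of an inoculated plant
#'
#' Percent of the biomass achieved under mineral-N supplementation that an
#' inoculated plant attains, after subtracting the seed-reserve baseline
#' measured on uninoculated plants:
#' `100 * (inoculated - uninoculated_mean) / (positive_mean -
#' uninoculated_mean)`. Values may be negative (plant below the baseline) or
#' exceed 100 (plant outgrows the N-supplemented mean); no truncation is
#' applied. The result is invariant to a common rescaling of all three
#' dry-matter inputs.
#'
#' @param inoculated Dry matter of the inoculated plant(s), mg; vectorised.
#' @param uninoculated_mean Mean dry matter of the uninoculated bulk, mg.
#' @param positive_mean Mean dry matter of the same family under mineral N,
#'   mg; must differ from `uninoculated_mean`.
#' @return Symbiotic potential in percent.
#' @examples
#' symbiotic_potential(11.4, 2.15, 25.1)
#' @export
symbiotic_potential <- function(inoculated, uninoculated_mean, positive_mean) {
  denom <- positive_mean - uninoculated_mean
  if (any(!is.na(denom) & denom == 0)) {
    stop(paste0("symbiotic_potential: positive-control mean equals the ",
                "uninoculated mean (degenerate controls)"), call. = FALSE)
  }
  100 * (inoculated - uninoculated_mean) / denom
}

#' Derive plot-level analysis traits from plant records
#'
#' Converts plant-level dry matter into the five analysis traits and
#' aggregates them to the REML analysis unit, the family x replicate plot
#' (quadrant) mean:
#'
#' * `shoot_dm`, `root_dm` (mg): plot means per treatment arm;
#' * `rsr`: plot mean of per-plant root:shoot ratios (a mean of ratios, not
#'   a ratio of means); plants with non-positive shoot dry matter are
#'   excluded from this trait;
#' * `shoot_sp`, `root_sp` (%): symbiotic potential of inoculated (`TA1`)
#'   plants only, using the family-specific positive-control (`NPLUS`) mean
#'   and the global negative-control bulk mean.
#'
#' With `sp_basis = "plant"` (default) the symbiotic potential is computed
#' per plant and averaged over the plot; with `"plot"` it is applied to the
#' plot-mean dry matter. Because the transform is affine in the inoculated
#' dry matter, the two bases give identical plot values; both are kept so
#' the choice is explicit.
#'
#' If the table has no `NPLUS` records (or no `NEG` records) the symbiotic
#' potential traits are omitted with a warning and the dry-matter traits are
#' still returned; families lacking `NPLUS` records get `NA` symbiotic
#' potential with a warning.
#'
#' @param records Plant-record data frame (schema of [read_plant_table()]).
#' @param sp_basis `"plant"` or `"plot"`; see Details.
#' @return Long data frame of plot observations: `family`, `replicate`,
#'   `treatment`, `row`, `column`, `trait`, `value`, `n_plants`.
#' @export
derive_trait_table <- function(records, sp_basis = c("plant", "plot")) {
  sp_basis <- match.arg(sp_basis)
  need <- c("family", "replicate", "treatment", "shoot_dm_mg", "root_dm_mg")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("derive_trait_table: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("row" %in% names(records))) records$row <- NA_integer_
  if (!("column" %in% names(records))) records$column <- NA_integer_

  fam <- records[records$treatment %in% c("TA1", "NPLUS"), , drop = FALSE]
  fam <- fam[!is.na(fam$family), , drop = FALSE]
  if (!nrow(fam)) stop("derive_trait_table: no family-structured records",
                       call. = FALSE)

  sp_possible <- TRUE
  if (!any(records$treatment == "NEG")) {
    warning("no NEG records: symbiotic potential traits omitted")
    sp_possible <- FALSE
  }
  if (!any(fam$treatment == "NPLUS")) {
    warning("no NPLUS records: symbiotic potential traits omitted")
    sp_possible <- FALSE
  }

  # per-plant trait values
  fam$rsr <- ifelse(fam$shoot_dm_mg > 0,
                    fam$root_dm_mg / fam$shoot_dm_mg, NA_real_)
  if (any(fam$shoot_dm_mg <= 0, na.rm = TRUE)) {
    warning(sprintf(
      "%d plant(s) with non-positive shoot dry matter excluded from RSR",
      sum(fam$shoot_dm_mg <= 0, na.rm = TRUE)))
  }

  if (sp_possible) {
    neg_shoot <- negative_control_mean(records, "shoot")
    neg_root <- negative_control_mean(records, "root")
    np <- fam[fam$treatment == "NPLUS", , drop = FALSE]
    pos_shoot <- tapply(np$shoot_dm_mg, np$family, mean, na.rm = TRUE)
    pos_root <- tapply(np$root_dm_mg, np$family, mean, na.rm = TRUE)
    is_ta1 <- fam$treatment == "TA1"
    fam_chr <- as.character(fam$family)
    ps <- unname(pos_shoot[fam_chr])
    pr <- unname(pos_root[fam_chr])
    no_pos <- is_ta1 & is.na(ps)
    if (any(no_pos)) {
      warning("symbiotic potential unavailable for families without NPLUS ",
              "records: ",
              paste(sort(unique(fam$family[no_pos])), collapse = ", "))
    }
    fam$shoot_sp <- NA_real_
    fam$root_sp <- NA_real_
    ok <- is_ta1 & !is.na(ps)
    if (any(ok)) {
      fam$shoot_sp[ok] <- symbiotic_potential(fam$shoot_dm_mg[ok], neg_shoot,
                                              ps[ok])
      fam$root_sp[ok] <- symbiotic_potential(fam$root_dm_mg[ok], neg_root,
                                             pr[ok])
    }
  }

  plant_traits <- c(shoot_dm = "shoot_dm_mg", root_dm = "root_dm_mg",
                    rsr = "rsr")
  if (sp_possible && sp_basis == "plant") {
    plant_traits <- c(plant_traits, shoot_sp = "shoot_sp", root_sp = "root_sp")
  }

  key <- interaction(fam$family, fam$replicate, fam$treatment, drop = TRUE)
  first <- !duplicated(key)
  base <- fam[first, c("family", "replicate", "treatment", "row", "column")]
  base <- base[order(key[first]), , drop = FALSE]
  lev <- sort(unique(key))

  out <- list()
  for (tn in names(plant_traits)) {
    v <- fam[[plant_traits[[tn]]]]
    m <- tapply(v, key, mean, na.rm = TRUE)
    n <- tapply(!is.na(v), key, sum)
    block <- base
    block$trait <- tn
    block$value <- as.numeric(m[as.character(lev)])
    block$n_plants <- as.integer(n[as.character(lev)])
    if (tn %in% c("shoot_sp", "root_sp")) {
      block <- block[block$treatment == "TA1", , drop = FALSE]
    }
    out[[tn]] <- block
  }

  if (sp_possible && sp_basis == "plot") {
    # apply the definition to the plot-mean dry matter instead
    sm <- out$shoot_dm[out$shoot_dm$treatment == "TA1", , drop = FALSE]
    rm_ <- out$root_dm[out$root_dm$treatment == "TA1", , drop = FALSE]
    ps <- unname(pos_shoot[as.character(sm$family)])
    pr <- unname(pos_root[as.character(rm_$family)])
    sp_s <- sm
    sp_s$trait <- "shoot_sp"
    sp_s$value <- ifelse(is.na(ps), NA_real_,
                         symbiotic_potential(sm$value, neg_shoot, ps))
    sp_r <- rm_
    sp_r$trait <- "root_sp"
    sp_r$value <- ifelse(is.na(pr), NA_real_,
                         symbiotic_potential(rm_$value, neg_root, pr))
    out$shoot_sp <- sp_s
    out$root_sp <- sp_r
  }

  res <- do.call(rbind, out)
  res <- res[, c("family", "replicate", "treatment", "row", "column",
                 "trait", "value", "n_plants")]
  res$value[is.nan(res$value)] <- NA_real_
  rownames(res) <- NULL
  res
}

#' Write a plot-observation table as CSV
#'
#' @param plots Plot-observation data frame from [derive_trait_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(plots, path) {
  write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
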