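#' Lay out a split-plot trial replicate-by-replicate
#'
#' Builds the physical layout of one treatment arm of a controlled-environment
#' trial: per environmental replicate (growth room), containers are arranged
#' on a near-square grid and each container is divided into four quadrants
#' (2 x 2). Every half-sib family is assigned to exactly one quadrant per
#' replicate by a random permutation, and each quadrant inherits a room-level
#' row and column index from its position in the container grid.
#'
#' @param n_families Number of half-sib families to place.
#' @param n_replicates Number of environmental replicates (growth rooms).
#' @param containers_per_replicate Containers available per replicate; each
#'   holds four quadrants, so capacity is `4 * containers_per_replicate`.
#' @param seed Optional integer seed; when given, the assignment permutation
#'   is drawn under a temporary RNG state so the layout is reproducible
#'   without disturbing the caller's RNG.
#'
#' @return A data frame with one row per family x replicate quadrant:
#'   `family`, `replicate`, `container`, `quadrant`, `row`, `column`.
#' @examples
#' d <- make_design(120, 2, 30, seed = 1)
#' table(table(d$family)) # every family appears once per replicate
#' @export
make_design <- function(n_families, n_replicates, containers_per_replicate,
                        seed = NULL) {
  stopifnot(n_families >= 1, n_replicates >= 1, containers_per_replicate >= 1)
  capacity <- 4L * as.integer(containers_per_replicate)
  if (n_families > capacity) {
    stop(sprintf(
      paste0("design capacity exceeded: %d families need at least %d ",
             "containers per replicate (4 quadrants each), but only %d given"),
      n_families, ceiling(n_families / 4), containers_per_replicate
    ), call. = FALSE)
  }
  draw <- function() {
    grid_cols <- ceiling(sqrt(containers_per_replicate))
    grid_rows <- ceiling(containers_per_replicate / grid_cols)
    out <- vector("list", n_replicates)
    for (j in seq_len(n_replicates)) {
      slots <- expand.grid(quadrant = 1:4,
                           container = seq_len(containers_per_replicate))
      slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
      slots <- slots[seq_len(n_families), , drop = FALSE]
      c_row <- (slots$container - 1L) %/% grid_cols + 1L
      c_col <- (slots$container - 1L) %% grid_cols + 1L
      q_row <- (slots$quadrant - 1L) %/% 2L + 1L
      q_col <- (slots$quadrant - 1L) %% 2L + 1L
      out[[j]] <- data.frame(
        family = seq_len(n_families),
        replicate = j,
        container = as.integer(slots$container),
        quadrant = as.integer(slots$quadrant),
        row = 2L * (c_row - 1L) + q_row,
        column = 2L * (c_col - 1L) + q_col
      )
    }
    do.call(rbind, out)
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}
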