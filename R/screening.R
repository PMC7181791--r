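.isVehicle <- function(dose) {
  suppressWarnings(num <- as.numeric(dose))
  (!is.na(num) & num == 0) | tolower(as.character(dose)) == "vehicle"
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two samples. The exact null distribution
#' of U is used when `max(n1, n2) <= exactThreshold` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. The reported U counts pairs won by `x`
#' (U = n1*n2 means every x exceeds every y).
#'
#' @param x,y numeric samples (non-empty).
#' @param exactThreshold largest per-group size for the exact branch.
#' @return a list with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1 exactly
#' @export
mannWhitneyU <- function(x, y, exactThreshold = 8) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= exactThreshold && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # fully tied samples: no evidence either way
  list(U = unname(wt$statistic), p = min(1, p),
       method = if (exact) "exact" else "normal")
}

#' Relative change in contraction amplitude versus vehicle
#'
#' Summarises a drug-screen table: within each experiment the chosen centre
#' (mean or median) of each compound/dose group is normalised to the vehicle
#' centre of the same experiment,
#' `(center_dose - center_vehicle) / center_vehicle`; these per-experiment
#' relative changes are then aggregated across experiments by the same centre
#' statistic. Each dose is additionally compared with the pooled vehicle
#' amplitudes by [mannWhitneyU()]. Normalising per experiment before
#' aggregating makes the summary invariant to experiment-wide rescaling.
#'
#' @param table a data.frame with columns `compound`, `dose`, `amplitude`
#'   and optionally `experiment` (single experiment assumed when absent) and
#'   `well`. Vehicle rows have `dose` equal to 0 or `"vehicle"`.
#' @param center `"mean"` (summaries as mean, spread as SD; default) or
#'   `"median"` (median, spread as MAD).
#' @param adjust `"none"` (unadjusted pairwise p-values, default) or
#'   `"holm"`; when `"holm"`, a clearly-labelled `p_holm` column is added
#'   (adjusted within compound across doses).
#' @param exactThreshold passed to [mannWhitneyU()].
#' @return a data.frame with one row per (compound, dose):
#'   `compound`, `dose`, `relative_change`, `center`, `spread`, `n`, `U`,
#'   `p` (and `p_holm` when requested), doses sorted within compound.
#' @export
relativeChange <- function(table, center = c("mean", "median"),
                           adjust = c("none", "holm"), exactThreshold = 8) {
  center <- match.arg(center)
  adjust <- match.arg(adjust)
  table <- as.data.frame(table)
  need <- c("compound", "dose", "amplitude")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(table$experiment)) table$experiment <- "E1"
  cfun <- if (center == "mean") mean else stats::median
  sfun <- if (center == "mean") stats::sd else stats::mad
  veh <- .isVehicle(table$dose)
  if (!any(veh)) stop("no vehicle rows (dose 0 or 'vehicle') in the table")
  ## per-experiment vehicle centres
  vtab <- table[veh, ]
  vcenter <- tapply(vtab$amplitude, vtab$experiment, cfun)
  if (any(vcenter == 0)) stop("vehicle centre amplitude is zero")
  dosed <- table[!veh, ]
  if (any(suppressWarnings(as.numeric(dosed$dose)) < 0, na.rm = TRUE)) {
    stop("doses must be non-negative")
  }
  groups <- unique(dosed[, c("compound", "dose")])
  num <- suppressWarnings(as.numeric(groups$dose))
  groups <- groups[order(groups$compound, num, groups$dose), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    gc <- groups$compound[i]; gd <- groups$dose[i]
    rows <- dosed[dosed$compound == gc & dosed$dose == gd, ]
    expts <- unique(rows$experiment)
    if (!all(expts %in% names(vcenter))) {
      stop("experiment without vehicle rows: ",
           paste(setdiff(expts, names(vcenter)), collapse = ", "))
    }
    rc <- vapply(expts, function(e) {
      (cfun(rows$amplitude[rows$experiment == e]) - vcenter[[e]]) / vcenter[[e]]
    }, numeric(1))
    mw <- mannWhitneyU(rows$amplitude, vtab$amplitude, exactThreshold)
    data.frame(compound = gc, dose = gd,
               relative_change = cfun(rc),
               center = cfun(rows$amplitude), spread = sfun(rows$amplitude),
               n = nrow(rows), U = mw$U, p = mw$p)
  }))
  if (adjust == "holm") {
    out$p_holm <- unlist(tapply(out$p, out$compound, stats::p.adjust,
                                method = "holm", simplify = FALSE)
                         [unique(out$compound)], use.names = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Automated seeding schedule for a plate
#'
#' Partitions the destination wells of a plate into batches dispensed one
#' robot cycle at a time (wells assigned in plate row-major order, row A
#' column 1 first), with per-well droplet positions cycling north, east,
#' south, west. The default 96 wells in batches of 16 gives the 6-cycle
#' schedule used to seed a full plate while minimising dead volume.
#'
#' @param nWells number of destination wells.
#' @param batchSize wells dispensed per cycle.
#' @param dropsPerWell droplets per well.
#' @param dropVolumeUl droplet volume, uL.
#' @param plateRows,plateCols plate geometry used for well naming.
#' @return a list of class `seedingPlan`: `batches` (list of data.frames
#'   with `well`, `row`, `col`), `dropPositions`, `dropVolumeUl`,
#'   `nBatches`.
#' @examples
#' plan <- seedingPlan(96, 16)
#' plan$nBatches  # 6
#' @export
seedingPlan <- function(nWells, batchSize = 16, dropsPerWell = 4,
                        dropVolumeUl = 2.5, plateRows = 8, plateCols = 12) {
  if (nWells < 1 || batchSize < 1 || dropsPerWell < 1 || dropVolumeUl <= 0) {
    stop("all arguments must be positive")
  }
  if (nWells > plateRows * plateCols) {
    stop("more wells than the plate holds")
  }
  i <- seq_len(nWells) - 1L
  row <- i %/% plateCols + 1L
  col <- i %% plateCols + 1L
  wells <- paste0(LETTERS[row], col)
  batchId <- i %/% batchSize + 1L
  positions <- rep(c("north", "east", "south", "west"),
                   length.out = dropsPerWell)
  plan <- list(
    batches = lapply(split(data.frame(well = wells, row = row, col = col),
                           batchId), function(d) {
      rownames(d) <- NULL
      d
    }),
    dropPositions = positions,
    dropVolumeUl = dropVolumeUl,
    nBatches = as.integer(max(batchId)))
  class(plan) <- "seedingPlan"
  plan
}

#' @export
print.seedingPlan <- function(x, ...) {
  sizes <- vapply(x$batches, nrow, integer(1))
  cat(sprintf(
    "Seeding plan: %d wells in %d batches (sizes %s); %d x %.2g uL drops per well (%s)\n",
    sum(sizes), x$nBatches, paste(sizes, collapse = ", "),
    length(x$dropPositions), x$dropVolumeUl,
    paste(x$dropPositions, collapse = ", ")))
  invisible(x)
}

#' Wells covered by a seeding plan
#'
#' @param plan a `seedingPlan`.
#' @return character vector of all well ids in dispense order.
#' @export
planWells <- function(plan) {
  unlist(lapply(plan$batches, function(b) b$well), use.names = FALSE)
}

#' Read a drug-screen well table from CSV
#'
#' Expects columns `well,compound,dose_molar,amplitude_um,experiment`
#' (vehicle rows have `dose_molar` 0 or `"vehicle"`); returns the internal
#' column naming used by [relativeChange()].
#'
#' @param path path to the CSV file.
#' @return a data.frame with columns `well`, `compound`, `dose`,
#'   `amplitude`, `experiment`.
#' @export
readDoseTable <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("well", "compound", "dose_molar", "amplitude_um")
  if (!all(need %in% names(tab))) {
    stop("dose CSV must have columns ", paste(need, collapse = ", "))
  }
  out <- data.frame(well = tab$well, compound = tab$compound,
                    dose = tab$dose_molar, amplitude = tab$amplitude_um)
  out$experiment <- if (is.null(tab$experiment)) "E1" else tab$experiment
  out
}
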