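#' Population spike-count dataset
#'
#' Bundles the presentations-by-units spike-count matrix for one recording
#' day with its presentation, unit, and trial metadata. Counts are total
#' spikes in a 200 ms response window per stimulus presentation (the window
#' is offset by 60 ms from stimulus onset to absorb response latency; that
#' offset is a property of how the counts were extracted, not of this
#' container).
#'
#' @param counts Non-negative integer matrix, presentations (T) x units (N).
#' @param presentations Data frame with one row per presentation and columns
#'   `presentation_id`, `trial_id`, `block_id`, `cue_side` ("L"/"R" visual
#'   hemifield), `within_trial_index` (0 = first standard of the trial),
#'   `timestamp_s` (strictly increasing), `is_standard` (logical), and
#'   optionally `delta_theta_deg` (orientation change, targets only).
#' @param units Data frame with columns `unit_id`, `hemisphere` ("L"/"R"),
#'   and optionally `sua_mua`.
#' @param trials Data frame with columns `trial_id`, `outcome` (one of
#'   "hit", "miss", "false_alarm", "catch", "invalid"), `target_side`
#'   ("cued", "opposite", "none"), `delta_theta_deg`, `rewarded` (logical).
#'   May be `NULL` when no behavioral record exists.
#'
#' @return An object of class `popgain_dataset`.
#' @export
popgain_dataset <- function(counts, presentations, units, trials = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  if (nrow(presentations) != nrow(counts))
    stop("presentations metadata does not match counts rows")
  if (nrow(units) != ncol(counts))
    stop("units metadata does not match counts columns")
  req_p <- c("presentation_id", "trial_id", "block_id", "cue_side",
             "within_trial_index", "timestamp_s", "is_standard")
  miss <- setdiff(req_p, names(presentations))
  if (length(miss)) stop("presentations lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(units$hemisphere %in% c("L", "R")))
    stop("unit hemisphere labels must be 'L' or 'R'")
  if (!all(presentations$cue_side %in% c("L", "R")))
    stop("cue_side must be 'L' or 'R'")
  if (is.unsorted(presentations$timestamp_s, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  tpb <- tapply(presentations$trial_id, presentations$block_id,
                function(x) length(unique(x)))
  if (any(tpb > 125)) stop("a block contains more than 125 trials")
  colnames(counts) <- units$unit_id
  structure(list(counts = counts,
                 presentations = as.data.frame(presentations),
                 units = as.data.frame(units),
                 trials = if (is.null(trials)) NULL else as.data.frame(trials)),
            class = "popgain_dataset")
}

#' @export
print.popgain_dataset <- function(x, ...) {
  cat(sprintf("popgain_dataset: %d presentations x %d units, %d trials, %d blocks\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$presentations$trial_id)),
              length(unique(x$presentations$block_id))))
  cat(sprintf("  standards: %d (%d after dropping first-of-trial)\n",
              sum(x$presentations$is_standard),
              sum(x$presentations$is_standard &
                  x$presentations$within_trial_index > 0)))
  invisible(x)
}

#' @export
dim.popgain_dataset <- function(x) dim(x$counts)

#' Analysis view of a dataset
#'
#' Restricts a dataset to the presentations and units actually analyzed:
#' standard (non-target) presentations, excluding the first standard of each
#' trial (whose onset transients are atypical), and units whose mean rate
#' exceeds a threshold. The threshold default of 0.1 spikes per 200 ms
#' window corresponds to 0.5 spikes/s.
#'
#' @param dataset A [popgain_dataset].
#' @param min_rate Minimum mean spikes per window for a unit to be kept.
#' @param drop_first_standard Exclude `within_trial_index == 0` rows.
#' @return A `popgain_dataset` restricted to the analysis rows/columns, with
#'   attributes `kept_presentations` and `kept_units` giving the indices
#'   into the parent dataset.
#' @export
analysis_view <- function(dataset, min_rate = 0.1, drop_first_standard = TRUE) {
  p <- dataset$presentations
  keep_t <- p$is_standard
  if (drop_first_standard) keep_t <- keep_t & p$within_trial_index > 0
  y <- dataset$counts[keep_t, , drop = FALSE]
  keep_n <- colMeans(y) > min_rate
  out <- popgain_dataset(y[, keep_n, drop = FALSE],
                         p[keep_t, , drop = FALSE],
                         dataset$units[keep_n, , drop = FALSE],
                         dataset$trials)
  attr(out, "kept_presentations") <- which(keep_t)
  attr(out, "kept_units") <- which(keep_n)
  out
}

#' Per-unit cue indicator matrix
#'
#' Builds the binary T x N cue matrix used throughout the model: entry
#' (t, n) is 1 when the cue on presentation t is directed toward unit n's
#' contralateral visual hemifield (i.e. "cue toward" that unit), 0 otherwise.
#' A unit recorded in the right hemisphere represents the left hemifield,
#' so it is "cued" when `cue_side == "L"`.
#'
#' @param cue_side Character vector ("L"/"R") per presentation.
#' @param hemisphere Character vector ("L"/"R") per unit.
#' @return Binary matrix, presentations x units.
#' @export
cue_indicator <- function(cue_side, hemisphere) {
  contra <- ifelse(hemisphere == "L", "R", "L")
  outer(cue_side, contra, "==") * 1
}

#' Write a dataset bundle to disk as delimited text
#'
#' Four tab-separated files are written under `dir`: `counts.tsv` (header =
#' unit ids, one row per presentation), `presentations.tsv`, `units.tsv`,
#' and `trials.tsv` (if present).
#'
#' @param dataset A [popgain_dataset].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$presentations, file.path(dir, "presentations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$units, file.path(dir, "units.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$trials))
    utils::write.table(dataset$trials, file.path(dir, "trials.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset_bundle()]
#'
#' @param dir Directory containing the bundle.
#' @return A [popgain_dataset].
#' @export
read_dataset_bundle <- function(dir) {
  counts <- as.matrix(utils::read.delim(file.path(dir, "counts.tsv"),
                                        check.names = FALSE))
  pres <- utils::read.delim(file.path(dir, "presentations.tsv"))
  un <- utils::read.delim(file.path(dir, "units.tsv"))
  tf <- file.path(dir, "trials.tsv")
  trials <- if (file.exists(tf)) utils::read.delim(tf) else NULL
  popgain_dataset(counts, pres, un, trials)
}
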