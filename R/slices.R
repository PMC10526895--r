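# Slice display: crossover/concordant partition at an adjustable display
# threshold, and the display-threshold sweep.

#' Partition trials into crossover and concordant subsets
#'
#' At a display threshold C0, a trial is a *crossover* when either its
#' contrast was strictly below C0 yet the participant responded
#' (`crossover_seen`), or its contrast was at or above C0 yet the
#' participant did not respond (`crossover_notseen`). All remaining trials
#' are *concordant*. The three subsets are mutually exclusive and together
#' cover every valid trial; the slice display shows only the crossover
#' subset.
#'
#' @param trials Tibble of valid trials with columns `log_contrast`, `seen`
#'   (and typically position columns carried through).
#' @param display_threshold C0 in log10 Weber contrast.
#' @return A `slice_selection`: the input tibble with an added factor column
#'   `subset` (levels `crossover_seen`, `crossover_notseen`, `concordant`)
#'   and a `display_threshold` column.
#' @export
slice_select <- function(trials, display_threshold) {
  stopifnot(all(c("log_contrast", "seen") %in% names(trials)))
  out <- mutate(
    trials,
    subset = factor(
      dplyr::case_when(
        .data$log_contrast < display_threshold & .data$seen ~ "crossover_seen",
        .data$log_contrast >= display_threshold & !.data$seen ~
          "crossover_notseen",
        TRUE ~ "concordant"
      ),
      levels = c("crossover_seen", "crossover_notseen", "concordant")
    ),
    display_threshold = display_threshold
  )
  structure(out, class = c("slice_selection", class(out)))
}

#' Sweep the display threshold across a contrast range
#'
#' Applies [slice_select()] at every display threshold of an inclusive
#' arithmetic sweep — by default from 0.5 down to -0.5 log units in steps of
#' -0.01, i.e. 101 frames — and reports per-frame subset counts. As C0
#' falls, the crossover-seen count can only shrink and the
#' crossover-not-seen count can only grow.
#'
#' @param trials Valid trials (see [slice_select()]).
#' @param start,stop,step Sweep parameters in log units; `step` must be
#'   nonzero and point from `start` toward `stop`.
#' @return A `slice_sweep` list: `counts` (tibble: frame, display_threshold,
#'   n_crossover_seen, n_crossover_notseen, n_concordant) and `selections`
#'   (list of `slice_selection`, one per frame).
#' @export
slice_sweep <- function(trials, start = 0.5, stop = -0.5, step = -0.01) {
  if (step == 0) abort("`step` must be nonzero.")
  if (sign(stop - start) != 0 && sign(step) != sign(stop - start)) {
    abort("`step` direction is inconsistent with `start` and `stop`.")
  }
  thresholds <- seq(start, stop, by = step)
  selections <- purrr::map(thresholds, function(c0) slice_select(trials, c0))
  counts <- purrr::imap(selections, function(sel, i) {
    tab <- table(sel$subset)
    tibble(
      frame = i,
      display_threshold = thresholds[i],
      n_crossover_seen = as.integer(tab[["crossover_seen"]]),
      n_crossover_notseen = as.integer(tab[["crossover_notseen"]]),
      n_concordant = as.integer(tab[["concordant"]])
    )
  })
  structure(
    list(counts = bind_rows(counts), selections = selections,
         thresholds = thresholds),
    class = "slice_sweep"
  )
}

#' @export
print.slice_sweep <- function(x, ...) {
  cat(sprintf("<slice_sweep> %d frames from %.2f to %.2f\n",
              length(x$thresholds), x$thresholds[1],
              x$thresholds[length(x$thresholds)]))
  invisible(x)
}

#' @describeIn slice_sweep `tidy()` returns the per-frame count table.
#' @param x A `slice_sweep`.
#' @param ... Unused.
#' @method tidy slice_sweep
#' @export
tidy.slice_sweep <- function(x, ...) {
  x$counts
}

#' Heuristic display-threshold chooser
#'
#' The published display thresholds were chosen by eye from the sweep; this
#' optional, unvalidated heuristic picks the sweep threshold whose
#' crossover-not-seen trials are most spatially clustered (smallest mean
#' nearest-neighbour distance), requiring at least `min_points` such trials.
#'
#' @param sweep A [slice_sweep()] result whose trials carry
#'   `inferred_x_deg`/`inferred_y_deg` (or nominal) columns.
#' @param min_points Minimum crossover-not-seen trials for a frame to be
#'   eligible (default 10).
#' @return The selected display threshold (log units), or `NA` when no frame
#'   is eligible.
#' @export
suggest_display_threshold <- function(sweep, min_points = 10) {
  score <- purrr::map_dbl(sweep$selections, function(sel) {
    sel <- ensure_inferred(sel)
    pts <- filter(sel, .data$subset == "crossover_notseen")
    if (nrow(pts) < min_points) return(NA_real_)
    d <- as.matrix(dist(cbind(pts$inferred_x_deg, pts$inferred_y_deg)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  })
  if (all(is.na(score))) return(NA_real_)
  sweep$thresholds[which.min(score)]
}
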