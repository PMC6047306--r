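#' Specification of a (delta, sigma) scenario grid with refinement schedule
#'
#' @param delta Sorted vector of true effect sizes (outcome units).
#' @param sigma Sorted vector of true standard deviations (> 0).
#' @param refine_rounds Number of coarse-to-fine refinement rounds >= 0.
#' @param reps_schedule Monte-Carlo replicates per round; length
#'   \code{refine_rounds + 1}, nondecreasing.
#' @return An object of class \code{"bssr_grid"}.
#' @export
grid_spec <- function(delta, sigma, refine_rounds = 0L,
                      reps_schedule = 1e4) {
  if (!length(delta) || !length(sigma))
    stop("'delta' and 'sigma' must be non-empty", call. = FALSE)
  if (is.unsorted(delta) || is.unsorted(sigma))
    stop("'delta' and 'sigma' must be sorted increasing", call. = FALSE)
  if (any(sigma <= 0)) stop("'sigma' values must be positive", call. = FALSE)
  if (refine_rounds < 0) stop("'refine_rounds' must be >= 0", call. = FALSE)
  if (length(reps_schedule) != refine_rounds + 1)
    stop("'reps_schedule' must have length refine_rounds + 1", call. = FALSE)
  if (is.unsorted(reps_schedule))
    stop("'reps_schedule' must be nondecreasing", call. = FALSE)
  structure(list(delta = delta, sigma = sigma,
                 refine_rounds = as.integer(refine_rounds),
                 reps_schedule = reps_schedule),
            class = "bssr_grid")
}

# objectives available on a scan table
.scan_objectives <- c("abs_bias_mean", "abs_bias_var", "noncover_lower",
                      "noncover_upper", "noncover_two_sided")

# derive a deterministic per-point seed from the base seed
.point_seed <- function(seed, i)
  as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483647)

.scan_table <- function(design, rule, delta, sigma, nrep, seed) {
  pts <- expand.grid(delta = delta, sigma = sigma,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    sc <- bssr_scenario(pts$delta[i], pts$sigma[i])
    s <- simulate_summary(design, sc, rule, nrep,
                          seed = .point_seed(seed, i))
    data.frame(delta = sc$delta, sigma = sc$sigma, nrep = nrep,
               bias_mean = s$bias_mean, bias_mean_se = s$bias_mean_se,
               bias_var = s$bias_var, bias_var_se = s$bias_var_se,
               noncover_lower = 1 - s$cover_lower,
               noncover_lower_se = s$cover_lower_se,
               noncover_upper = 1 - s$cover_upper,
               noncover_upper_se = s$cover_upper_se,
               noncover_two_sided = 1 - s$cover_two_sided,
               noncover_two_sided_se = s$cover_two_sided_se)
  })
  do.call(rbind, rows)
}

.scan_argmax <- function(tab, objective) {
  vals <- if (startsWith(objective, "abs_"))
    abs(tab[[sub("^abs_", "", objective)]])
  else tab[[objective]]
  se <- tab[[paste0(sub("^abs_", "", objective), "_se")]]
  i <- which.max(vals)
  runner <- if (nrow(tab) > 1) max(vals[-i]) else -Inf
  list(objective = objective, value = vals[i], se = se[i],
       delta = tab$delta[i], sigma = tab$sigma[i],
       at_boundary =
         (length(unique(tab$delta)) > 1L &&
            tab$delta[i] %in% range(tab$delta)) ||
         (length(unique(tab$sigma)) > 1L &&
            tab$sigma[i] %in% range(tab$sigma)),
       resolved = (vals[i] - runner) < 3 * se[i] || !is.finite(runner),
       degenerate = vals[i] <= 3 * se[i])
}

#' Evaluate bias and non-coverage over a scenario grid
#'
#' Runs the Monte-Carlo engine at every \code{(delta, sigma)} grid point with
#' the round-0 replicate count, deterministically given \code{seed}, and
#' locates the maximizer of each objective (absolute mean bias, absolute
#' variance bias, and one-/two-sided non-coverage).
#'
#' @param design A [bssr_design()].
#' @param rule A [reassessment_rule()].
#' @param grid A [grid_spec()].
#' @param seed Integer base seed; per-point seeds are derived from it.
#' @return An object of class \code{"bssr_scan"}: list with \code{table}
#'   (one row per grid point), \code{argmax} (one record per objective with
#'   value, standard error, location, at-boundary and degeneracy flags),
#'   \code{design}, \code{rule}, \code{grid}, \code{seed}, \code{round}.
#' @export
evaluate_grid <- function(design, rule, grid, seed = 1L) {
  stopifnot(inherits(design, "bssr_design"), inherits(grid, "bssr_grid"))
  tab <- .scan_table(design, rule, grid$delta, grid$sigma,
                     grid$reps_schedule[1], seed)
  structure(list(table = tab,
                 argmax = lapply(stats::setNames(.scan_objectives,
                                                 .scan_objectives),
                                 function(o) .scan_argmax(tab, o)),
                 design = design, rule = rule, grid = grid,
                 seed = seed, round = 0L),
            class = "bssr_scan")
}

#' Coarse-to-fine refinement of a grid maximum
#'
#' Each round re-grids a shrinking neighborhood (half the current span in
#' each direction, same number of points, clipped to the original outer box)
#' around the current argmax of the chosen objective, using the next — larger
#' — replicate count of the grid's schedule. The reported maximum carries its
#' Monte-Carlo standard error; between rounds it never decreases by more than
#' noise.
#'
#' @param result A \code{"bssr_scan"} from [evaluate_grid()].
#' @param objective One of \code{"abs_bias_mean"}, \code{"abs_bias_var"},
#'   \code{"noncover_lower"}, \code{"noncover_upper"},
#'   \code{"noncover_two_sided"}.
#' @param rounds Number of refinement rounds (at most the grid's
#'   \code{refine_rounds}).
#' @return A refined \code{"bssr_scan"} whose \code{argmax} entry for
#'   \code{objective} reflects the final round; \code{history} records the
#'   maximum per round.
#' @export
refine_maximum <- function(result, objective, rounds = NULL) {
  stopifnot(inherits(result, "bssr_scan"))
  if (!objective %in% .scan_objectives)
    stop("unknown objective '", objective, "'; available: ",
         paste(.scan_objectives, collapse = ", "), call. = FALSE)
  grid <- result$grid
  if (is.null(rounds)) rounds <- grid$refine_rounds
  if (rounds > grid$refine_rounds)
    stop("'rounds' exceeds the grid's refine_rounds", call. = FALSE)
  box_d <- range(grid$delta)
  box_s <- range(grid$sigma)
  cur <- result
  history <- list(cur$argmax[[objective]])
  for (k in seq_len(rounds)) {
    am <- cur$argmax[[objective]]
    span_d <- diff(range(cur$grid$delta)) / 2
    span_s <- diff(range(cur$grid$sigma)) / 2
    dd <- pmin(pmax(seq(am$delta - span_d / 2, am$delta + span_d / 2,
                        length.out = length(grid$delta)),
                    box_d[1]), box_d[2])
    ss <- pmin(pmax(seq(am$sigma - span_s / 2, am$sigma + span_s / 2,
                        length.out = length(grid$sigma)),
                    box_s[1]), box_s[2])
    dd <- sort(unique(dd))
    ss <- sort(unique(ss))
    tab <- .scan_table(cur$design, cur$rule, dd, ss,
                       grid$reps_schedule[k + 1],
                       .point_seed(result$seed, 1000L + k))
    cur$table <- tab
    cur$grid <- grid_spec(dd, ss, 0L, grid$reps_schedule[k + 1])
    cur$grid$reps_schedule <- grid$reps_schedule
    cur$grid$refine_rounds <- grid$refine_rounds
    cur$argmax <- lapply(stats::setNames(.scan_objectives,
                                         .scan_objectives),
                         function(o) .scan_argmax(tab, o))
    cur$round <- k
    history[[k + 1]] <- cur$argmax[[objective]]
  }
  cur$history <- history
  cur
}

#' @export
print.bssr_scan <- function(x, ...) {
  cat(sprintf("Scenario scan: %d grid points, round %d\n",
              nrow(x$table), x$round))
  for (am in x$argmax)
    cat(sprintf(
      "  max %-18s %.5g (se %.2g) at delta=%.3g sigma=%.3g%s%s\n",
      am$objective, am$value, am$se, am$delta, am$sigma,
      if (am$at_boundary) " [boundary]" else "",
      if (am$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Export a scan's maxima as CSV
#'
#' One row per objective with columns \code{n1, rule, objective, max_value,
#' max_se, argmax_delta, argmax_sigma, at_boundary}.
#'
#' @param result A \code{"bssr_scan"}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_scan_csv <- function(result, path) {
  stopifnot(inherits(result, "bssr_scan"))
  rows <- do.call(rbind, lapply(result$argmax, function(am)
    data.frame(n1 = result$design$n1,
               rule = attr(result$rule, "rule_type"),
               objective = am$objective, max_value = am$value,
               max_se = am$se, argmax_delta = am$delta,
               argmax_sigma = am$sigma, at_boundary = am$at_boundary)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
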