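#' Configuration of a credibility-by-reach Monte Carlo sweep
#'
#' The study design: a grid of mean credibility perceptions for the two
#' candidates crossed with a set of reach ratios (broadcast reach divided by
#' the fixed micro-targeting reach), each cell replicated `reps` times with
#' distinct seeds derived from `base_seed`. The defaults reproduce the full
#' design — 3 x 3 credibility means x 10 ratios x 100 repetitions = 9,000
#' runs.
#'
#' @param cred_means_mtc,cred_means_stoch Mean credibility perceptions swept
#'   for each candidate (defaults `c(0.4, 0.5, 0.6)`).
#' @param reach_mtc Fixed daily reach of the micro-targeting candidate
#'   (default 20).
#' @param reach_ratios Broadcast-to-MTC reach ratios (default 0.5 to 5 in
#'   steps of 0.5). Broadcast reach is `round(ratio * reach_mtc)`.
#' @param reps Repetitions per cell (default 100).
#' @param base_seed Integer from which every run's seed is derived.
#' @param n_voters,n_ticks Electorate size and campaign length per run.
#' @param cred_sd Sd of the trust/expertise draws (default 0.25).
#' @param thresholds A [targeting_thresholds()].
#' @param table A [credibility_table()].
#'
#' @return A list of class `sweep_config`.
#' @examples
#' sweep_config(reps = 2, n_voters = 200)
#' @export
sweep_config <- function(cred_means_mtc = c(0.4, 0.5, 0.6),
                         cred_means_stoch = c(0.4, 0.5, 0.6),
                         reach_mtc = 20,
                         reach_ratios = seq(0.5, 5, by = 0.5),
                         reps = 100,
                         base_seed = 1,
                         n_voters = 10000,
                         n_ticks = 50,
                         cred_sd = 0.25,
                         thresholds = targeting_thresholds(),
                         table = credibility_table()) {
  reach_mtc <- check_count(reach_mtc, "reach_mtc", min = 0L)
  reps <- check_count(reps, "reps", min = 1L)
  n_voters <- check_count(n_voters, "n_voters", min = 1L)
  n_ticks <- check_count(n_ticks, "n_ticks", min = 1L)
  if (length(reach_ratios) < 1L || any(reach_ratios <= 0)) {
    abort("`reach_ratios` must be positive.")
  }
  table_rows(table) # validates
  structure(list(cred_means_mtc = cred_means_mtc,
                 cred_means_stoch = cred_means_stoch,
                 reach_mtc = reach_mtc, reach_ratios = reach_ratios,
                 reps = reps, base_seed = base_seed,
                 n_voters = n_voters, n_ticks = n_ticks, cred_sd = cred_sd,
                 thresholds = thresholds, table = table),
            class = "sweep_config")
}

#' Run the credibility-by-reach sweep
#'
#' Executes every (mu_mtc, mu_stoch, ratio, rep) combination of the design
#' as an independent seeded run, aggregates mean MTC vote share per cell,
#' and estimates the break-even reach ratio — where the mean-share curve
#' crosses 0.5 — for each credibility pairing. Each run's seed is a
#' deterministic function of `base_seed` and the run's position in the grid,
#' so the result is independent of execution order and fully reproducible.
#'
#' @param config A [sweep_config()].
#' @param n_workers Number of worker processes; when greater than 1 the runs
#'   are distributed with [parallel::mclapply()] (each run still uses its
#'   own derived seed, so results do not depend on scheduling).
#' @param verbose Print a line per cell as the sweep progresses.
#'
#' @return An object of class `campaign_sweep`: a list with `runs` (one row
#'   per simulation: `mu_mtc`, `mu_stoch`, `ratio`, `rep`, `seed`,
#'   `votes_mtc`, `votes_stoch`, `abstentions`, `share_mtc`), `cells`
#'   (per-cell mean/sd of MTC share), `breakeven` (per credibility pairing)
#'   and `config`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sw <- run_sweep(sweep_config(cred_means_mtc = 0.5, cred_means_stoch = 0.5,
#'                              reach_ratios = c(1, 2), reps = 2,
#'                              n_voters = 200, n_ticks = 10, base_seed = 1))
#' tidy(sw)
#' @export
run_sweep <- function(config, n_workers = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  grid <- tidyr::expand_grid(
    mu_mtc = config$cred_means_mtc,
    mu_stoch = config$cred_means_stoch,
    ratio = config$reach_ratios,
    rep = seq_len(config$reps)
  )
  grid$run_index <- seq_len(nrow(grid))
  grid$seed <- derive_seed(config$base_seed, grid$run_index)

  one_run <- function(i) {
    row <- grid[i, ]
    rc <- run_config(
      population = population_config(
        n_voters = config$n_voters,
        cred_mean_mtc = row$mu_mtc, cred_mean_stoch = row$mu_stoch,
        cred_sd = config$cred_sd
      ),
      candidates = list(
        mtc_candidate(reach = config$reach_mtc),
        stochastic_candidate(reach = round(row$ratio * config$reach_mtc))
      ),
      thresholds = config$thresholds,
      n_ticks = config$n_ticks,
      table = config$table,
      seed = row$seed
    )
    res <- run_simulation(rc)$result
    if (verbose && row$rep == config$reps) {
      message(sprintf("cell (%.2f, %.2f) ratio %.2f done", row$mu_mtc,
                      row$mu_stoch, row$ratio))
    }
    res
  }

  results <- if (n_workers > 1L) {
    parallel::mclapply(seq_len(nrow(grid)), one_run, mc.cores = n_workers)
  } else {
    lapply(seq_len(nrow(grid)), one_run)
  }
  runs <- dplyr::bind_cols(
    grid[c("mu_mtc", "mu_stoch", "ratio", "rep", "seed")],
    dplyr::bind_rows(results)
  )

  cells <- runs |>
    dplyr::group_by(.data$mu_mtc, .data$mu_stoch, .data$ratio) |>
    dplyr::summarise(
      mean_share_mtc = mean(.data$share_mtc),
      sd_share_mtc = stats::sd(.data$share_mtc),
      n_reps = dplyr::n(),
      .groups = "drop"
    )

  breakeven <- cells |>
    dplyr::arrange(.data$mu_mtc, .data$mu_stoch, .data$ratio) |>
    dplyr::group_by(.data$mu_mtc, .data$mu_stoch) |>
    dplyr::group_modify(function(df, key) {
      be <- if (nrow(df) < 2L) NA_real_ else estimate_breakeven(
        tibble(ratio = df$ratio, share_mtc = df$mean_share_mtc)
      )
      tibble(breakeven_ratio = be)
    }) |>
    dplyr::ungroup()

  structure(list(runs = runs, cells = cells, breakeven = breakeven,
                 config = config),
            class = "campaign_sweep")
}

#' Break-even reach ratio of a share-versus-ratio curve
#'
#' Linearly interpolates the mean MTC vote share against the reach ratio and
#' returns the smallest ratio at which the curve crosses 0.5 — the point
#' where the broadcast candidate's greater reach exactly offsets the
#' micro-targeting advantage. Returns `NA` when the curve never crosses 0.5
#' within the swept range.
#'
#' @param curve A data frame with columns `ratio` (strictly increasing) and
#'   `share_mtc`, ordered by ratio.
#' @return A single numeric ratio, or `NA_real_` if there is no crossing.
#' @examples
#' estimate_breakeven(data.frame(ratio = c(1, 2), share_mtc = c(0.6, 0.4)))
#' @export
estimate_breakeven <- function(curve) {
  if (!all(c("ratio", "share_mtc") %in% names(curve))) {
    abort("`curve` needs columns `ratio` and `share_mtc`.")
  }
  r <- curve$ratio
  s <- curve$share_mtc
  if (length(r) < 2L) abort("Need at least two (ratio, share) points.")
  if (is.unsorted(r, strictly = TRUE)) {
    abort("`curve` must be ordered by strictly increasing `ratio`.")
  }
  for (i in seq_along(r)) {
    if (!is.na(s[i]) && s[i] == 0.5) return(r[i])
    if (i < length(r) && !anyNA(s[i:(i + 1)]) &&
        (s[i] - 0.5) * (s[i + 1] - 0.5) < 0) {
      return(r[i] + (0.5 - s[i]) * (r[i + 1] - r[i]) / (s[i + 1] - s[i]))
    }
  }
  NA_real_
}

#' @export
print.campaign_sweep <- function(x, ...) {
  cat("Campaign sweep:", nrow(x$runs), "runs over",
      nrow(x$cells), "cells\n")
  print(x$breakeven)
  invisible(x)
}

#' Per-cell summary of a sweep
#'
#' @param x A `campaign_sweep`.
#' @param ... Unused.
#' @return The cell-level tibble: credibility means, reach ratio, mean and
#'   sd of the MTC share of cast votes, and repetition count.
#' @method tidy campaign_sweep
#' @export
tidy.campaign_sweep <- function(x, ...) x$cells

#' One-row summary of a sweep
#'
#' @param x A `campaign_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with the design dimensions and total run count.
#' @method glance campaign_sweep
#' @export
glance.campaign_sweep <- function(x, ...) {
  tibble(
    n_runs = nrow(x$runs),
    n_cells = nrow(x$cells),
    reps = x$config$reps,
    reach_mtc = x$config$reach_mtc,
    n_voters = x$config$n_voters,
    n_ticks = x$config$n_ticks
  )
}

#' Plot mean MTC vote share against reach ratio
#'
#' One facet per credibility pairing (rows: MTC candidate mean, columns:
#' broadcast candidate mean), with the 0.5 break-even line dashed.
#'
#' @param object A `campaign_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot campaign_sweep
#' @export
autoplot.campaign_sweep <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(.data$ratio, .data$mean_share_mtc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$mu_mtc),
      cols = ggplot2::vars(.data$mu_stoch),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "Reach ratio (broadcast / micro-targeted)",
      y = "Mean MTC share of cast votes"
    ) +
    ggplot2::theme_bw()
}

#' @export
plot.campaign_sweep <- function(x, ...) print(autoplot(x, ...))
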