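# Replicated operating-characteristics simulation.

#' Operating characteristics of a design on one scenario
#'
#' Simulates `n_replicates` independent trials and aggregates the four
#' standard metrics: percentage of correct MTD selection (PCS), mean number
#' of patients treated at the true MTD, risk of overdosing (share of
#' replicates in which strictly more than `f_over` of the treated patients
#' received doses above the true MTD), and risk of underdosing (same with
#' doses below and `f_under`). Early-terminated trials count as incorrect
#' selections, and their realized sample size is the denominator of their
#' allocation fractions.
#'
#' Each replicate runs on its own seed derived from `master_seed`, the
#' scenario label and the design label, so replicate sets are
#' order-independent and adding a scenario to a grid never perturbs the
#' others.
#'
#' @param scenario A [dose_scenario()].
#' @param design A [design_spec()].
#' @param prior A `prior_table` for `*_prior` variants.
#' @param n_replicates Number of simulated trials.
#' @param master_seed Integer master seed.
#' @param f_over,f_under Allocation fractions defining the overdosing and
#'   underdosing risks; default 0.6 each.
#' @param design_label Label used in the output and the per-cell seed;
#'   defaults to the variant name.
#' @return A one-row data.frame of class `oc_metrics` with columns
#'   `design`, `scenario`, `true_mtd`, `pcs_pct`, `mean_n_at_mtd`,
#'   `risk_over_pct`, `risk_under_pct`, `mean_total_n`, `mean_dlt`,
#'   `n_replicates`, `f_over`, `f_under`.
#' @examples
#' sc <- builtin_scenarios(0.2)[["s8"]]
#' run_oc(sc, design_spec(0.2, "boin"), n_replicates = 200, master_seed = 1)
#' @export
run_oc <- function(scenario, design, prior = NULL,
                   n_replicates = 1000L, master_seed = 1L,
                   f_over = 0.6, f_under = 0.6,
                   design_label = design$variant) {
  stopifnot(inherits(scenario, "dose_scenario"), inherits(design, "design_spec"))
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  probs <- scenario$probs
  tb <- .trial_tables(design, prior, length(probs))
  mtd <- scenario$true_mtd
  cell <- .cell_seed(master_seed, scenario$label, design_label)
  m <- 2147483646

  correct <- 0L; over_risk <- 0L; under_risk <- 0L
  n_at_mtd <- 0; tot_n <- 0; tot_dlt <- 0
  for (i in seq_len(n_replicates)) {
    set.seed((cell + i) %% m + 1L)
    r <- .sim_trial(probs, tb, keep_log = FALSE)
    if (!is.na(r$selected_mtd) && r$selected_mtd == mtd) correct <- correct + 1L
    n_at_mtd <- n_at_mtd + r$n[mtd]
    tot_n <- tot_n + r$total_n
    tot_dlt <- tot_dlt + sum(r$y)
    above <- if (mtd < length(probs)) sum(r$n[(mtd + 1L):length(probs)]) else 0L
    below <- if (mtd > 1L) sum(r$n[seq_len(mtd - 1L)]) else 0L
    if (above > f_over * r$total_n) over_risk <- over_risk + 1L
    if (below > f_under * r$total_n) under_risk <- under_risk + 1L
  }
  out <- data.frame(
    design = design_label,
    scenario = scenario$label,
    true_mtd = mtd,
    pcs_pct = 100 * correct / n_replicates,
    mean_n_at_mtd = n_at_mtd / n_replicates,
    risk_over_pct = 100 * over_risk / n_replicates,
    risk_under_pct = 100 * under_risk / n_replicates,
    mean_total_n = tot_n / n_replicates,
    mean_dlt = tot_dlt / n_replicates,
    n_replicates = as.integer(n_replicates),
    f_over = f_over,
    f_under = f_under,
    stringsAsFactors = FALSE
  )
  class(out) <- c("oc_metrics", class(out))
  out
}

#' Operating characteristics over a scenario-by-design grid
#'
#' Runs [run_oc()] for every combination of the supplied scenarios and
#' designs. Each cell is seeded independently from `master_seed` and the
#' two labels, so the whole table is reproducible and insensitive to cell
#' order.
#'
#' @param scenarios A list of [dose_scenario()] objects.
#' @param designs A named list; each element is either a [design_spec()] or
#'   a list with elements `design` and (optionally) `prior`.
#' @inheritParams run_oc
#' @return A long-format data.frame, one row per cell (see [run_oc()]);
#'   reshape with [oc_pivot()].
#' @examples
#' sc <- builtin_scenarios(0.2)[1:2]
#' run_grid(sc, list(boin = design_spec(0.2, "boin")),
#'          n_replicates = 100, master_seed = 1)
#' @export
run_grid <- function(scenarios, designs, n_replicates = 1000L,
                     master_seed = 1L, f_over = 0.6, f_under = 0.6) {
  if (is.null(names(designs)) || any(names(designs) == "")) {
    stop("`designs` must be a fully named list", call. = FALSE)
  }
  rows <- list()
  for (dn in names(designs)) {
    item <- designs[[dn]]
    if (inherits(item, "design_spec")) item <- list(design = item)
    des <- item$design
    pri <- item$prior
    for (sc in scenarios) {
      if (!is.null(pri) && ncol(pri) != length(sc$probs)) {
        stop("prior/scenario dose-count mismatch in cell (", dn, ", ",
             sc$label, ")", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        run_oc(sc, des, pri, n_replicates, master_seed,
               f_over, f_under, design_label = dn)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot a grid of operating characteristics to report layout
#'
#' Reshapes the long table from [run_grid()] into the conventional report
#' layout: one row per design, one column per scenario, plus an `Average`
#' column (unweighted mean over scenarios).
#'
#' @param grid A data.frame from [run_grid()].
#' @param metric Which metric column to pivot (default `"pcs_pct"`).
#' @return A data.frame with a `design` column, one column per scenario
#'   label, and `Average`.
#' @examples
#' sc <- builtin_scenarios(0.2)[1:3]
#' g <- run_grid(sc, list(boin = design_spec(0.2, "boin")),
#'               n_replicates = 100, master_seed = 1)
#' oc_pivot(g)
#' @export
oc_pivot <- function(grid, metric = "pcs_pct") {
  if (!metric %in% names(grid)) {
    stop("unknown metric column: ", metric, call. = FALSE)
  }
  designs <- unique(grid$design)
  scen <- unique(grid$scenario)
  m <- matrix(NA_real_, length(designs), length(scen),
              dimnames = list(NULL, scen))
  for (i in seq_along(designs)) {
    sub <- grid[grid$design == designs[i], ]
    m[i, sub$scenario] <- sub[[metric]]
  }
  out <- data.frame(design = designs, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$Average <- rowMeans(m)
  out
}
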