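# Dose-toxicity scenarios and the packaged simulation-study fixtures.

#' Define a dose-toxicity scenario
#'
#' @param probs Vector of true DLT probabilities per dose, non-decreasing,
#'   in \[0, 1\].
#' @param true_mtd Index of the dose whose true DLT probability is the
#'   design target (the correct selection).
#' @param label Short label used in reports and for per-cell seeding.
#' @return An object of class `dose_scenario`.
#' @examples
#' dose_scenario(c(0.05, 0.1, 0.2, 0.3, 0.35), true_mtd = 3, label = "s8")
#' @export
dose_scenario <- function(probs, true_mtd, label = "scenario") {
  if (!is.numeric(probs) || any(!is.finite(probs)) ||
      any(probs < 0) || any(probs > 1)) {
    stop("`probs` must be DLT probabilities in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(probs)) {
    stop("`probs` must be non-decreasing in dose", call. = FALSE)
  }
  if (!.is_count(true_mtd) || true_mtd < 1 || true_mtd > length(probs)) {
    stop("`true_mtd` must be a dose index", call. = FALSE)
  }
  structure(list(probs = probs, true_mtd = as.integer(true_mtd),
                 label = as.character(label)),
            class = "dose_scenario")
}

#' @export
print.dose_scenario <- function(x, ...) {
  cat(sprintf("<dose_scenario> %s  true MTD = dose %d\n", x$label, x$true_mtd))
  cat("  p =", paste(format(x$probs), collapse = " "), "\n")
  invisible(x)
}

# Ten five-dose scenarios per target; the bolded dose in each row of the
# published study design equals the target exactly.
.scenario_rows <- list(
  `0.2` = list(
    list(c(0.20, 0.22, 0.23, 0.25, 0.27), 1L),
    list(c(0.18, 0.20, 0.22, 0.23, 0.25), 2L),
    list(c(0.17, 0.18, 0.20, 0.22, 0.23), 3L),
    list(c(0.10, 0.15, 0.18, 0.20, 0.22), 4L),
    list(c(0.08, 0.10, 0.15, 0.18, 0.20), 5L),
    list(c(0.20, 0.30, 0.35, 0.40, 0.45), 1L),
    list(c(0.10, 0.20, 0.30, 0.35, 0.40), 2L),
    list(c(0.05, 0.10, 0.20, 0.30, 0.35), 3L),
    list(c(0.01, 0.05, 0.10, 0.20, 0.30), 4L),
    list(c(0.01, 0.05, 0.08, 0.10, 0.20), 5L)
  ),
  `0.3` = list(
    list(c(0.30, 0.33, 0.34, 0.35, 0.36), 1L),
    list(c(0.27, 0.30, 0.33, 0.34, 0.35), 2L),
    list(c(0.26, 0.27, 0.30, 0.33, 0.34), 3L),
    list(c(0.15, 0.20, 0.27, 0.30, 0.33), 4L),
    list(c(0.10, 0.15, 0.20, 0.27, 0.30), 5L),
    list(c(0.30, 0.40, 0.45, 0.50, 0.55), 1L),
    list(c(0.20, 0.30, 0.40, 0.45, 0.50), 2L),
    list(c(0.10, 0.20, 0.30, 0.40, 0.45), 3L),
    list(c(0.05, 0.10, 0.20, 0.30, 0.40), 4L),
    list(c(0.05, 0.10, 0.15, 0.20, 0.30), 5L)
  )
)

#' Packaged dose-toxicity scenarios
#'
#' The ten five-dose scenarios used in the package's operating-
#' characteristics study, for a target DLT rate of 20% or 30%. In each
#' scenario the true MTD's probability equals the target exactly; scenarios
#' 1-5 move the MTD across doses with shallow curves, scenarios 6-10 with
#' steeper ones.
#'
#' @param target Target DLT rate, 0.2 or 0.3.
#' @return A named list of ten [dose_scenario()] objects (`s1`..`s10`).
#' @examples
#' builtin_scenarios(0.2)[["s4"]]
#' @export
builtin_scenarios <- function(target = 0.2) {
  key <- as.character(target)
  if (!key %in% names(.scenario_rows)) {
    stop("packaged scenarios exist for targets 0.2 and 0.3 only",
         call. = FALSE)
  }
  rows <- .scenario_rows[[key]]
  out <- lapply(seq_along(rows), function(i) {
    dose_scenario(rows[[i]][[1]], rows[[i]][[2]],
                  label = sprintf("dlt%d-s%d", round(target * 100), i))
  })
  names(out) <- paste0("s", seq_along(rows))
  out
}

#' All packaged fixtures of the operating-characteristics study
#'
#' One call returns everything needed to replicate the packaged simulation
#' study: both ten-scenario sets, the MTD-confidence vector
#' `pi0 = (0.2, 0.45, 0.7, 0.45, 0.2)` with its guess at dose 3, the prior
#' table elicited from it, and the default design constants
#' (`delta = 0.4 * phi`, `g1 = 0.4`, `g2 = 0.9`, lead-in 6, cohorts of 3,
#' 30 patients).
#'
#' @return A list with elements `scenarios` (list `dlt20`, `dlt30`), `pi0`,
#'   `mtd_guess`, `prior` (the elicited `prior_table`), and `designs` (a
#'   named list of [design_spec()] objects: `boin20`, `aboin20`,
#'   `aboin_prior20`, `boin30`, `aboin30`, `aboin_prior30`).
#' @examples
#' fx <- builtin_fixtures()
#' fx$prior
#' @export
builtin_fixtures <- function() {
  pi0 <- c(0.2, 0.45, 0.7, 0.45, 0.2)
  list(
    scenarios = list(dlt20 = builtin_scenarios(0.2),
                     dlt30 = builtin_scenarios(0.3)),
    pi0 = pi0,
    mtd_guess = 3L,
    prior = elicit_prior_table(pi0, mtd_guess = 3L),
    designs = list(
      boin20        = design_spec(0.2, "boin"),
      aboin20       = design_spec(0.2, "aboin"),
      aboin_prior20 = design_spec(0.2, "aboin_prior"),
      boin30        = design_spec(0.3, "boin"),
      aboin30       = design_spec(0.3, "aboin"),
      aboin_prior30 = design_spec(0.3, "aboin_prior")
    )
  )
}
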