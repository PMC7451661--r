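# Cohort-by-cohort trial conduct: dose decisions, safety elimination,
# lead-in switching, MTD selection, and the single-trial simulator.

#' Create or update a trial state
#'
#' A `trial_state` carries per-dose patient (`n`) and DLT (`y`) counts, the
#' current dose, elimination flags, and the early-termination flag. States
#' are also what the interactive decision helpers ([decide()],
#' [effective_boundaries()], [safety_eliminate()]) consume, so a trial run
#' outside the simulator (a real study) can be driven by constructing
#' states from the observed counts.
#'
#' @param n,y Integer vectors of patients treated and DLTs observed per
#'   dose (`y[j] <= n[j]`).
#' @param current_dose Current dose index.
#' @param eliminated Logical vector of per-dose elimination flags (once a
#'   dose is eliminated all higher doses must be too); defaults to none.
#' @param terminated_early Whether the trial stopped because the lowest
#'   dose was eliminated.
#' @return An object of class `trial_state`.
#' @examples
#' trial_state(n = c(3, 3, 0), y = c(0, 1, 0), current_dose = 2)
#' @export
trial_state <- function(n, y, current_dose = 1L,
                        eliminated = rep(FALSE, length(n)),
                        terminated_early = FALSE) {
  J <- length(n)
  if (length(y) != J || length(eliminated) != J) {
    stop("`n`, `y` and `eliminated` must have one entry per dose",
         call. = FALSE)
  }
  if (any(n < 0) || any(y < 0) || any(y > n)) {
    stop("counts must satisfy 0 <= y[j] <= n[j]", call. = FALSE)
  }
  if (!.is_count(current_dose) || current_dose < 1 || current_dose > J) {
    stop("`current_dose` must be a dose index", call. = FALSE)
  }
  if (any(eliminated) && !all(eliminated[min(which(eliminated)):J])) {
    stop("elimination must include all doses above the lowest eliminated one",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), y = as.integer(y),
                 current_dose = as.integer(current_dose),
                 eliminated = as.logical(eliminated),
                 total_n = sum(as.integer(n)),
                 terminated_early = isTRUE(terminated_early)),
            class = "trial_state")
}

#' @export
print.trial_state <- function(x, ...) {
  cat(sprintf("<trial_state> current dose %d, %d patients%s\n",
              x$current_dose, x$total_n,
              if (x$terminated_early) " (terminated early)" else ""))
  print(data.frame(dose = seq_along(x$n), n = x$n, y = x$y,
                   eliminated = x$eliminated), row.names = FALSE)
  invisible(x)
}

#' Boundaries in effect at a given point of a trial
#'
#' Resolves the lead-in rule: adaptive variants use the fixed pair
#' (evaluated at the one-patient hypothesis rates
#' \eqn{\phi \mp \Delta}) until the trial has treated `lead_in` patients in
#' total, then switch to the shrinking pair at the dose's own `n_j`.
#' Non-adaptive variants always return their fixed (or prior-adjusted)
#' pair. For a dose not yet visited the prior and shrinkage terms are
#' evaluated at `n_j = 1`.
#'
#' @param state A [trial_state()].
#' @param design A [design_spec()].
#' @param prior A `prior_table`, or `NULL` for no-prior variants.
#' @param dose_j Dose whose boundaries are wanted; defaults to the current
#'   dose.
#' @return A `boundary_pair`.
#' @examples
#' st <- trial_state(n = c(3, 0, 0), y = c(0, 0, 0))
#' effective_boundaries(st, design_spec(0.3, "aboin")) # still fixed: 3 < 6
#' @export
effective_boundaries <- function(state, design, prior = NULL,
                                 dose_j = state$current_dose) {
  stopifnot(inherits(state, "trial_state"), inherits(design, "design_spec"))
  n_j <- max(state$n[dose_j], 1L)
  if (.is_adaptive(design) && state$total_n < design$lead_in) {
    return(boin_boundaries(design$phi,
                           design$phi - design$delta1,
                           design$phi + design$delta2))
  }
  .variant_boundaries(design, n_j, prior, dose_j, warn = TRUE)
}

#' Dose-assignment decision for the next cohort
#'
#' Compares the observed DLT rate at the current dose to the boundaries in
#' effect: escalate when \eqn{\hat p_j \le \lambda_1}, de-escalate when
#' \eqn{\hat p_j \ge \lambda_2}, otherwise stay. Edge adjustments: the
#' decision is "stay" when escalation is indicated at the top dose (or the
#' next dose is eliminated) and when de-escalation is indicated at the
#' bottom dose. An eliminated current dose always de-escalates.
#'
#' @inheritParams effective_boundaries
#' @return `"escalate"`, `"stay"`, or `"de-escalate"`.
#' @examples
#' st <- trial_state(n = c(3, 0, 0), y = c(0, 0, 0))
#' decide(st, design_spec(0.3, "boin"))
#' @export
decide <- function(state, design, prior = NULL) {
  stopifnot(inherits(state, "trial_state"), inherits(design, "design_spec"))
  d <- state$current_dose
  if (state$n[d] == 0L) {
    stop("no patients treated at the current dose; a decision needs data",
         call. = FALSE)
  }
  J <- length(state$n)
  if (state$eliminated[d]) {
    return(if (d > 1L) "de-escalate" else "stay")
  }
  bp <- effective_boundaries(state, design, prior, d)
  phat <- state$y[d] / state$n[d]
  if (phat <= bp$lambda1) {
    if (d < J && !state$eliminated[d + 1L]) "escalate" else "stay"
  } else if (phat >= bp$lambda2) {
    if (d > 1L) "de-escalate" else "stay"
  } else {
    "stay"
  }
}

#' Apply the safety elimination rule
#'
#' A dose (and every higher dose) is eliminated when at least three
#' patients have been treated there and the Beta(1 + y, 1 + n - y)
#' posterior puts more than `elimination_cutoff` probability on the DLT
#' rate exceeding the target. If the lowest dose is eliminated the trial
#' terminates with no MTD.
#'
#' @inheritParams effective_boundaries
#' @return An updated [trial_state()]; `terminated_early` is set and the
#'   current dose moved below the eliminated range when applicable.
#' @examples
#' st <- trial_state(n = c(3, 3, 0), y = c(0, 3, 0), current_dose = 2)
#' safety_eliminate(st, design_spec(0.3, "boin"))
#' @export
safety_eliminate <- function(state, design) {
  stopifnot(inherits(state, "trial_state"), inherits(design, "design_spec"))
  J <- length(state$n)
  hit <- which(state$n >= 3L &
                 1 - pbeta(design$phi, state$y + 1, state$n - state$y + 1) >
                   design$elimination_cutoff)
  if (!length(hit)) return(state)
  first <- min(hit)
  state$eliminated[first:J] <- TRUE
  if (first == 1L) {
    state$terminated_early <- TRUE
  } else if (state$current_dose >= first) {
    state$current_dose <- first - 1L
  }
  state
}

# Reference-style isotonic MTD selection from final counts. Posterior-mean
# toxicity estimates under a Beta(0.05, 0.05) prior, pooled monotone by
# PAVA with inverse-posterior-variance weights; a tiny increasing offset
# breaks ties toward the higher dose when the tied estimates sit below the
# target and toward the lower dose otherwise.
.select_mtd_counts <- function(y, n, eliminated, phi) {
  if (eliminated[1L]) return(NA_integer_)
  adm <- which(n > 0L & !eliminated)
  if (!length(adm)) return(NA_integer_)
  ya <- y[adm]; na <- n[adm]
  phat <- (ya + 0.05) / (na + 0.1)
  pvar <- (ya + 0.05) * (na - ya + 0.05) / ((na + 0.1)^2 * (na + 0.1 + 1))
  iso <- .pava(phat, w = 1 / pvar) + seq_along(adm) * 1e-10
  adm[which.min(abs(iso - phi))]
}

#' Select the MTD at the end of a trial
#'
#' Isotonic regression (pool-adjacent-violators) of the per-dose toxicity
#' estimates over all treated, non-eliminated doses; the dose whose
#' monotone estimate is closest to the target is selected. Ties are broken
#' toward the higher dose when the tied estimates are below the target and
#' toward the lower dose otherwise. Returns `NA` when the lowest dose was
#' eliminated (no safe dose).
#'
#' @inheritParams effective_boundaries
#' @return The selected dose index, or `NA_integer_`.
#' @examples
#' st <- trial_state(n = c(9, 9, 9), y = c(0, 2, 4))
#' select_mtd(st, design_spec(0.2, "boin"))
#' @export
select_mtd <- function(state, design) {
  stopifnot(inherits(state, "trial_state"), inherits(design, "design_spec"))
  if (all(state$n == 0L)) {
    stop("no dose was ever treated; nothing to select", call. = FALSE)
  }
  if (state$terminated_early) return(NA_integer_)
  .select_mtd_counts(state$y, state$n, state$eliminated, design$phi)
}

# ---- fast in-simulation machinery -------------------------------------

# Precompute everything the inner loop needs: per-dose lambda matrices for
# n_j = 1..max_n, the lead-in fixed pair, and the elimination count table.
.trial_tables <- function(design, prior, J) {
  if (.needs_prior(design) && is.null(prior)) {
    stop("variant '", design$variant, "' requires a prior table", call. = FALSE)
  }
  if (!is.null(prior) && ncol(prior) != J) {
    stop("prior table covers ", ncol(prior), " doses but the scenario has ",
         J, call. = FALSE)
  }
  N <- design$max_n
  l1 <- matrix(NA_real_, J, N)
  l2 <- matrix(NA_real_, J, N)
  for (j in seq_len(J)) {
    bp <- .variant_boundaries(design, seq_len(N), prior, j, warn = FALSE)
    l1[j, ] <- bp$lambda1
    l2[j, ] <- bp$lambda2
  }
  adaptive <- .is_adaptive(design)
  if (adaptive) {
    fix <- boin_boundaries(design$phi, design$phi - design$delta1,
                           design$phi + design$delta2)
  } else {
    fix <- list(lambda1 = NA_real_, lambda2 = NA_real_)
  }
  list(J = J, l1 = l1, l2 = l2,
       adaptive = adaptive, lead_in = design$lead_in,
       fix1 = fix$lambda1, fix2 = fix$lambda2,
       cohort = design$cohort_size, max_n = design$max_n,
       elim_y = .elimination_boundary(design$phi, design$max_n,
                                      design$elimination_cutoff),
       phi = design$phi)
}

# One simulated trial given precomputed tables. Mirrors decide()/
# safety_eliminate()/select_mtd() exactly but without object overhead.
.sim_trial <- function(probs, tb, keep_log = FALSE) {
  J <- tb$J
  n <- integer(J); y <- integer(J); elim <- rep(FALSE, J)
  d <- 1L; tot <- 0L; stopped <- FALSE
  ncoh <- tb$max_n %/% tb$cohort
  if (keep_log) {
    log_dose <- integer(ncoh); log_n <- integer(ncoh); log_y <- integer(ncoh)
    log_l1 <- numeric(ncoh); log_l2 <- numeric(ncoh)
    log_dec <- character(ncoh)
  }
  k <- 0L
  while (tot + tb$cohort <= tb$max_n) {
    y_new <- rbinom(1L, tb$cohort, probs[d])
    n[d] <- n[d] + tb$cohort
    y[d] <- y[d] + y_new
    tot <- tot + tb$cohort
    k <- k + 1L
    ej <- tb$elim_y[n[d]]
    if (!is.na(ej) && y[d] >= ej) {
      elim[d:J] <- TRUE
      if (keep_log) {
        log_dose[k] <- d; log_n[k] <- n[d]; log_y[k] <- y[d]
        log_l1[k] <- NA_real_; log_l2[k] <- NA_real_
        log_dec[k] <- if (d == 1L) "terminate" else "de-escalate"
      }
      if (d == 1L) { stopped <- TRUE; break }
      d <- d - 1L
      next
    }
    phat <- y[d] / n[d]
    if (tb$adaptive && tot < tb$lead_in) {
      b1 <- tb$fix1; b2 <- tb$fix2
    } else {
      b1 <- tb$l1[d, n[d]]; b2 <- tb$l2[d, n[d]]
    }
    if (phat <= b1) {
      if (d < J && !elim[d + 1L]) { dec <- "escalate"; dn <- d + 1L }
      else { dec <- "stay"; dn <- d }
    } else if (phat >= b2) {
      if (d > 1L) { dec <- "de-escalate"; dn <- d - 1L }
      else { dec <- "stay"; dn <- d }
    } else { dec <- "stay"; dn <- d }
    if (keep_log) {
      log_dose[k] <- d; log_n[k] <- n[d]; log_y[k] <- y[d]
      log_l1[k] <- b1; log_l2[k] <- b2; log_dec[k] <- dec
    }
    d <- dn
  }
  selected <- if (stopped) NA_integer_ else .select_mtd_counts(y, n, elim, tb$phi)
  out <- list(selected_mtd = selected, n = n, y = y, eliminated = elim,
              total_n = tot, terminated_early = stopped)
  if (keep_log) {
    keep <- seq_len(k)
    out$log <- data.frame(dose = log_dose[keep], n_j = log_n[keep],
                          y_j = log_y[keep], lambda1 = log_l1[keep],
                          lambda2 = log_l2[keep], decision = log_dec[keep])
  }
  out
}

#' Simulate one complete trial
#'
#' Runs a trial cohort by cohort on a true dose-toxicity scenario: each
#' cohort's DLTs are Bernoulli draws at the current dose's true rate,
#' followed by the safety-elimination check and the interval decision, then
#' the move. The trial stops when `max_n` patients are treated or the
#' lowest dose is eliminated. The full decision log is returned for
#' auditing: one row per cohort with the dose, cumulative counts, the
#' boundary pair in effect (`NA` on elimination rows) and the decision.
#'
#' @param scenario A [dose_scenario()] (or a bare probability vector, in
#'   which case `true_mtd` is taken as 1).
#' @param design A [design_spec()].
#' @param prior A `prior_table` for `*_prior` variants.
#' @param seed Integer seed making the trial reproducible.
#' @return An object of class `trial_result`: `selected_mtd` (dose index or
#'   `NA`), per-dose `n` and `y`, `eliminated`, `total_n`,
#'   `terminated_early`, and the decision `log` data.frame.
#' @examples
#' sc <- dose_scenario(c(0.05, 0.1, 0.2, 0.3, 0.35), 3, "s8")
#' run_trial(sc, design_spec(0.2, "boin"), seed = 1)
#' @export
run_trial <- function(scenario, design, prior = NULL, seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  if (!inherits(scenario, "dose_scenario")) {
    scenario <- dose_scenario(scenario, true_mtd = 1L)
  }
  tb <- .trial_tables(design, prior, length(scenario$probs))
  set.seed(seed)
  res <- .sim_trial(scenario$probs, tb, keep_log = TRUE)
  res$scenario <- scenario$label
  res$seed <- seed
  class(res) <- "trial_result"
  res
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s: %d patients, selected MTD = %s%s\n",
              x$scenario, x$total_n,
              if (is.na(x$selected_mtd)) "none" else paste("dose", x$selected_mtd),
              if (x$terminated_early) " (terminated early)" else ""))
  print(data.frame(dose = seq_along(x$n), n = x$n, y = x$y,
                   eliminated = x$eliminated), row.names = FALSE)
  invisible(x)
}
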