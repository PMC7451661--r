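#' Specify a dose-finding design
#'
#' Bundles every tuning constant of an interval design variant. The fixed
#' parameterization uses `phi1`/`phi2` (the highest sub-therapeutic and the
#' lowest over-toxic DLT rate); the shrinking parameterization uses effect
#' sizes `delta1`/`delta2` and discount exponents `g1`/`g2`, under which the
#' hypothesized rates at a dose with `n` patients are
#' \eqn{\phi_1 = \phi - \Delta_1 n^{-g_1}} and
#' \eqn{\phi_2 = \phi + \Delta_2 n^{-g_2}}. With the default
#' `delta = 0.4 * phi` the two parameterizations coincide at `n = 1`.
#'
#' @param phi Target DLT probability, in (0, 1).
#' @param variant One of `"boin"`, `"boin_prior"`, `"aboin"`,
#'   `"aboin_prior"`. The `*_prior` variants require a hypothesis prior
#'   table wherever boundaries are evaluated.
#' @param phi1,phi2 Fixed-boundary hypothesis rates; defaults `0.6 * phi`
#'   and `1.4 * phi`.
#' @param delta1,delta2 Shrinking-boundary effect sizes; default
#'   `0.4 * phi` each.
#' @param g1,g2 Discount exponents in (0, 1) controlling how fast the lower
#'   and upper boundary shrink toward `phi`; defaults 0.4 and 0.9 (the
#'   upper boundary tightens faster, penalizing over-dosing).
#' @param lead_in Number of patients treated under fixed boundaries before
#'   shrinking activates (adaptive variants only); default 6.
#' @param cohort_size Patients per cohort; default 3.
#' @param max_n Maximum sample size; default 30.
#' @param elimination_cutoff Posterior probability threshold of the safety
#'   rule; default 0.95.
#'
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(0.3, "boin")
#' design_spec(0.2, "aboin", g1 = 0.4, g2 = 0.9)
#' @export
design_spec <- function(phi,
                        variant = c("boin", "boin_prior", "aboin", "aboin_prior"),
                        phi1 = 0.6 * phi, phi2 = 1.4 * phi,
                        delta1 = 0.4 * phi, delta2 = 0.4 * phi,
                        g1 = 0.4, g2 = 0.9,
                        lead_in = 6L,
                        cohort_size = 3L,
                        max_n = 30L,
                        elimination_cutoff = 0.95) {
  variant <- match.arg(variant)
  if (!.is_prob(phi) || length(phi) != 1L) {
    stop("`phi` must be a single probability in (0, 1)", call. = FALSE)
  }
  if (variant %in% c("boin", "boin_prior")) {
    .check_phi_order(phi, phi1, phi2)
  } else {
    if (delta1 <= 0 || delta2 <= 0) {
      stop("`delta1` and `delta2` must be positive", call. = FALSE)
    }
    if (phi - delta1 <= 0) {
      stop("phi - delta1 must be positive at n = 1; choose a smaller delta1",
           call. = FALSE)
    }
    if (phi + delta2 >= 1) {
      stop("phi + delta2 must be below 1 at n = 1; choose a smaller delta2",
           call. = FALSE)
    }
    if (g1 <= 0 || g1 >= 1 || g2 <= 0 || g2 >= 1) {
      stop("`g1` and `g2` must lie in (0, 1)", call. = FALSE)
    }
  }
  if (!.is_count(lead_in) || lead_in < 0) {
    stop("`lead_in` must be a non-negative integer", call. = FALSE)
  }
  if (!.is_count(cohort_size) || cohort_size < 1) {
    stop("`cohort_size` must be a positive integer", call. = FALSE)
  }
  if (!.is_count(max_n) || max_n < cohort_size) {
    stop("`max_n` must be an integer >= `cohort_size`", call. = FALSE)
  }
  if (!.is_prob(elimination_cutoff) || length(elimination_cutoff) != 1L) {
    stop("`elimination_cutoff` must be a probability in (0, 1)", call. = FALSE)
  }
  structure(
    list(phi = phi, variant = variant,
         phi1 = phi1, phi2 = phi2,
         delta1 = delta1, delta2 = delta2,
         g1 = g1, g2 = g2,
         lead_in = as.integer(lead_in),
         cohort_size = as.integer(cohort_size),
         max_n = as.integer(max_n),
         elimination_cutoff = elimination_cutoff),
    class = "design_spec"
  )
}

.check_phi_order <- function(phi, phi1, phi2) {
  if (!(phi1 > 0)) stop("ordering violated: 0 < phi1", call. = FALSE)
  if (!(phi1 < phi)) stop("ordering violated: phi1 < phi", call. = FALSE)
  if (!(phi < phi2)) stop("ordering violated: phi < phi2", call. = FALSE)
  if (!(phi2 < 1)) stop("ordering violated: phi2 < 1", call. = FALSE)
  invisible(TRUE)
}

.is_adaptive <- function(design) design$variant %in% c("aboin", "aboin_prior")
.needs_prior <- function(design) design$variant %in% c("boin_prior", "aboin_prior")

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> variant=%s  target phi=%.3g\n", x$variant, x$phi))
  if (.is_adaptive(x)) {
    cat(sprintf("  delta1=%.4g delta2=%.4g g1=%.3g g2=%.3g lead_in=%d\n",
                x$delta1, x$delta2, x$g1, x$g2, x$lead_in))
  } else {
    cat(sprintf("  phi1=%.4g phi2=%.4g\n", x$phi1, x$phi2))
  }
  cat(sprintf("  cohort_size=%d max_n=%d elimination_cutoff=%.3g\n",
              x$cohort_size, x$max_n, x$elimination_cutoff))
  invisible(x)
}
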