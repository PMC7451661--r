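# Escalation/de-escalation boundaries for the four design variants.
#
# All four are pure functions of their arguments. The fixed pair is the
# decision-error-minimizing solution under three point hypotheses with
# equal prior weight; the prior-informed pair adds the per-dose log prior
# odds scaled by 1/n_j; the shrinking pair re-evaluates the fixed formulas
# at phi1(n_j) = phi - delta1 * n_j^(-g1), phi2(n_j) = phi + delta2 * n_j^(-g2).

# lambda1: escalate when the observed rate is <= lambda1.
.lambda1 <- function(phi, phi1, prior_term = 0) {
  (log((1 - phi1) / (1 - phi)) + prior_term) /
    log(phi * (1 - phi1) / (phi1 * (1 - phi)))
}

# lambda2: de-escalate when the observed rate is >= lambda2.
.lambda2 <- function(phi, phi2, prior_term = 0) {
  (log((1 - phi) / (1 - phi2)) + prior_term) /
    log(phi2 * (1 - phi) / (phi * (1 - phi2)))
}

.new_boundary_pair <- function(lambda1, lambda2, warn = TRUE) {
  if (warn && any(lambda1 >= lambda2)) {
    warning("lambda1 >= lambda2: the prior overwhelms the likelihood at ",
            "this sample size; decisions will never de-escalate before ",
            "they stop escalating", call. = FALSE)
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2),
            class = "boundary_pair")
}

#' @export
print.boundary_pair <- function(x, ...) {
  cat("<boundary_pair>\n")
  print(data.frame(lambda1 = x$lambda1, lambda2 = x$lambda2), row.names = FALSE)
  invisible(x)
}

#' Fixed optimal interval boundaries
#'
#' The classical interval-design pair \eqn{(\lambda_1, \lambda_2)} that
#' minimizes the probability of an incorrect dose-assignment decision under
#' the point hypotheses \eqn{p_j = \phi}, \eqn{p_j = \phi_1} (sub-therapeutic)
#' and \eqn{p_j = \phi_2} (over-toxic) with equal prior weight:
#' \deqn{\lambda_1 = \frac{\log\frac{1-\phi_1}{1-\phi}}
#'   {\log\frac{\phi(1-\phi_1)}{\phi_1(1-\phi)}}, \qquad
#'   \lambda_2 = \frac{\log\frac{1-\phi}{1-\phi_2}}
#'   {\log\frac{\phi_2(1-\phi)}{\phi(1-\phi_2)}}.}
#' Always \eqn{\lambda_1 < \phi < \lambda_2}.
#'
#' @param phi Target DLT probability.
#' @param phi1,phi2 Hypothesized sub-therapeutic and over-toxic rates,
#'   `0 < phi1 < phi < phi2 < 1`; defaults `0.6 * phi` and `1.4 * phi`.
#' @return A `boundary_pair` with elements `lambda1`, `lambda2`.
#' @examples
#' boin_boundaries(0.3) # lambda1 = 0.2365, lambda2 = 0.3585
#' @export
boin_boundaries <- function(phi, phi1 = 0.6 * phi, phi2 = 1.4 * phi) {
  .check_phi_order(phi, phi1, phi2)
  .new_boundary_pair(.lambda1(phi, phi1), .lambda2(phi, phi2))
}

.check_prior_probs <- function(pi0, pi1, pi2) {
  p <- c(pi0, pi1, pi2)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("prior probabilities must be strictly positive (log odds undefined ",
         "at zero)", call. = FALSE)
  }
  if (any(abs(pi0 + pi1 + pi2 - 1) > 1e-6)) {
    stop("prior probabilities pi0 + pi1 + pi2 must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fixed boundaries incorporating historical information
#'
#' Adds the per-dose log prior odds of the three hypotheses to the fixed
#' pair: the escalation boundary gains \eqn{n_j^{-1}\log(\pi_{1j}/\pi_{0j})}
#' in its numerator and the de-escalation boundary gains
#' \eqn{n_j^{-1}\log(\pi_{0j}/\pi_{2j})}. A prior favouring the under-dose
#' hypothesis therefore eases escalation, and one favouring "this dose is
#' the MTD" resists de-escalation; both effects fade at rate \eqn{1/n_j}
#' and the pair converges to [boin_boundaries()] as \eqn{n_j} grows.
#'
#' @inheritParams boin_boundaries
#' @param n_j Number of patients treated at the dose (>= 1); may be a vector.
#' @param pi0,pi1,pi2 Prior probabilities of the at-MTD, under-dose and
#'   over-dose hypotheses at this dose; strictly positive, summing to 1.
#' @return A `boundary_pair`.
#' @examples
#' prior_boin_boundaries(0.3, n_j = 3, pi0 = 0.7, pi1 = 0.15, pi2 = 0.15)
#' @export
prior_boin_boundaries <- function(phi, phi1 = 0.6 * phi, phi2 = 1.4 * phi,
                                  n_j, pi0, pi1, pi2) {
  .check_phi_order(phi, phi1, phi2)
  .check_prior_probs(pi0, pi1, pi2)
  if (any(n_j < 1)) stop("`n_j` must be >= 1", call. = FALSE)
  .new_boundary_pair(
    .lambda1(phi, phi1, log(pi1 / pi0) / n_j),
    .lambda2(phi, phi2, log(pi0 / pi2) / n_j)
  )
}

.shrunk_phi1 <- function(phi, delta1, g1, n_j) phi - delta1 * n_j^(-g1)
.shrunk_phi2 <- function(phi, delta2, g2, n_j) phi + delta2 * n_j^(-g2)

.check_shrunk <- function(phi1n, phi2n) {
  if (any(phi1n <= 0)) {
    stop("implied phi1 = phi - delta1 * n^(-g1) is <= 0; choose a smaller ",
         "delta1", call. = FALSE)
  }
  if (any(phi2n >= 1)) {
    stop("implied phi2 = phi + delta2 * n^(-g2) is >= 1; choose a smaller ",
         "delta2", call. = FALSE)
  }
  invisible(TRUE)
}

#' Adaptive shrinking boundaries
#'
#' Re-evaluates the fixed-boundary formulas at sample-size-dependent
#' hypothesis rates \eqn{\phi_1(n_j) = \phi - \Delta_1 n_j^{-g_1}} and
#' \eqn{\phi_2(n_j) = \phi + \Delta_2 n_j^{-g_2}}, so the decision interval
#' contracts toward the target as evidence accumulates at the dose. With
#' `delta = 0.4 * phi` and `n_j = 1` the pair equals the classical fixed
#' pair; as `n_j` grows both boundaries converge monotonically to `phi`.
#'
#' @inheritParams prior_boin_boundaries
#' @param delta1,delta2 Effect sizes (> 0); default `0.4 * phi`.
#' @param g1,g2 Discount exponents in (0, 1); larger values shrink the
#'   corresponding boundary faster.
#' @return A `boundary_pair`.
#' @examples
#' aboin_boundaries(0.3, n_j = 1)  # identical to boin_boundaries(0.3)
#' aboin_boundaries(0.3, n_j = 9)
#' @export
aboin_boundaries <- function(phi, delta1 = 0.4 * phi, delta2 = 0.4 * phi,
                             g1 = 0.4, g2 = 0.9, n_j = 1) {
  if (any(n_j < 1)) stop("`n_j` must be >= 1", call. = FALSE)
  phi1n <- .shrunk_phi1(phi, delta1, g1, n_j)
  phi2n <- .shrunk_phi2(phi, delta2, g2, n_j)
  .check_shrunk(phi1n, phi2n)
  .new_boundary_pair(.lambda1(phi, phi1n), .lambda2(phi, phi2n))
}

#' Adaptive shrinking boundaries incorporating historical information
#'
#' Combines the shrinking hypothesis rates of [aboin_boundaries()] with the
#' prior log-odds terms of [prior_boin_boundaries()]. Under a uniform prior
#' it reduces to [aboin_boundaries()]; as \eqn{n_j \to \infty} both the
#' shrinkage and the prior terms vanish and both boundaries tend to `phi`.
#'
#' @inheritParams aboin_boundaries
#' @inheritParams prior_boin_boundaries
#' @return A `boundary_pair`.
#' @examples
#' aboin_prior_boundaries(0.2, n_j = 6, pi0 = 0.7, pi1 = 0.15, pi2 = 0.15)
#' @export
aboin_prior_boundaries <- function(phi, delta1 = 0.4 * phi, delta2 = 0.4 * phi,
                                   g1 = 0.4, g2 = 0.9, n_j = 1,
                                   pi0, pi1, pi2) {
  .check_prior_probs(pi0, pi1, pi2)
  if (any(n_j < 1)) stop("`n_j` must be >= 1", call. = FALSE)
  phi1n <- .shrunk_phi1(phi, delta1, g1, n_j)
  phi2n <- .shrunk_phi2(phi, delta2, g2, n_j)
  .check_shrunk(phi1n, phi2n)
  .new_boundary_pair(
    .lambda1(phi, phi1n, log(pi1 / pi0) / n_j),
    .lambda2(phi, phi2n, log(pi0 / pi2) / n_j)
  )
}

# Variant dispatcher used by the trial engine and decision_table(). Returns
# plain numeric lambda1/lambda2 vectors over n_j for dose `dose`; `prior`
# is a prior_table (or NULL for the no-prior variants). No lead-in logic
# here: this is the per-n_j boundary, not the in-trial effective one.
.variant_boundaries <- function(design, n_j, prior = NULL, dose = 1L,
                                warn = FALSE) {
  if (.needs_prior(design)) {
    if (is.null(prior)) {
      stop("variant '", design$variant, "' requires a prior table",
           call. = FALSE)
    }
    pi0 <- prior["H0", dose]; pi1 <- prior["H1", dose]; pi2 <- prior["H2", dose]
  }
  compute <- function() switch(design$variant,
    boin = boin_boundaries(design$phi, design$phi1, design$phi2),
    boin_prior = prior_boin_boundaries(design$phi, design$phi1, design$phi2,
                                       n_j, pi0, pi1, pi2),
    aboin = aboin_boundaries(design$phi, design$delta1, design$delta2,
                             design$g1, design$g2, n_j),
    aboin_prior = aboin_prior_boundaries(design$phi, design$delta1,
                                         design$delta2, design$g1, design$g2,
                                         n_j, pi0, pi1, pi2)
  )
  bp <- if (warn) compute() else suppressWarnings(compute())
  if (design$variant == "boin") {
    bp$lambda1 <- rep(bp$lambda1, length(n_j))
    bp$lambda2 <- rep(bp$lambda2, length(n_j))
  }
  bp
}

#' Tabulate decisions by patient count
#'
#' Expands a design's boundaries into the look-up table practitioners pin
#' to the protocol: for each per-dose sample size `n_j`, the boundary pair
#' and the DLT counts that trigger escalation (`y <= escalate_if_y_le`),
#' de-escalation (`y >= deescalate_if_y_ge`) and safety elimination
#' (`y >= eliminate_if_y_ge`; `NA` below three patients). For adaptive
#' variants the per-`n_j` shrinking boundaries are shown; the in-trial
#' lead-in switch depends on total accrual and is handled by
#' [effective_boundaries()].
#'
#' @param design A [design_spec()].
#' @param prior A prior table (required by `*_prior` variants).
#' @param dose Dose index whose prior column is used; irrelevant for
#'   no-prior variants.
#' @param n Vector of per-dose sample sizes; defaults to `1:max_n`.
#' @return A data.frame with one row per `n`.
#' @examples
#' decision_table(design_spec(0.3, "boin"), n = 3 * (1:4))
#' @export
decision_table <- function(design, prior = NULL, dose = 1L, n = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(n)) n <- seq_len(design$max_n)
  bp <- .variant_boundaries(design, n, prior, dose, warn = TRUE)
  elim <- .elimination_boundary(design$phi, max(n), design$elimination_cutoff)
  data.frame(
    n_j = n,
    lambda1 = bp$lambda1,
    lambda2 = bp$lambda2,
    escalate_if_y_le = floor(bp$lambda1 * n + 1e-10),
    deescalate_if_y_ge = ceiling(bp$lambda2 * n - 1e-10),
    eliminate_if_y_ge = elim[n]
  )
}
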