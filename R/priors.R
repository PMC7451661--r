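# Hypothesis prior tables and the odds-anchored elicitation algorithm.

#' Construct a hypothesis prior table
#'
#' A 3 x J matrix of prior probabilities \eqn{\pi_{kj}} for the three point
#' hypotheses at each dose j: row `H0` (dose j is the MTD), row `H1` (dose
#' j is sub-therapeutic), row `H2` (dose j is over-toxic). Each column must
#' sum to 1, all entries must lie strictly in (0, 1), the `H1` row must be
#' non-increasing in dose and the `H2` row non-decreasing (higher doses are
#' less plausibly under-dosed and more plausibly over-toxic).
#'
#' @param pi A 3 x J numeric matrix (rows H0, H1, H2 in that order) or a
#'   matrix with rownames `H0`, `H1`, `H2`.
#' @param strict If `TRUE` (default), invalid tables raise an error; the
#'   violations are those reported by [validate_prior_table()].
#' @return A `prior_table` (matrix with class attribute).
#' @examples
#' prior_table(rbind(H0 = c(0.6, 0.6), H1 = c(0.3, 0.2), H2 = c(0.1, 0.2)))
#' @export
prior_table <- function(pi, strict = TRUE) {
  pi <- as.matrix(pi)
  if (nrow(pi) != 3L) stop("`pi` must have 3 rows (H0, H1, H2)", call. = FALSE)
  if (ncol(pi) < 2L) stop("`pi` must cover at least 2 doses", call. = FALSE)
  if (!is.null(rownames(pi)) && all(c("H0", "H1", "H2") %in% rownames(pi))) {
    pi <- pi[c("H0", "H1", "H2"), , drop = FALSE]
  } else {
    rownames(pi) <- c("H0", "H1", "H2")
  }
  colnames(pi) <- paste0("D", seq_len(ncol(pi)))
  out <- structure(pi, class = c("prior_table", "matrix"))
  if (strict) {
    bad <- validate_prior_table(out)
    if (length(bad)) {
      stop("invalid prior table:\n  ", paste(bad, collapse = "\n  "),
           call. = FALSE)
    }
  }
  out
}

#' Validate a hypothesis prior table
#'
#' Checks the `prior_table` invariants and reports every violation instead
#' of raising: column normalization (sum 1 within 1e-9), entries strictly
#' inside (0, 1), `H1` non-increasing and `H2` non-decreasing across doses.
#'
#' @param table A `prior_table` or any 3 x J numeric matrix (rows taken as
#'   H0, H1, H2).
#' @return A character vector of violation messages, empty when the table
#'   is valid. Each message names the constraint and the dose involved.
#' @examples
#' tab <- rbind(H0 = c(0.6, 0.6), H1 = c(0.3, 0.2), H2 = c(0.1, 0.2))
#' validate_prior_table(tab) # character(0)
#' @export
validate_prior_table <- function(table) {
  pi <- unclass(as.matrix(table))
  out <- character(0)
  if (nrow(pi) != 3L) {
    return(sprintf("table must have 3 rows, found %d", nrow(pi)))
  }
  J <- ncol(pi)
  if (!is.numeric(pi) || any(!is.finite(pi))) {
    return("table entries must be finite numbers")
  }
  sums <- colSums(pi)
  for (j in which(abs(sums - 1) > 1e-9)) {
    out <- c(out, sprintf("normalization: column %d sums to %.10g, not 1",
                          j, sums[j]))
  }
  for (j in which(apply(pi <= 0 | pi >= 1, 2, any))) {
    out <- c(out, sprintf(
      "range: column %d has entries outside the open interval (0, 1)", j))
  }
  if (J >= 2L) {
    h1 <- pi[2L, ]
    for (j in which(diff(h1) > 1e-9) + 1L) {
      out <- c(out, sprintf(
        "monotonicity: H1 row increases at dose %d (under-dose probability must be non-increasing)", j))
    }
    h2 <- pi[3L, ]
    for (j in which(diff(h2) < -1e-9) + 1L) {
      out <- c(out, sprintf(
        "monotonicity: H2 row decreases at dose %d (over-dose probability must be non-decreasing)", j))
    }
  }
  out
}

#' Elicit a full prior table from per-dose MTD confidence
#'
#' Expands an investigator's confidence vector for "dose j is the MTD"
#' (the `H0` row) into the complete three-hypothesis table, using odds
#' anchors at the extreme doses and at the best MTD guess:
#'
#' 1. At the lowest dose the under- vs over-dose odds
#'    \eqn{\pi_{1,1}/\pi_{2,1}} are set to `odds_low`, so
#'    \eqn{\pi_{1,1} = (1-\pi_{0,1})\,\mathrm{odds}/(1+\mathrm{odds})};
#'    symmetrically at the highest dose with `odds_high`.
#' 2. At `mtd_guess` the odds are 1, splitting the residual mass equally.
#'    If the guess is the lowest or highest dose, that dose's anchor odds
#'    are forced to 1 (overriding `odds_low`/`odds_high`).
#' 3. The `H1` row between anchors is filled by linear interpolation in
#'    the dose index; the `H2` row is the residual
#'    \eqn{1 - \pi_{0j} - \pi_{1j}}.
#'
#' The defaults `odds_low = 9`, `odds_high = 1/9` split the non-MTD mass
#' 90%/10% at the extremes, reproducing the published convention for this
#' algorithm (nine-to-one odds that the lowest dose is under-dosed).
#'
#' @param pi0 Numeric vector (length J >= 2) of MTD confidences per dose,
#'   all strictly in (0, 1). Must attain its maximum at `mtd_guess` and be
#'   unimodal enough that the interpolated rows stay monotone.
#' @param mtd_guess Index of the dose believed closest to the MTD.
#' @param odds_low Under/over-dose odds anchor at dose 1 (default 9).
#' @param odds_high Anchor at dose J (default 1/9).
#' @return A validated `prior_table`.
#' @examples
#' elicit_prior_table(c(0.2, 0.45, 0.7, 0.45, 0.2), mtd_guess = 3)
#' @export
elicit_prior_table <- function(pi0, mtd_guess, odds_low = 9, odds_high = 1 / 9) {
  J <- length(pi0)
  if (J < 2L) stop("`pi0` must cover at least 2 doses", call. = FALSE)
  if (!.is_prob(pi0)) {
    stop("all `pi0` entries must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!.is_count(mtd_guess) || mtd_guess < 1 || mtd_guess > J) {
    stop("`mtd_guess` must be a dose index in 1..", J, call. = FALSE)
  }
  if (pi0[mtd_guess] < max(pi0) - 1e-12) {
    stop("`pi0` must attain its maximum at `mtd_guess`", call. = FALSE)
  }
  if (odds_low <= 0 || odds_high <= 0) {
    stop("odds anchors must be positive", call. = FALSE)
  }
  m <- as.integer(mtd_guess)
  odds1 <- if (m == 1L) 1 else odds_low
  oddsJ <- if (m == J) 1 else odds_high

  pi1 <- rep(NA_real_, J)
  pi1[1L] <- (1 - pi0[1L]) * odds1 / (1 + odds1)
  pi1[J] <- (1 - pi0[J]) * oddsJ / (1 + oddsJ)
  pi1[m] <- (1 - pi0[m]) / 2  # odds 1 at the MTD guess

  # index-linear interpolation of the under-dose row between anchors
  interp <- function(a, b) {
    if (b - a >= 2L) {
      k <- seq.int(a + 1L, b - 1L)
      pi1[k] <<- pi1[a] + (k - a) / (b - a) * (pi1[b] - pi1[a])
    }
  }
  interp(1L, m)
  interp(m, J)

  pi2 <- 1 - pi0 - pi1
  low <- which(pi2 <= 0)
  if (length(low)) {
    stop("elicited over-dose probability is not positive at dose ",
         paste(low, collapse = ", "),
         "; the pi0 vector leaves no room for the anchor odds", call. = FALSE)
  }
  tab <- rbind(H0 = pi0, H1 = pi1, H2 = pi2)
  bad <- validate_prior_table(tab)
  if (length(bad)) {
    stop("elicited table violates prior constraints:\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
  prior_table(tab, strict = FALSE)
}

#' @export
print.prior_table <- function(x, digits = 4, ...) {
  cat(sprintf("<prior_table> %d doses\n", ncol(x)))
  print(round(unclass(x), digits))
  invisible(x)
}
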