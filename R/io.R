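# Study configuration files and result serialization.

#' Load a study configuration
#'
#' Reads a YAML study description and returns fully validated, default-
#' filled objects ready for [run_grid()]. The file has up to four blocks:
#'
#' ```yaml
#' design:
#'   target: 0.3          # required
#'   variant: aboin       # default boin
#'   # optional overrides: phi1 phi2 delta1 delta2 g1 g2 lead_in
#'   #                     cohort_size max_n elimination_cutoff
#' prior:                 # required by *_prior variants
#'   pi0: [0.2, 0.45, 0.7, 0.45, 0.2]   # either this + mtd_guess ...
#'   mtd_guess: 3
#'   # table: [[...], [...], [...]]     # ... or an explicit 3 x J table
#' scenarios:
#'   fixture: dlt30       # packaged set, or a list of inline scenarios:
#'   # - probs: [0.1, 0.2, 0.3]
#'   #   true_mtd: 2
#'   #   label: custom-1
#' simulation:
#'   replicates: 1000
#'   seed: 2024
#'   f_over: 0.6
#'   f_under: 0.6
#' ```
#'
#' Unset design fields take the package defaults (`phi1 = 0.6 * phi`,
#' `phi2 = 1.4 * phi`, `delta = 0.4 * phi`, `g1 = 0.4`, `g2 = 0.9`,
#' lead-in 6, cohorts of 3, 30 patients). Supplying both `pi0` and `table`
#' in the prior block is an error, as is any dose-count mismatch between
#' blocks.
#'
#' @param path Path to the YAML file.
#' @return A list of class `study_config` with elements `design`
#'   ([design_spec()]), `prior` (`prior_table` or `NULL`), `scenarios`
#'   (list of [dose_scenario()]), and `simulation` (list with `replicates`,
#'   `seed`, `f_over`, `f_under`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$design) || is.null(cfg$design$target)) {
    stop("config error at design.target: a target DLT rate is required",
         call. = FALSE)
  }
  dz <- cfg$design
  args <- list(phi = dz$target, variant = dz$variant %||% "boin")
  for (f in c("phi1", "phi2", "delta1", "delta2", "g1", "g2", "lead_in",
              "cohort_size", "max_n", "elimination_cutoff")) {
    if (!is.null(dz[[f]])) args[[f]] <- dz[[f]]
  }
  design <- do.call(design_spec, args)

  prior <- NULL
  if (!is.null(cfg$prior)) {
    pz <- cfg$prior
    if (!is.null(pz$pi0) && !is.null(pz$table)) {
      stop("config error at prior: supply either pi0 + mtd_guess or an ",
           "explicit table, not both", call. = FALSE)
    }
    if (!is.null(pz$table)) {
      prior <- prior_table(do.call(rbind, pz$table))
    } else if (!is.null(pz$pi0)) {
      if (is.null(pz$mtd_guess)) {
        stop("config error at prior.mtd_guess: required with pi0",
             call. = FALSE)
      }
      prior <- elicit_prior_table(unlist(pz$pi0), pz$mtd_guess,
                                  odds_low = pz$odds_low %||% 9,
                                  odds_high = pz$odds_high %||% (1 / 9))
    }
  }
  if (.needs_prior(design) && is.null(prior)) {
    stop("config error at prior: variant '", design$variant,
         "' requires a prior block", call. = FALSE)
  }

  scenarios <- list()
  if (!is.null(cfg$scenarios)) {
    sz <- cfg$scenarios
    if (!is.null(sz$fixture)) {
      scenarios <- switch(sz$fixture,
        dlt20 = builtin_scenarios(0.2),
        dlt30 = builtin_scenarios(0.3),
        stop("config error at scenarios.fixture: unknown fixture '",
             sz$fixture, "' (use dlt20 or dlt30)", call. = FALSE))
    } else {
      scenarios <- lapply(seq_along(sz), function(i) {
        s <- sz[[i]]
        if (is.null(s$probs) || is.null(s$true_mtd)) {
          stop("config error at scenarios[", i, "]: probs and true_mtd ",
               "are required", call. = FALSE)
        }
        dose_scenario(unlist(s$probs), s$true_mtd,
                      label = s$label %||% paste0("scenario-", i))
      })
      names(scenarios) <- vapply(scenarios, `[[`, "", "label")
    }
  }

  Js <- c(if (!is.null(prior)) ncol(prior),
          vapply(scenarios, function(s) length(s$probs), 1L))
  if (length(unique(Js)) > 1L) {
    stop("config error: inconsistent number of doses across blocks (",
         paste(unique(Js), collapse = " vs "), ")", call. = FALSE)
  }

  sim <- cfg$simulation %||% list()
  structure(
    list(design = design, prior = prior, scenarios = scenarios,
         simulation = list(replicates = sim$replicates %||% 1000L,
                           seed = sim$seed %||% 1L,
                           f_over = sim$f_over %||% 0.6,
                           f_under = sim$f_under %||% 0.6)),
    class = "study_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write simulation results to disk
#'
#' Serializes an operating-characteristics table losslessly: TSV with
#' full-precision (17 significant digits) numbers, or JSON written at full
#' precision. Rounding for display belongs to [oc_pivot()] consumers, not
#' to the stored results.
#'
#' @param metrics A data.frame (e.g. from [run_grid()]).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @seealso [read_results()]
#' @export
write_results <- function(metrics, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(metrics), path, digits = I(17),
                         auto_unbox = TRUE)
  } else {
    out <- as.data.frame(metrics)
    for (cl in names(out)) {
      if (is.double(out[[cl]])) {
        out[[cl]] <- formatC(out[[cl]], digits = 17, format = "g")
      }
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back results written by [write_results()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; guessed from the extension when
#'   missing.
#' @return A data.frame equal (to full floating-point precision) to the
#'   one written.
#' @export
read_results <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  }
}
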