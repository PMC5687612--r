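#' Generate a protocol-ready statistical plan
#'
#' Produces the statistical-considerations text for a clinical trial protocol
#' using a pick-the-winner design: the per-arm Simon two-stage narrative with
#' all bounds and attained error rates, the winner rule with its approximate
#' response-difference interpretation, sample-size bounds, and a joint
#' outcome-probability table for each requested true-rate scenario.
#'
#' @param x A [ptw_design()].
#' @param scenarios A list of `c(pA, pB)` true-rate pairs to tabulate;
#'   `NULL` (default) uses the design's alternative and null; `list()` omits
#'   the scenario section.
#' @param file Optional path; when given the plan text is also written there.
#' @return A character vector of plan lines, class `"ptw_plan"`, invisibly
#'   printable via `print()`/`cat()`.
#' @examples
#' tr <- ptw_design(p0 = 0.2, p1 = 0.4, delta = 0.8)
#' plan <- statistical_plan(tr, scenarios = list())
#' @export
statistical_plan <- function(x, scenarios = NULL, file = NULL) {
  stopifnot(inherits(x, "ptw_design"))
  hA <- x$design_A$hypothesis
  hB <- x$design_B$hypothesis
  arm_text <- function(d, h, label) {
    ch <- d$characteristics
    c(sprintf("Arm %s (Simon %s two-stage design for %.0f%% vs %.0f%% response rate, alpha = %.0f%%, beta = %.0f%%):",
              label, d$kind, 100 * h$p0, 100 * h$p1, 100 * h$alpha, 100 * h$beta),
      sprintf("  %d patients will be enrolled in the first stage. If %d or fewer respond, the arm will be stopped.",
              d$n1, d$r1),
      sprintf("  If %d or more respond, %d additional patients (a total of %d) will be enrolled.",
              d$r1 + 1, d$n2, d$n),
      sprintf("  If the total number of responders is %d or less, the treatment will be considered ineffective.",
              d$r),
      sprintf("  Attained type I error %.1f%%, power %.1f%%, PET(p0) = %.2f, EN(p0) = %.1f patients.",
              100 * ch$attained_alpha, 100 * ch$attained_power, ch$pet0, ch$en0))
  }
  # approximate response difference at the threshold, from the map
  map <- prob_vs_difference_map(x$design_B, x$rule$prior)
  approx_diff <- difference_at_probability(map, x$rule$delta)

  lines <- c(
    "STATISTICAL PLAN: Bayesian pick-the-winner randomized phase II design",
    "",
    "Patients are randomized between two treatment arms, each evaluated by its",
    "own Simon two-stage futility design. An arm passing the second stage is",
    "considered competitive.",
    "",
    arm_text(x$design_A, hA, "A"),
    "",
    arm_text(x$design_B, hB, "B"),
    "",
    "Winner rule:",
    "  If both arms fail at the first or second stage, the trial stops and no",
    "  winner is claimed. If only one arm passes the second stage, that arm is",
    "  the winner. If both arms pass, the winner is decided by the Bayesian",
    "  posterior probability Pr(B > A) computed from independent beta",
    sprintf("  posteriors under the '%s' prior family:", x$rule$prior$family),
    sprintf("  arm B is the winner if Pr(B > A) > %.2f and arm A is the winner if", x$rule$delta),
    sprintf("  Pr(B > A) < %.2f; otherwise no clear winner is declared.", 1 - x$rule$delta),
    sprintf("  A threshold of %.2f corresponds to an observed response-rate difference of about %.0f%%.",
            x$rule$delta, 100 * approx_diff),
    "",
    "Sample size:",
    sprintf("  The total sample size ranges from %d if both arms stop at the first stage",
            x$design_A$n1 + x$design_B$n1),
    sprintf("  through %d if only one arm stops early, to a maximum of %d if both arms complete.",
            min(x$design_A$n1 + x$design_B$n, x$design_A$n + x$design_B$n1),
            x$design_A$n + x$design_B$n))

  if (is.null(scenarios))
    scenarios <- list(c(hA$p0, hB$p1), c(hA$p0, hA$p0))
  for (s in scenarios) {
    oc <- exact_operating_characteristics(x$design_A, x$design_B,
                                          pA = s[1], pB = s[2], rule = x$rule)
    tab <- utils::capture.output(print(round(oc$matrix3x3, 4)))
    lines <- c(lines, "",
               sprintf("Operating characteristics at true response rates A = %.0f%%, B = %.0f%%:",
                       100 * s[1], 100 * s[2]),
               paste0("  ", tab),
               sprintf("  Both arms competitive: %.2f%%. Among all outcomes, arm B is declared",
                       100 * oc$p_both_pass),
               sprintf("  winner with overall probability %.1f%% (local, both passing: %.2f%%);",
                       100 * oc$p_B_winner_overall, 100 * oc$p_B_winner_local),
               sprintf("  arm A %.2f%%; no winner %.2f%%. Expected total sample size %.1f.",
                       100 * oc$p_A_winner_overall, 100 * oc$p_no_winner,
                       oc$en_total))
  }
  if (!is.null(file)) writeLines(lines, file)
  structure(lines, class = "ptw_plan")
}

#' @export
print.ptw_plan <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Read a trial configuration file
#'
#' Reads a YAML or JSON configuration describing a pick-the-winner design.
#' Recognised keys: `p0`, `p1`, `alpha`, `beta`, `delta` (all required),
#' `kind` (`"optimal"`/`"minimax"`, default optimal), `prior` (a mapping with
#' `family` and, per family, `c` or `mean_A`/`mean_B`/`sd`), and `scenarios`
#' (a list of `[pA, pB]` pairs). No defaults are supplied for the required
#' keys.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `"ptw_config"` with elements `p0`, `p1`, `alpha`,
#'   `beta`, `delta`, `kind`, `prior` (a [prior_spec()]) and `scenarios`.
#' @export
read_trial_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("p0", "p1", "alpha", "beta", "delta")
  missing_keys <- setdiff(required, names(raw))
  if (length(missing_keys))
    stop("config is missing required keys: ", paste(missing_keys, collapse = ", "))
  prior <- if (is.null(raw$prior)) prior_spec() else {
    pr <- raw$prior
    prior_spec(family = pr$family %||% "noninformative",
               c = pr$c %||% 1,
               mean_A = pr$mean_A, mean_B = pr$mean_B,
               sd = pr$sd %||% 0.1)
  }
  scenarios <- NULL
  if (!is.null(raw$scenarios)) {
    scenarios <- if (is.matrix(raw$scenarios)) {
      lapply(seq_len(nrow(raw$scenarios)), function(i) as.numeric(raw$scenarios[i, ]))
    } else {
      lapply(raw$scenarios, as.numeric)
    }
  }
  structure(list(p0 = raw$p0, p1 = raw$p1, alpha = raw$alpha, beta = raw$beta,
                 delta = raw$delta, kind = raw$kind %||% "optimal",
                 prior = prior, scenarios = scenarios),
            class = "ptw_config")
}

#' Write a trial configuration file
#'
#' Emits the YAML configuration corresponding to a config list, such that
#' [read_trial_config()] recovers an equivalent configuration.
#'
#' @param config A `"ptw_config"` list (see [read_trial_config()]).
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_trial_config <- function(config, path) {
  pr <- config$prior
  out <- list(p0 = config$p0, p1 = config$p1, alpha = config$alpha,
              beta = config$beta, delta = config$delta, kind = config$kind,
              prior = c(list(family = pr$family),
                        if (pr$family == "moments")
                          list(mean_A = pr$mean_A, mean_B = pr$mean_B, sd = pr$sd)
                        else list(c = pr$c)))
  if (!is.null(config$scenarios)) out$scenarios <- config$scenarios
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
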