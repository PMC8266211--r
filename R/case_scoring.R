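#' The six compared cases
#'
#' Case identifiers for the cross of three constitutive laws (W1, W2, W3)
#' and two fiber architectures (FD1 body-fitted, FD2 circumferential).
#'
#' @return Character vector of case ids in canonical order.
#' @export
case_ids <- function() {
  c("W1FD1", "W2FD1", "W3FD1", "W1FD2", "W2FD2", "W3FD2")
}

#' Criterion direction registry
#'
#' The twelve comparison criteria with their preferred direction:
#' \code{lower} (smaller raw value is better) or \code{higher}. Fixed by
#' the physiological interpretation of each metric: short opening/closing,
#' small regurgitation, small fitting error, homogeneous strain/stress,
#' low RF/TPG/energy loss are good; large orifice, forward flow and EOA
#' are good.
#'
#' @return Named character vector mapping criterion name to direction.
#' @export
criterion_directions <- function() {
  c(ex_vivo_fitting    = "lower",
    opening_orifice    = "higher",
    opening_duration   = "lower",
    closing_duration   = "lower",
    forward_flow       = "higher",
    regurgitation_flow = "lower",
    strain_variation   = "lower",
    stress_variation   = "lower",
    RF                 = "lower",
    TPG                = "lower",
    EOA                = "higher",
    EL                 = "lower")
}

#' Regional variation of a field metric
#'
#' Absolute difference between the belly-region and top-center-region
#' values of a leaflet field (fiber strain or fiber stress) at the closed
#' state — a homogeneity measure; smaller is closer to physiological
#' homeostasis. The absolute value matters: for circumferential
#' architectures the top-center stress can exceed the belly stress.
#'
#' @param belly,top_center region-averaged values; vectorized.
#' @return |belly - top_center|.
#' @export
variation <- function(belly, top_center) {
  stopifnot(all(is.finite(belly)), all(is.finite(top_center)))
  abs(belly - top_center)
}

#' Min-max normalize one criterion across cases
#'
#' Linear rescaling so the best case scores 1 and the worst 0:
#' higher-better uses \eqn{(v - \min)/(\max - \min)}, lower-better
#' \eqn{(\max - v)/(\max - \min)}. If all values are equal every case
#' scores 1 (no information, no penalty).
#'
#' @param values raw metric per case.
#' @param direction "lower" or "higher".
#' @return Scores in [0, 1], same names as \code{values}.
#' @export
normalize_criterion <- function(values, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(values)))
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(stats::setNames(rep(1, length(values)), names(values)))
  }
  s <- (values - rng[1]) / (rng[2] - rng[1])
  if (direction == "lower") s <- 1 - s
  s
}

# round half-up to 2 decimals (printed-table convention); the tiny epsilon
# absorbs binary representation of exact halves like 0.625
round2_half_up <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

#' Build the multi-criteria score table
#'
#' Normalizes each criterion across the six cases with its registered
#' direction, optionally rounds the scores to two decimals (half-up) before
#' totaling — the convention of the published comparison table — sums per
#' case, and ranks the cases from best to worst total.
#'
#' @param raw named list or criteria-by-cases matrix/data.frame of raw
#'   metric values; rows (or list names) are criterion names from
#'   \code{\link{criterion_directions}}, columns the six cases.
#' @param prenormalized optional named list of criteria supplied already as
#'   [0, 1] scores (used for criteria whose raw values are not available);
#'   these bypass normalization.
#' @param round_scores round scores half-up to 2 decimals before totaling
#'   (default TRUE, matching printed-table reproduction).
#' @param require_all error if any of the twelve criteria is missing
#'   (default TRUE).
#' @return An object of class \code{score_table}: \code{scores}
#'   (criteria x cases), \code{totals}, \code{rank} (case ids best first).
#' @export
build_score_table <- function(raw, prenormalized = NULL,
                              round_scores = TRUE, require_all = TRUE) {
  dirs <- criterion_directions()
  cases <- case_ids()
  as_row <- function(x, nm) {
    x <- unlist(x)
    if (length(x) != length(cases)) {
      stop(sprintf("criterion '%s' needs %d values", nm, length(cases)))
    }
    if (!is.null(names(x)) && all(cases %in% names(x))) x <- x[cases]
    stats::setNames(as.numeric(x), cases)
  }
  raw <- if (is.matrix(raw) || is.data.frame(raw)) {
    stats::setNames(lapply(seq_len(nrow(raw)),
                           function(i) as_row(raw[i, ], rownames(raw)[i])),
                    rownames(raw))
  } else {
    lapply(stats::setNames(names(raw), names(raw)),
           function(nm) as_row(raw[[nm]], nm))
  }
  pre <- lapply(stats::setNames(names(prenormalized),
                                names(prenormalized)),
                function(nm) as_row(prenormalized[[nm]], nm))

  unknown <- setdiff(c(names(raw), names(pre)), names(dirs))
  if (length(unknown) > 0) {
    stop("unknown criteria: ", paste(unknown, collapse = ", "))
  }
  overlap <- intersect(names(raw), names(pre))
  if (length(overlap) > 0) {
    stop("criteria given both raw and prenormalized: ",
         paste(overlap, collapse = ", "))
  }
  have <- c(names(raw), names(pre))
  missing <- setdiff(names(dirs), have)
  if (require_all && length(missing) > 0) {
    stop("missing criteria: ", paste(missing, collapse = ", "))
  }

  crits <- intersect(names(dirs), have)   # canonical order
  scores <- matrix(NA_real_, length(crits), length(cases),
                   dimnames = list(crits, cases))
  for (nm in crits) {
    scores[nm, ] <- if (nm %in% names(pre)) pre[[nm]]
                    else normalize_criterion(raw[[nm]], dirs[[nm]])
  }
  if (any(scores < -1e-9 | scores > 1 + 1e-9)) {
    stop("prenormalized scores must lie in [0, 1]")
  }
  if (round_scores) scores <- round2_half_up(scores)
  totals <- colSums(scores)
  structure(list(scores = scores, totals = totals,
                 rank = cases[order(-totals,
                                    match(cases, case_ids()))],
                 rounded = round_scores),
            class = "score_table")
}

#' @export
print.score_table <- function(x, digits = 2, ...) {
  tab <- rbind(x$scores, Total = x$totals)
  print(round(tab, digits))
  cat("rank:", paste(x$rank, collapse = " > "), "\n")
  invisible(x)
}

#' Bundled published comparison metrics for the six cases
#'
#' The raw per-case metrics of the published comparative valve study, as
#' printed: averaged ex vivo fitting errors per law (kPa), opening and
#' closing durations (s), closed-state belly and top-center fiber strain
#' and fiber stress (for the variation criteria), and the four hemodynamic
#' indices. Three criteria whose raw six-case vectors were not printed
#' (opening orifice, forward flow, regurgitation flow) are provided as
#' published normalized scores.
#'
#' @return List with elements \code{raw} (named list of six-vectors, in
#'   the order of \code{\link{case_ids}}) and \code{prenormalized}.
#' @export
av_case_metrics <- function() {
  cases <- case_ids()
  nm <- function(x) stats::setNames(x, cases)
  strain_belly <- nm(c(0.32, 0.25, 0.27, 0.31, 0.28, 0.30))
  strain_top   <- nm(c(0.10, 0.07, -0.04, 0.14, 0.13, -0.01))
  stress_belly <- nm(c(336, 376, 330, 309, 295, 262))
  stress_top   <- nm(c(178, 135, -4, 480, 555, 54))
  list(
    raw = list(
      ex_vivo_fitting  = nm(c(0.7, 0.75, 1.72, 0.7, 0.75, 1.72)),
      opening_duration = nm(c(0.09, 0.1, 0.09, 0.1, 0.09, 0.095)),
      closing_duration = nm(c(0.16, 0.175, 0.2, 0.165, 0.165, 0.16)),
      strain_variation = variation(strain_belly, strain_top),
      stress_variation = variation(stress_belly, stress_top),
      RF  = nm(c(6.73, 4.47, 13.67, 5.22, 4.90, 18.16)),
      TPG = nm(c(4.69, 5.91, 2.28, 3.19, 4.32, 3.66)),
      EOA = nm(c(3.41, 3.00, 4.25, 3.51, 2.95, 3.25)),
      EL  = nm(c(107.04, 106.73, 110.79, 82.95, 92.92, 200.69))
    ),
    prenormalized = list(
      opening_orifice    = nm(c(0.72, 0, 1, 0.92, 0.96, 0.56)),
      forward_flow       = nm(c(1, 0.92, 0.23, 0.10, 0, 0.06)),
      regurgitation_flow = nm(c(0.56, 0.86, 0, 0.86, 1, 0.74))
    ),
    regions = list(strain_belly = strain_belly, strain_top = strain_top,
                   stress_belly = stress_belly, stress_top = stress_top)
  )
}

#' Score table of the published study
#'
#' Convenience wrapper: builds the full twelve-criterion score table from
#' the bundled published metrics (\code{\link{av_case_metrics}}) using the
#' printed-table rounding convention.
#'
#' @return A \code{score_table}.
#' @export
av_reference_score_table <- function() {
  m <- av_case_metrics()
  build_score_table(m$raw, prenormalized = m$prenormalized,
                    round_scores = TRUE)
}

#' Read raw metrics from JSON
#'
#' JSON object keyed by criterion; each entry either an object of
#' case:value pairs or \code{\{"prenormalized": true, "values": \{...\}\}}.
#'
#' @param path JSON file.
#' @return List with \code{raw} and \code{prenormalized}, ready for
#'   \code{\link{build_score_table}}.
#' @export
read_metrics_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  raw <- list(); pre <- list()
  for (nm in names(x)) {
    e <- x[[nm]]
    if (is.list(e) && isTRUE(e$prenormalized)) {
      pre[[nm]] <- unlist(e$values)
    } else if (is.list(e) && !is.null(e$values)) {
      raw[[nm]] <- unlist(e$values)
    } else {
      raw[[nm]] <- unlist(e)
    }
  }
  list(raw = raw, prenormalized = pre)
}

#' Write a score table to JSON
#'
#' @param st \code{score_table}.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
score_table_to_json <- function(st, path = NULL) {
  stopifnot(inherits(st, "score_table"))
  obj <- list(scores = apply(st$scores, 1, as.list, simplify = FALSE),
              totals = as.list(st$totals),
              rank = st$rank)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
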