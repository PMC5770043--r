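# Call-centre analytics: the semester x compliance x zone tabulation of
# referred calls and every rate derived from it. Conventions used throughout
# (documented in the methods vignette): rates are percentages rounded
# half-up to 1 decimal unless stated; ratios to 2 decimals; zone shares of
# compliance use the semester's full complied count (all zones, including
# excluded-zone records) as denominator.

ZONE_LEVELS <- c("green", "yellow", "red", "excluded")

#' Tabulate referred calls by semester, compliance and zone
#'
#' @param calls Tibble of referred call records with columns `semester`
#'   (1-4), `zone` (green/yellow/red/excluded), `complied` (0/1) and
#'   `used_transport` (0/1). All records must have `referred = 1` if the
#'   column is present.
#' @return A `compliance_table`: tibble with one row per occupied
#'   (semester, zone, complied) cell, columns `n` and `n_used`.
#' @export
tabulate_calls <- function(calls) {
  if ("referred" %in% names(calls) && any(calls$referred != 1L)) {
    stop("tabulate_calls expects referred records only", call. = FALSE)
  }
  bad <- !calls$zone %in% ZONE_LEVELS
  if (any(bad)) {
    stop("consistency error: unknown zone label(s): ",
         paste(unique(calls$zone[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(calls$used_transport > calls$complied)) {
    stop("consistency error: transport use without compliance", call. = FALSE)
  }
  tab <- dplyr::summarise(
    dplyr::group_by(calls, semester = .data$semester, zone = .data$zone,
                    complied = .data$complied),
    n = dplyr::n(), n_used = sum(.data$used_transport), .groups = "drop")
  tab <- dplyr::arrange(tab, .data$semester, dplyr::desc(.data$complied),
                        match(.data$zone, ZONE_LEVELS))
  class(tab) <- c("compliance_table", class(tab))
  tab
}

tab_sum <- function(tab, col, ...) {
  sel <- rep(TRUE, nrow(tab))
  filters <- list(...)
  for (nm in names(filters)) {
    if (!is.null(filters[[nm]])) sel <- sel & tab[[nm]] == filters[[nm]]
  }
  sum(tab[[col]][sel])
}

check_denominator <- function(d, what) {
  if (d == 0) stop("undefined rate: zero ", what, " in scope", call. = FALSE)
  d
}

#' Referral compliance rate
#'
#' 100 x complied / referred within the scope, rounded half-up.
#'
#' @param tab A `compliance_table` from [tabulate_calls()].
#' @param by `"overall"`, `"semester"` or `"zone"`.
#' @param digits Decimals to round to (default 1).
#' @return A single percent for `"overall"`, otherwise a tibble with
#'   `referred`, `complied` and `percent` per group.
#' @export
compliance_rate <- function(tab, by = c("overall", "semester", "zone"),
                            digits = 1) {
  by <- match.arg(by)
  if (by == "overall") {
    r <- check_denominator(tab_sum(tab, "n"), "referred calls")
    return(round_half_up(100 * tab_sum(tab, "n", complied = 1L) / r, digits))
  }
  g <- dplyr::summarise(dplyr::group_by(tab, .data[[by]]),
                        referred = sum(.data$n),
                        complied = sum(.data$n[.data$complied == 1L]),
                        .groups = "drop")
  g$percent <- round_half_up(100 * g$complied / g$referred, digits)
  g
}

#' Refusal rate (complement of compliance on the same denominator)
#'
#' @inheritParams compliance_rate
#' @return Percent, 1 dp arithmetic on the shared denominator so that
#'   compliance + refusal = 100.0 exactly.
#' @export
refusal_rate <- function(tab, digits = 1) {
  r <- check_denominator(tab_sum(tab, "n"), "referred calls")
  round_half_up(100 * tab_sum(tab, "n", complied = 0L) / r, digits)
}

#' Project-transport usage rate among compliers
#'
#' 100 x transport users / compliers within the scope. The published
#' headline figure is printed at 0 decimals.
#'
#' @inheritParams compliance_rate
#' @export
transport_usage_rate <- function(tab, by = c("overall", "semester", "zone"),
                                 digits = 1) {
  by <- match.arg(by)
  if (by == "overall") {
    d <- check_denominator(tab_sum(tab, "n", complied = 1L), "complied calls")
    return(round_half_up(100 * tab_sum(tab, "n_used", complied = 1L) / d,
                         digits))
  }
  g <- dplyr::summarise(dplyr::group_by(tab[tab$complied == 1L, ], .data[[by]]),
                        complied = sum(.data$n), used = sum(.data$n_used),
                        .groups = "drop")
  g$percent <- round_half_up(100 * g$used / g$complied, digits)
  g
}

#' A zone's share of a semester's compliers
#'
#' 100 x (zone's complied) / (semester's total complied, all zones), 1 dp.
#'
#' @param tab A `compliance_table`.
#' @param semester Semester 1-4.
#' @param zone Zone label.
#' @export
zone_share_of_compliance <- function(tab, semester, zone) {
  d <- check_denominator(tab_sum(tab, "n", complied = 1L, semester = semester),
                         "complied calls in semester")
  num <- tab_sum(tab, "n", complied = 1L, semester = semester, zone = zone)
  round_half_up(100 * num / d, 1)
}

#' Red-to-yellow transport usage ratio within a semester
#'
#' Ratio of the red zone's transport-user count to the yellow zone's, 2 dp.
#'
#' @inheritParams zone_share_of_compliance
#' @export
usage_ratio_red_yellow <- function(tab, semester) {
  y <- tab_sum(tab, "n_used", complied = 1L, semester = semester,
               zone = "yellow")
  if (y == 0) stop("undefined ratio: no yellow-zone transport use in semester ",
                   semester, call. = FALSE)
  r <- tab_sum(tab, "n_used", complied = 1L, semester = semester, zone = "red")
  round_half_up(r / y, 2)
}

#' Transport-utilisation trend across semesters
#'
#' Per-semester usage percentages among compliers (exact and rounded),
#' pairwise ratios between semesters (2 dp on the exact proportions) and
#' successive percentage-point differences (1 dp on the exact values).
#'
#' @param tab A `compliance_table`.
#' @return List with `percent` (tibble: semester, complied, used, exact,
#'   percent), `ratio` (4x4 matrix, entry \[i, j\] = usage(i)/usage(j)) and
#'   `successive_diff` (percentage-point change from each semester to the
#'   next, 1 dp).
#' @export
utilisation_trend <- function(tab) {
  sems <- sort(unique(tab$semester))
  complied <- vapply(sems, function(s)
    tab_sum(tab, "n", complied = 1L, semester = s), numeric(1))
  used <- vapply(sems, function(s)
    tab_sum(tab, "n_used", complied = 1L, semester = s), numeric(1))
  if (any(complied == 0)) {
    stop("undefined trend: a semester has no complied calls", call. = FALSE)
  }
  exact <- 100 * used / complied
  ratio <- round_half_up(outer(exact, exact, "/"), 2)
  dimnames(ratio) <- list(paste0("S", sems), paste0("S", sems))
  list(
    percent = tibble::tibble(semester = sems, complied = complied,
                             used = used, exact = exact,
                             percent = round_half_up(exact, 1)),
    ratio = ratio,
    successive_diff = round_half_up(diff(exact), 1)
  )
}

#' The full derived-statistics set
#'
#' Computes every summary the call-centre analysis reports: totals,
#' compliance/refusal, overall and per-semester transport usage, third
#' semester zone shares of compliance, red:yellow usage ratios and the
#' utilisation trend ratios.
#'
#' @param tab A `compliance_table`.
#' @param semester_totals Optional tibble (semester, complied = 1, n,
#'   n_used) of authoritative per-semester complier/user totals to base
#'   the trend statistics on. Defaults to the totals implied by `tab`;
#'   supply this when the source tabulation's printed total rows disagree
#'   with its zone rows (see [table_fixtures()]).
#' @return Named list of scalars and small tibbles, JSON-serialisable.
#' @export
referral_statistics <- function(tab, semester_totals = NULL) {
  trend_src <- if (is.null(semester_totals)) tab else semester_totals
  trend <- utilisation_trend(trend_src)
  sems <- sort(unique(tab$semester))
  n_complied <- tab_sum(tab, "n", complied = 1L)
  n_used <- tab_sum(trend_src, "n_used", complied = 1L)
  list(
    n_referred = tab_sum(tab, "n"),
    n_complied = n_complied,
    n_used_transport = n_used,
    compliance_pct = compliance_rate(tab),
    refusal_pct = refusal_rate(tab),
    usage_pct_0dp = round_half_up(100 * n_used / n_complied, 0),
    usage_pct_by_semester = trend$percent$percent,
    zone_share_s3_yellow = zone_share_of_compliance(tab, 3, "yellow"),
    zone_share_s3_red = zone_share_of_compliance(tab, 3, "red"),
    usage_ratio_red_yellow = vapply(sems, function(s)
      usage_ratio_red_yellow(tab, s), numeric(1)),
    trend_ratio_last_vs = trend$ratio[length(sems), -length(sems)],
    usage_diff_s1_s2 = -trend$successive_diff[1]
  )
}
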