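#' Preference index of a two-target plate
#'
#' `PI = (T - C) / (T + C)`, the normalized imbalance of worms reaching
#' the test versus control circle: +1 = all worms at the test circle,
#' -1 = all at the control circle, 0 = no preference.
#'
#' @param count_target worms in the test circle (T).
#' @param count_control worms in the control circle (C).
#' @return the preference index, in \[-1, 1\].
#' @examples
#' preference_index(15, 5)  # 0.5
#' @export
preference_index <- function(count_target, count_control) {
  if (anyNA(c(count_target, count_control)) ||
      count_target < 0 || count_control < 0)
    stop("counts must be nonnegative", call. = FALSE)
  total <- count_target + count_control
  if (any(total == 0))
    stop("preference index undefined: no worms reached either circle",
         call. = FALSE)
  (count_target - count_control) / total
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic is
#' reported for `x` against `y` (number of pairs with `x > y`, ties
#' counting one half). The p-value is exact by full enumeration of all
#' `choose(n1 + n2, n1)` rank allocations when `min(n1, n2) <= 8` and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric vectors (e.g. per-plate preference indices).
#' @return list with `u`, `p` (two-sided), `n1`, `n2`, `method`
#'   (`"exact"` or `"normal approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || anyNA(x) || anyNA(y))
    stop("both groups must be nonempty and free of NA", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)
  if (min(n1, n2) <= 8 && !has_ties) {
    # exact null distribution of U over every rank allocation to group x
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(seq_len(n)[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    p <- if (u == mid) 1 else if (u < mid) 2 * mean(u_all <= u) else
      2 * mean(u_all >= u)
    p <- min(p, 1)
    method <- "exact"
  } else {
    # normal approximation, tie-corrected variance, continuity correction
    z <- u - n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - tie_term))
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    method <- "normal approximation"
  }
  list(u = u, p = p, n1 = n1, n2 = n2, method = method)
}

.plates_by_condition <- function(plates) {
  conds <- vapply(plates, `[[`, character(1), "condition")
  split(plates, factor(conds, levels = unique(conds)))
}

#' Analyze a two-target magnet/chemotaxis assay
#'
#' Computes per-plate preference indices by condition and compares the
#' magnet and diacetyl groups against the control group with the
#' two-sided [mann_whitney_u()] test. No multiple-testing adjustment is
#' applied. Plates where no worm reached either circle have an undefined
#' preference index and are dropped with a warning.
#'
#' @param plates list of [magnet_plate()] objects.
#' @return list of class `magnet_report`: per-condition PI lists, group
#'   sizes, and one `u`/`p` entry per comparison performed.
#' @export
magnet_assay_analysis <- function(plates) {
  stopifnot(length(plates) > 0)
  undef <- vapply(plates, function(p) is.na(p$pi), logical(1))
  if (any(undef)) {
    warning(sprintf("dropping %d plate(s) with undefined preference index: %s",
                    sum(undef),
                    paste(vapply(plates[undef], `[[`, character(1), "plate_id"),
                          collapse = ", ")))
    plates <- plates[!undef]
  }
  groups <- .plates_by_condition(plates)
  pis <- lapply(groups, function(g) vapply(g, `[[`, numeric(1), "pi"))
  comparisons <- list()
  for (cond in intersect(c("magnet", "diacetyl"), names(pis))) {
    if (!"control" %in% names(pis)) break
    mw <- mann_whitney_u(pis[[cond]], pis[["control"]])
    comparisons[[paste0(cond, "_vs_control")]] <- mw
  }
  structure(
    list(schema_version = REPORT_SCHEMA_VERSION,
         assay = "magnet",
         pi = pis,
         group_sizes = lapply(pis, length),
         comparisons = comparisons),
    class = "magnet_report"
  )
}

#' @export
print.magnet_report <- function(x, ...) {
  cat("Two-target assay report\n")
  for (cond in names(x$pi))
    cat(sprintf("  %s: n = %d plates, median PI = %.3f\n", cond,
                length(x$pi[[cond]]), stats::median(x$pi[[cond]])))
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    cat(sprintf("  %s: U = %g, two-sided p = %.4g (%s)\n", nm, cc$u, cc$p,
                cc$method))
  }
  invisible(x)
}

#' Analyze a horizontal-field orientation assay
#'
#' The full second-order analysis. Plates are filtered with
#' [filter_plates()]; for each condition the mean vector of each kept
#' plate is computed by vector summation of its worm headings; the plate
#' mean directions, taken as unit vectors, form the second-order sample on
#' which the mean vector, [rayleigh_test()] and [bootstrap_r_ci()] are
#' computed (so `n` is the number of kept plates, never the number of
#' worms). If a zero-field group is present, its second-order directedness
#' `r` is checked against the bootstrap interval of every magnetic
#' condition with [ci_contains()]: a magnetic group whose interval lies
#' entirely above the zero-field `r` is significantly more directed.
#'
#' @param plates list of [field_plate()] objects.
#' @param filters a [filter_config()].
#' @param n_reps bootstrap resamples per condition. Default 100,000.
#' @param seed integer seed; each condition's bootstrap uses a distinct
#'   stream derived from it.
#' @return list of class `field_report` with per-condition summaries,
#'   cross-condition directedness verdicts, the filtering summary, and
#'   the balance verdict.
#' @export
field_assay_analysis <- function(plates, filters = filter_config(),
                                 n_reps = 1e5, seed = 1) {
  stopifnot(length(plates) > 0)
  flt <- filter_plates(plates, filters)
  conds_in <- unique(vapply(plates, `[[`, character(1), "condition"))
  kept_groups <- .plates_by_condition(flt$kept)
  for (cond in conds_in) {
    n_kept <- if (cond %in% names(kept_groups)) length(kept_groups[[cond]]) else 0L
    if (n_kept < 2)
      stop(sprintf(
        "condition '%s' has %d plate(s) after filtering; at least 2 required",
        cond, n_kept), call. = FALSE)
  }
  per_condition <- list()
  for (ci in seq_along(kept_groups)) {
    cond <- names(kept_groups)[ci]
    grp <- kept_groups[[cond]]
    plate_summaries <- lapply(grp, function(p) mean_vector(p$headings))
    defined <- vapply(plate_summaries, `[[`, logical(1), "mu_defined")
    if (!all(defined))
      warning(sprintf("%d plate(s) in '%s' have undefined mean direction (r = 0); excluded from the second-order sample",
                      sum(!defined), cond))
    plate_mus <- vapply(plate_summaries[defined], `[[`, numeric(1), "mu_deg")
    second_order_sample <- angle_sample(plate_mus)
    boot_seed <- seed + match(cond, FIELD_CONDITIONS)
    per_condition[[cond]] <- list(
      plate_ids = vapply(grp, `[[`, character(1), "plate_id"),
      plate_summaries = lapply(plate_summaries, unclass),
      second_order = unclass(mean_vector(second_order_sample)),
      rayleigh = unclass(rayleigh_test(second_order_sample)),
      bootstrap_ci = unclass(bootstrap_r_ci(second_order_sample,
                                            n_reps = n_reps,
                                            seed = boot_seed))
    )
  }
  cross <- list()
  if ("zero" %in% names(per_condition)) {
    r_zero <- per_condition[["zero"]]$second_order$r
    for (cond in setdiff(names(per_condition), "zero")) {
      ci_obj <- structure(per_condition[[cond]]$bootstrap_ci,
                          class = "bootstrap_ci")
      cross[[cond]] <- c(ci_contains(ci_obj, r_zero),
                         list(ci_lower = ci_obj$lower, ci_upper = ci_obj$upper))
    }
  }
  structure(
    list(schema_version = REPORT_SCHEMA_VERSION,
         assay = "field",
         seed = as.integer(seed),
         n_boot_reps = as.integer(n_reps),
         filters = unclass(filters),
         filtering = list(
           n_input = length(plates),
           n_kept = length(flt$kept),
           n_excluded = length(plates) - length(flt$kept),
           exclusions = flt$exclusions),
         balance = balance_check(flt$kept),
         conditions = per_condition,
         zero_r_containment = cross),
    class = "field_report"
  )
}

#' @export
print.field_report <- function(x, ...) {
  cat(sprintf("Horizontal-field assay report (%d/%d plates kept)\n",
              x$filtering$n_kept, x$filtering$n_input))
  for (cond in names(x$conditions)) {
    rl <- x$conditions[[cond]]$rayleigh
    ci <- x$conditions[[cond]]$bootstrap_ci
    cat(sprintf("  %s: n = %d plates, r = %.3f, Z = %.2f, p = %.3f, 95%% CI r [%.3f, %.3f]\n",
                cond, rl$n, rl$r, rl$z, rl$p, ci$lower, ci$upper))
  }
  for (cond in names(x$zero_r_containment))
    cat(sprintf("  zero-field r vs %s CI: %s\n", cond,
                x$zero_r_containment[[cond]]$verdict))
  cat(sprintf("  balance: %s (chi-square p = %.3f)\n", x$balance$verdict,
              x$balance$p))
  invisible(x)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write an assay report to JSON
#'
#' Serializes a [magnet_assay_analysis()] or [field_assay_analysis()]
#' report to a schema-versioned JSON document with every statistic, CI,
#' filter decision and seed at full double precision, plus the package
#' version. Identical reports serialize to byte-identical files.
#'
#' @param report a `magnet_report` or `field_report`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
render_report <- function(report, path) {
  if (!inherits(report, c("magnet_report", "field_report")))
    stop("report must come from magnet_assay_analysis() or field_assay_analysis()",
         call. = FALSE)
  doc <- unclass(report)
  doc$software <- list(package = "magtaxis",
                       version = as.character(utils::packageVersion("magtaxis")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an assay report back from JSON
#'
#' @param path a file written by [render_report()].
#' @return the report as a plain list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
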