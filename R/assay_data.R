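#' @name assay-conditions
#' @title Condition labels
#' @description
#' The horizontal-field assay uses the closed set `zero`, `field1`,
#' `field2` (near-zero field, Earth-strength horizontal field, and the
#' same field rotated 90 degrees). The two-target assay uses `magnet`,
#' `control`, `diacetyl` (neodymium magnet vs aluminum sham, double-sham
#' control, and the chemoattractant positive control).
#' @keywords internal
NULL

FIELD_CONDITIONS <- c("zero", "field1", "field2")
MAGNET_CONDITIONS <- c("magnet", "control", "diacetyl")

#' Environmental metadata for one assay plate
#'
#' @param humidity_pct relative humidity (%) at assay start, in \[0, 100\].
#' @param temp_start_c,temp_end_c temperature (deg C) at start and end.
#' @param duration_min assay length in minutes, > 0.
#' @return list of class `env_metadata`.
#' @export
env_metadata <- function(humidity_pct, temp_start_c, temp_end_c, duration_min) {
  vals <- c(humidity_pct = humidity_pct, temp_start_c = temp_start_c,
            temp_end_c = temp_end_c, duration_min = duration_min)
  if (anyNA(vals)) stop("environmental metadata contains NA", call. = FALSE)
  if (humidity_pct < 0 || humidity_pct > 100)
    stop("humidity_pct must be in [0, 100]", call. = FALSE)
  if (duration_min <= 0) stop("duration_min must be positive", call. = FALSE)
  structure(as.list(vals), class = "env_metadata")
}

#' One horizontal-field assay plate
#'
#' A plate is the unit of statistical independence: worms migrating on the
#' same plate can interact, so their headings are never treated as
#' independent observations downstream.
#'
#' @param plate_id unique identifier (character).
#' @param condition one of `"zero"`, `"field1"`, `"field2"`.
#' @param headings an [angle_sample()] (or numeric degrees) of worm exit
#'   headings.
#' @param env an [env_metadata()] object.
#' @return list of class `field_plate`.
#' @export
field_plate <- function(plate_id, condition, headings, env) {
  condition <- match.arg(condition, FIELD_CONDITIONS)
  stopifnot(inherits(env, "env_metadata"))
  structure(
    list(plate_id = as.character(plate_id), condition = condition,
         headings = as_angle_sample(headings), env = env),
    class = "field_plate"
  )
}

#' @export
print.field_plate <- function(x, ...) {
  cat(sprintf("Field plate %s [%s]: %d worms, RH %.1f%%, %.1f->%.1f C, %g min\n",
              x$plate_id, x$condition, length(x$headings),
              x$env$humidity_pct, x$env$temp_start_c, x$env$temp_end_c,
              x$env$duration_min))
  invisible(x)
}

#' One two-target assay plate
#'
#' Counts of worms paralyzed in the test circle (`count_target`, above the
#' magnet or odorant) and the control circle (`count_control`, above the
#' sham). The preference index is computable only when at least one worm
#' reached a circle.
#'
#' @param plate_id unique identifier.
#' @param condition one of `"magnet"`, `"control"`, `"diacetyl"`.
#' @param count_target,count_control nonnegative integer counts.
#' @return list of class `magnet_plate` with a `pi` element
#'   (`NA` when both counts are zero).
#' @export
magnet_plate <- function(plate_id, condition, count_target, count_control) {
  condition <- match.arg(condition, MAGNET_CONDITIONS)
  t <- count_target; c0 <- count_control
  if (anyNA(c(t, c0)) || t < 0 || c0 < 0 || t != round(t) || c0 != round(c0))
    stop("counts must be nonnegative integers", call. = FALSE)
  pi_val <- if (t + c0 > 0) (t - c0) / (t + c0) else NA_real_
  structure(
    list(plate_id = as.character(plate_id), condition = condition,
         count_target = as.integer(t), count_control = as.integer(c0),
         pi = pi_val),
    class = "magnet_plate"
  )
}

#' @export
print.magnet_plate <- function(x, ...) {
  cat(sprintf("Magnet plate %s [%s]: T = %d, C = %d, PI = %s\n",
              x$plate_id, x$condition, x$count_target, x$count_control,
              if (is.na(x$pi)) "undefined" else sprintf("%.3f", x$pi)))
  invisible(x)
}

#' Plate-inclusion filter thresholds
#'
#' Defaults encode the inclusion rules of the orientation assay: at least
#' 30 worms scored (inclusive), relative humidity strictly below 50%,
#' maximal temperature (the larger of the start and end reading) at most
#' 25 deg C (inclusive), absolute start-to-end temperature difference
#' strictly below 2 deg C, and assay duration 55-65 minutes inclusive.
#'
#' @param min_worms minimum worms scored per plate (inclusive).
#' @param max_humidity_pct humidity ceiling (%; exclusive).
#' @param max_temp_c temperature ceiling (deg C; inclusive; applied to the
#'   maximum of the start and end readings).
#' @param max_temp_delta_c temperature-drift ceiling (deg C; exclusive;
#'   absolute difference).
#' @param duration_range_min inclusive duration window in minutes,
#'   length-2 ascending.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_worms = 30, max_humidity_pct = 50,
                          max_temp_c = 25, max_temp_delta_c = 2,
                          duration_range_min = c(55, 65)) {
  stopifnot(min_worms > 0, max_humidity_pct > 0, max_temp_c > 0,
            max_temp_delta_c > 0, length(duration_range_min) == 2,
            duration_range_min[1] <= duration_range_min[2])
  structure(
    list(min_worms = min_worms, max_humidity_pct = max_humidity_pct,
         max_temp_c = max_temp_c, max_temp_delta_c = max_temp_delta_c,
         duration_range_min = as.numeric(duration_range_min)),
    class = "filter_config"
  )
}

.check_columns <- function(df, expected, path) {
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read horizontal-field assay data from CSV
#'
#' Joins a per-worm headings table to a per-plate metadata table by
#' `plate_id`. Headings CSV columns: `plate_id,condition,angle_deg`;
#' plates CSV columns:
#' `plate_id,condition,humidity_pct,temp_start_c,temp_end_c,duration_min`.
#' Angles are normalized into \[0, 360). Orphan heading rows, duplicate
#' plate ids, condition mismatches and unknown condition labels are
#' reported with row numbers.
#'
#' @param headings_path path to the headings CSV.
#' @param plates_path path to the plate metadata CSV.
#' @return list of [field_plate()] objects, in plate-table order.
#' @export
read_field_data <- function(headings_path, plates_path) {
  heads <- utils::read.csv(headings_path, stringsAsFactors = FALSE)
  plates <- utils::read.csv(plates_path, stringsAsFactors = FALSE)
  .check_columns(heads, c("plate_id", "condition", "angle_deg"), headings_path)
  .check_columns(plates, c("plate_id", "condition", "humidity_pct",
                           "temp_start_c", "temp_end_c", "duration_min"),
                 plates_path)
  bad <- which(!plates$condition %in% FIELD_CONDITIONS)
  if (length(bad))
    stop(sprintf("%s: unknown condition %s at row(s) %s", plates_path,
                 paste(unique(plates$condition[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  dup <- which(duplicated(plates$plate_id))
  if (length(dup))
    stop(sprintf("%s: duplicate plate_id %s at row(s) %s", plates_path,
                 paste(unique(plates$plate_id[dup]), collapse = ", "),
                 paste(dup, collapse = ", ")), call. = FALSE)
  orphan <- which(!heads$plate_id %in% plates$plate_id)
  if (length(orphan))
    stop(sprintf("%s: heading row(s) %s reference unknown plate_id %s",
                 headings_path, paste(orphan, collapse = ", "),
                 paste(unique(heads$plate_id[orphan]), collapse = ", ")),
         call. = FALSE)
  mism <- which(heads$condition !=
                  plates$condition[match(heads$plate_id, plates$plate_id)])
  if (length(mism))
    stop(sprintf("%s: heading row(s) %s disagree with the plate table condition",
                 headings_path, paste(mism, collapse = ", ")), call. = FALSE)
  lapply(seq_len(nrow(plates)), function(i) {
    p <- plates[i, ]
    ang <- heads$angle_deg[heads$plate_id == p$plate_id]
    if (length(ang) == 0)
      stop(sprintf("%s: plate %s has no heading rows", plates_path, p$plate_id),
           call. = FALSE)
    field_plate(p$plate_id, p$condition, angle_sample(ang),
                env_metadata(p$humidity_pct, p$temp_start_c, p$temp_end_c,
                             p$duration_min))
  })
}

#' Write horizontal-field assay data to CSV
#'
#' Inverse of [read_field_data()]: emits the normalized headings and plate
#' metadata tables with documented column order and fixed float formatting
#' (up to 10 significant digits, `.` decimal separator), so that
#' write-read-write round-trips are byte-stable.
#'
#' @param plates list of [field_plate()] objects.
#' @param headings_path,plates_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_field_data <- function(plates, headings_path, plates_path) {
  fmt <- function(x) sprintf("%.10g", x)
  hlines <- c("plate_id,condition,angle_deg")
  plines <- c("plate_id,condition,humidity_pct,temp_start_c,temp_end_c,duration_min")
  for (p in plates) {
    hlines <- c(hlines, sprintf("%s,%s,%s", p$plate_id, p$condition,
                                fmt(p$headings$angles)))
    plines <- c(plines, sprintf("%s,%s,%s,%s,%s,%s", p$plate_id, p$condition,
                                fmt(p$env$humidity_pct), fmt(p$env$temp_start_c),
                                fmt(p$env$temp_end_c), fmt(p$env$duration_min)))
  }
  writeLines(hlines, headings_path)
  writeLines(plines, plates_path)
  invisible(c(headings_path, plates_path))
}

#' Read two-target assay counts from CSV
#'
#' CSV columns: `plate_id,condition,count_target,count_control` with
#' condition in `magnet`, `control`, `diacetyl`. Negative counts and
#' unknown conditions are rejected with row numbers; plates with
#' `T = C = 0` load with an undefined preference index.
#'
#' @param counts_path path to the counts CSV.
#' @return list of [magnet_plate()] objects.
#' @export
read_magnet_data <- function(counts_path) {
  df <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  .check_columns(df, c("plate_id", "condition", "count_target",
                       "count_control"), counts_path)
  bad <- which(!df$condition %in% MAGNET_CONDITIONS)
  if (length(bad))
    stop(sprintf("%s: unknown condition %s at row(s) %s", counts_path,
                 paste(unique(df$condition[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  neg <- which(df$count_target < 0 | df$count_control < 0)
  if (length(neg))
    stop(sprintf("%s: negative count at row(s) %s", counts_path,
                 paste(neg, collapse = ", ")), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    magnet_plate(df$plate_id[i], df$condition[i], df$count_target[i],
                 df$count_control[i]))
}

#' Write two-target assay counts to CSV
#'
#' @param plates list of [magnet_plate()] objects.
#' @param counts_path output CSV path.
#' @return invisibly, the path.
#' @export
write_magnet_data <- function(plates, counts_path) {
  lines <- c("plate_id,condition,count_target,count_control",
             vapply(plates, function(p)
               sprintf("%s,%s,%d,%d", p$plate_id, p$condition,
                       p$count_target, p$count_control), character(1)))
  writeLines(lines, counts_path)
  invisible(counts_path)
}

# Names of the filter rules a plate can violate; order fixed for reporting.
FILTER_RULES <- c("min_worms", "humidity", "max_temp", "temp_delta", "duration")

.violated_rules <- function(plate, config) {
  env <- plate$env
  rules <- character(0)
  if (length(plate$headings) < config$min_worms) rules <- c(rules, "min_worms")
  if (env$humidity_pct >= config$max_humidity_pct) rules <- c(rules, "humidity")
  if (max(env$temp_start_c, env$temp_end_c) > config$max_temp_c)
    rules <- c(rules, "max_temp")
  if (abs(env$temp_end_c - env$temp_start_c) >= config$max_temp_delta_c)
    rules <- c(rules, "temp_delta")
  if (env$duration_min < config$duration_range_min[1] ||
      env$duration_min > config$duration_range_min[2])
    rules <- c(rules, "duration")
  rules
}

#' Apply the plate-inclusion filters
#'
#' A plate is kept iff it satisfies every rule of the [filter_config()]:
#' worms scored >= `min_worms`, humidity < `max_humidity_pct`,
#' max(start, end temperature) <= `max_temp_c`, |temperature drift| <
#' `max_temp_delta_c`, and duration inside `duration_range_min`
#' (inclusive). The worms-scored count is the number of headings on the
#' plate, never a separate column.
#'
#' @param plates list of [field_plate()] objects.
#' @param config a [filter_config()].
#' @return list with `kept` (the surviving plates) and `exclusions`, a
#'   data frame with one row per excluded plate and rule
#'   (`plate_id`, `condition`, `rule`).
#' @export
filter_plates <- function(plates, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  viol <- lapply(plates, .violated_rules, config = config)
  keep <- lengths(viol) == 0
  excl <- data.frame(
    plate_id = rep(vapply(plates, `[[`, character(1), "plate_id")[!keep],
                   lengths(viol)[!keep]),
    condition = rep(vapply(plates, `[[`, character(1), "condition")[!keep],
                    lengths(viol)[!keep]),
    rule = unlist(viol[!keep], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  list(kept = plates[keep], exclusions = excl)
}

#' Check group-size balance after filtering
#'
#' Advisory check that plate exclusion did not unbalance the per-condition
#' sample sizes: a chi-square goodness-of-fit test of the kept-plate counts
#' against equal allocation across the conditions present. The verdict is
#' `"balanced"` when p >= 0.05; it is reported, never used as a gate.
#'
#' @param kept nonempty list of [field_plate()] objects (or a named integer
#'   vector of per-condition counts).
#' @return list with `counts` (named integer vector), `chisq`, `df`, `p`,
#'   `verdict`.
#' @export
balance_check <- function(kept) {
  counts <- if (is.numeric(kept)) {
    as.integer(kept)
  } else {
    if (length(kept) == 0) stop("no plates to check", call. = FALSE)
    conds <- vapply(kept, `[[`, character(1), "condition")
    tab <- table(conds)
    stats::setNames(as.integer(tab), names(tab))
  }
  if (length(counts) < 2)
    return(list(counts = counts, chisq = 0, df = 0, p = 1, verdict = "balanced"))
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(counts = counts, chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       verdict = if (ct$p.value >= 0.05) "balanced" else "unbalanced")
}
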