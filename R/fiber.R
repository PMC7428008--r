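# DNA fiber combing: tract lengths to replication fork speeds.

#' Convert a fiber tract length to kilobases
#'
#' Combed DNA fibers stretch uniformly; 1 micrometer corresponds to
#' ~2.59 kilobases.
#'
#' @param length_um Tract length(s) in micrometers; non-negative.
#' @param kb_per_um Conversion factor (default 2.59).
#' @return Length(s) in kilobases.
#' @export
tract_kb <- function(length_um, kb_per_um = 2.59) {
  if (any(length_um < 0)) .stopf("tract length must be non-negative")
  length_um * kb_per_um
}

#' Read a fiber tract table from TSV
#'
#' Columns: `fiber_id`, `condition`, `idu_um`, `cldu_um`, and optional
#' `idu_pulse_min` / `cldu_pulse_min` overrides.
#'
#' @param path TSV file.
#' @param idu_pulse_min,cldu_pulse_min Default pulse durations in minutes
#'   (20 each), used where the table has no override columns.
#' @return data.frame of tracts.
#' @export
read_fiber_tsv <- function(path, idu_pulse_min = 20, cldu_pulse_min = 20) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("fiber_id", "condition", "idu_um", "cldu_um")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    .stopf("%s: missing column(s) %s", path, paste(missing_cols, collapse = ", "))
  if (!"idu_pulse_min" %in% names(dt)) dt$idu_pulse_min <- idu_pulse_min
  if (!"cldu_pulse_min" %in% names(dt)) dt$cldu_pulse_min <- cldu_pulse_min
  dt
}

#' Fork speed and fork-class calls from dual-label fiber tracts
#'
#' Fibers are pulse-labelled with IdU then CldU (20 min each by default).
#' A fiber with both labels is an *ongoing* fork whose speed is the total
#' tract length in kb over the total pulse time; only the first label means
#' the fork *stalled* before the second pulse; only the second label marks
#' a *new origin* fired during the second pulse. Speed is reported only for
#' ongoing forks. A `stall_threshold_um` above 0 treats very short second
#' labels as absent.
#'
#' @param tracts data.frame as from [read_fiber_tsv()]; per-row pulse
#'   durations are taken from `idu_pulse_min`/`cldu_pulse_min` when
#'   present.
#' @param kb_per_um Micrometer-to-kilobase conversion (default 2.59).
#' @param stall_threshold_um Label lengths at or below this count as absent
#'   (default 0).
#' @param per_label Use the alternative per-label speed (each segment over
#'   its own pulse, averaged) instead of total length over total time.
#' @return data.frame: `fiber_id`, `condition`, `class` (`ongoing`,
#'   `stalled`, `new_origin`), `speed_kb_per_min` (NA unless ongoing).
#' @export
fork_speed <- function(tracts, kb_per_um = 2.59, stall_threshold_um = 0,
                       per_label = FALSE) {
  if (any(tracts$idu_um < 0 | tracts$cldu_um < 0))
    .stopf("tract lengths must be non-negative")
  if (any(tracts$idu_um == 0 & tracts$cldu_um == 0))
    .stopf("fiber with both labels absent")
  if (is.null(tracts$idu_pulse_min)) tracts$idu_pulse_min <- 20
  if (is.null(tracts$cldu_pulse_min)) tracts$cldu_pulse_min <- 20
  if (any(tracts$idu_pulse_min <= 0 | tracts$cldu_pulse_min <= 0))
    .stopf("pulse durations must be positive")
  has1 <- tracts$idu_um > stall_threshold_um
  has2 <- tracts$cldu_um > stall_threshold_um
  cls <- ifelse(has1 & has2, "ongoing",
                ifelse(has1, "stalled", "new_origin"))
  speed <- rep(NA_real_, nrow(tracts))
  ongoing <- cls == "ongoing"
  if (per_label) {
    speed[ongoing] <- (tract_kb(tracts$idu_um[ongoing], kb_per_um) /
                         tracts$idu_pulse_min[ongoing] +
                       tract_kb(tracts$cldu_um[ongoing], kb_per_um) /
                         tracts$cldu_pulse_min[ongoing]) / 2
  } else {
    speed[ongoing] <- tract_kb(tracts$idu_um[ongoing] + tracts$cldu_um[ongoing],
                               kb_per_um) /
      (tracts$idu_pulse_min[ongoing] + tracts$cldu_pulse_min[ongoing])
  }
  data.frame(fiber_id = tracts$fiber_id, condition = tracts$condition,
             class = factor(cls, levels = c("ongoing", "stalled", "new_origin")),
             speed_kb_per_min = speed)
}

#' Cohort summary of fork calls
#'
#' Mean and SEM of ongoing-fork speeds plus class fractions, per condition.
#'
#' @param calls A [fork_speed()] result.
#' @return data.frame, one row per condition: `condition`, `n_fibers`,
#'   `mean_speed_kb_per_min`, `sem_speed`, `frac_ongoing`, `frac_stalled`,
#'   `frac_new_origin`.
#' @export
fiber_summary <- function(calls) {
  out <- lapply(split(calls, calls$condition), function(grp) {
    sp <- grp$speed_kb_per_min[grp$class == "ongoing"]
    fr <- table(grp$class) / nrow(grp)
    data.frame(condition = grp$condition[1], n_fibers = nrow(grp),
               mean_speed_kb_per_min = if (length(sp)) mean(sp) else NA_real_,
               sem_speed = .sem(sp),
               frac_ongoing = as.numeric(fr[["ongoing"]]),
               frac_stalled = as.numeric(fr[["stalled"]]),
               frac_new_origin = as.numeric(fr[["new_origin"]]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
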