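# DRIP-qPCR and RT-qPCR quantification.
#
# All computations follow the exponential amplification model
# quantity ~ efficiency^(-Ct); efficiency defaults to 2 (perfect doubling).

#' Read a qPCR well table from CSV
#'
#' Expected columns: `sample_id`, `amplicon`, `role` (`IP`, `input` or
#' `cDNA`), `condition`, `rnaseh` (logical: RNase H pre-treated),
#' `input_fraction` (fraction of the template pool the input well
#' represents, in (0, 1]), `replicate`, `ct` (empty/NA = undetermined).
#'
#' @param path CSV file.
#' @return data.frame of wells.
#' @export
read_qpcr_csv <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  need <- c("sample_id", "amplicon", "role", "condition", "rnaseh",
            "input_fraction", "replicate", "ct")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    .stopf("%s: missing column(s) %s", path, paste(missing_cols, collapse = ", "))
  dt$rnaseh <- as.logical(dt$rnaseh)
  dt$ct <- suppressWarnings(as.numeric(dt$ct))
  if (any(!is.na(dt$ct) & dt$ct <= 0)) .stopf("%s: Ct values must be positive", path)
  if (any(dt$input_fraction <= 0 | dt$input_fraction > 1))
    .stopf("%s: input_fraction must be in (0, 1]", path)
  dt
}

.sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0

#' DRIP-qPCR relative abundance of DNA:RNA hybrids
#'
#' Normalizes the immunoprecipitated (IP) signal to equal amounts of
#' template in the non-immunoprecipitated input. Per replicate, the input
#' Ct is first adjusted to represent the full template pool,
#' `ct_input + log_E(input_fraction)`, and the relative abundance is
#' `E^(adjusted_input_ct - ct_ip)` with amplification efficiency `E`.
#' Replicates are matched by the `replicate` column and aggregated as mean
#' with standard error.
#'
#' An undetermined IP Ct (NA) contributes a value of 0 (signal absent) and
#' sets the `any_undetermined` flag.
#'
#' @param ip,input data.frames of wells (as from [read_qpcr_csv()]) for one
#'   amplicon/condition: IP wells and matched input wells.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return One-row data.frame: `amplicon`, `condition`, `value`,
#'   `n_replicates`, `sem`, `any_undetermined`.
#' @export
drip_relative_abundance <- function(ip, input, efficiency = 2.0) {
  if (nrow(input) == 0L) .stopf("no matched input wells")
  if (nrow(ip) == 0L) .stopf("no IP wells")
  amp <- unique(c(ip$amplicon, input$amplicon))
  cond <- unique(c(ip$condition, input$condition))
  if (length(amp) != 1L || length(cond) != 1L)
    .stopf("IP and input wells must share one amplicon and condition")
  vals <- vapply(seq_len(nrow(ip)), function(i) {
    m <- input[input$replicate == ip$replicate[i], ]
    if (nrow(m) == 0L)
      .stopf("no input well for replicate %s", ip$replicate[i])
    if (is.na(ip$ct[i])) {
      warning(sprintf("undetermined IP Ct (amplicon %s, replicate %s): value 0",
                      amp, ip$replicate[i]), call. = FALSE)
      return(0)
    }
    adj_input <- m$ct[1] + log(m$input_fraction[1], base = efficiency)
    efficiency^(adj_input - ip$ct[i])
  }, 0)
  data.frame(amplicon = amp, condition = cond, value = mean(vals),
             n_replicates = length(vals), sem = .sem(vals),
             any_undetermined = anyNA(ip$ct))
}

#' Tabulate DRIP relative abundance for a whole well table
#'
#' Splits a well table by amplicon, condition and RNase H status and
#' applies [drip_relative_abundance()] to each group, matching IP wells
#' with their input wells.
#'
#' @param wells Well table (see [read_qpcr_csv()]).
#' @param efficiency Amplification factor per cycle (default 2).
#' @return data.frame with one row per amplicon/condition/RNase H group.
#' @export
drip_table <- function(wells, efficiency = 2.0) {
  key <- interaction(wells$amplicon, wells$condition, wells$rnaseh,
                     drop = TRUE)
  out <- lapply(split(wells, key), function(grp) {
    res <- drip_relative_abundance(grp[grp$role == "IP", ],
                                   grp[grp$role == "input", ], efficiency)
    res$rnaseh <- grp$rnaseh[1]
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$amplicon, res$condition, res$rnaseh), ]
}

#' RNase H sensitivity of a DRIP signal
#'
#' Ratio of the RNase H pre-treated relative abundance to the untreated
#' one; values near 0 indicate hybrid-specific (R-loop) signal, values near
#' 1 indicate hybrid-independent background.
#'
#' @param untreated,treated One-row results of
#'   [drip_relative_abundance()] for the same amplicon/condition.
#' @return Ratio (treated / untreated), or `NA` when the untreated value
#'   is 0.
#' @export
rnaseh_sensitivity <- function(untreated, treated) {
  if (untreated$amplicon != treated$amplicon ||
      untreated$condition != treated$condition)
    .stopf("untreated and treated must share amplicon and condition")
  if (untreated$value == 0) return(NA_real_)
  treated$value / untreated$value
}

#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' Standard relative mRNA quantification: per condition the target Ct is
#' referenced to a housekeeping amplicon (`dCt = ct_target - ct_ref`,
#' replicate-matched), and expression of the treated condition relative to
#' control is `E^-(dCt_treated - mean dCt_control)`. Per-replicate treated
#' folds (each against the mean control dCt) give the mean and SEM.
#'
#' @param target_treated,ref_treated,target_control,ref_control Well
#'   data.frames (role `cDNA`) for the target and reference amplicons in
#'   each condition.
#' @param efficiency Amplification factor per cycle (default 2).
#' @return One-row data.frame: `fold`, `n_replicates`, `sem`.
#' @export
relative_expression <- function(target_treated, ref_treated,
                                target_control, ref_control,
                                efficiency = 2.0) {
  for (w in list(target_treated, ref_treated, target_control, ref_control))
    if (nrow(w) == 0L) .stopf("missing wells for one of the four conditions")
  dct <- function(target, ref) {
    vapply(seq_len(nrow(target)), function(i) {
      m <- ref[ref$replicate == target$replicate[i], ]
      if (nrow(m) == 0L)
        .stopf("no reference well for replicate %s", target$replicate[i])
      target$ct[i] - m$ct[1]
    }, 0)
  }
  dct_t <- dct(target_treated, ref_treated)
  dct_c <- dct(target_control, ref_control)
  folds <- efficiency^(-(dct_t - mean(dct_c)))
  data.frame(fold = mean(folds), n_replicates = length(folds),
             sem = .sem(folds))
}
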