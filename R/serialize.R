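#' Serialize ONEST and agreement results
#'
#' `onest_report` turns an `onest_result` (and optionally an exhaustive
#' envelope and an ICC) into a plain list ready for JSON; `write_onest_json`
#' writes it; `write_envelope_csv` exports the envelopes as a CSV with
#' columns `k`, `min`, `mean`, `max`.
#'
#' @param result an `onest_result`.
#' @param envelope optional `onest_envelope` to embed.
#' @param icc optional `icc_result` to embed.
#' @param extra optional named list merged into the report (e.g. run
#'   configuration).
#' @return `onest_report`: a list. The writers return the path, invisibly.
#' @export
onest_report <- function(result, envelope = NULL, icc = NULL, extra = NULL) {
  stopifnot(inherits(result, "onest_result"))
  rep <- list(
    n_cases = result$n_cases,
    n_observers = result$n_observers,
    n_perm = result$n_perm,
    seed = result$seed,
    exhaustive = result$exhaustive,
    k = result$k,
    min_curve = unname(result$min_curve),
    mean_curve = unname(result$mean_curve),
    max_curve = unname(result$max_curve),
    bandwidth = result$bandwidth,
    bandwidth_mode = result$bandwidth_mode,
    plateau_k = result$plateau_k,
    plateau_value = result$plateau_value,
    plateau_eps = result$plateau_eps,
    opa_all = result$opa_all,
    min_realized = result$min_realized,
    consensus = as.list(result$consensus$counts),
    consensus_total = result$consensus$total)
  if (!is.null(envelope)) {
    rep$exhaustive_min <- unname(envelope$min_curve)
    rep$exhaustive_mean <- unname(envelope$mean_curve)
    rep$exhaustive_max <- unname(envelope$max_curve)
  }
  if (!is.null(icc)) {
    rep$icc <- list(estimate = icc$estimate, ci_low = icc$ci_low,
                    ci_high = icc$ci_high, reliability = icc$reliability)
  }
  if (!is.null(extra)) rep <- c(rep, extra)
  rep
}

#' @rdname onest_report
#' @param path output file path.
#' @param ... passed to [onest_report()].
#' @export
write_onest_json <- function(result, path, ...) {
  jsonlite::write_json(onest_report(result, ...), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname onest_report
#' @export
write_envelope_csv <- function(result, path) {
  df <- data.frame(k = result$k, min = unname(result$min_curve),
                   mean = unname(result$mean_curve),
                   max = unname(result$max_curve))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
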