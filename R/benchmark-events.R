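# Event timestamps for the classification benchmark. Case stays take the
# first timed PI evidence (staging chart event or keyword mention) later
# than 24 h after admission. Control stays receive a matched timestamp drawn
# from a parametric fit of the case note-duration distribution, paired to
# their true note duration by rank so that control documents are not
# systematically longer than case documents.

#' Event timestamps for case stays
#'
#' Per case, the minimum over qualifying staging-event times and non-negated
#' keyword-mention times strictly later than `min_hours` after admission.
#'
#' @param labels a [label_cohort()] table; only rows with `status == "case"`
#'   and a timed route are used.
#' @param staging_events [extract_staging_events()] output for the cohort.
#' @param mentions [scan_notes()] output for the cohort.
#' @param admit_ts named `POSIXct` (names = stay_id).
#' @param min_hours evidence threshold (strict `>`), default 24.
#' @return named `POSIXct` vector, one entry per timed case.
#' @export
case_event_timestamps <- function(labels, staging_events, mentions, admit_ts,
                                  min_hours = 24) {
  cases <- labels$stay_id[labels$status == "case" & labels$route != "icd9"]
  if (!length(cases)) return(stats::setNames(as.POSIXct(character(), tz = "UTC"), character()))
  se <- staging_events[staging_events$stay_id %in% cases, , drop = FALSE]
  se <- se[hours_since(se$ts, admit_ts[se$stay_id]) > min_hours, , drop = FALSE]
  mn <- mentions[mentions$stay_id %in% cases & !mentions$negated &
                   !mentions$date_only & !is.na(mentions$ts), , drop = FALSE]
  mn <- mn[hours_since(mn$ts, admit_ts[mn$stay_id]) > min_hours, , drop = FALSE]
  ev <- rbind(data.frame(stay_id = se$stay_id, ts = se$ts, stringsAsFactors = FALSE),
              data.frame(stay_id = mn$stay_id, ts = mn$ts, stringsAsFactors = FALSE))
  missing <- setdiff(cases, ev$stay_id)
  if (length(missing))
    stop(sprintf("%d case stay(s) carry no timed PI evidence beyond %g h (inconsistent labels)",
                 length(missing), min_hours), call. = FALSE)
  agg <- tapply(as.numeric(ev$ts), ev$stay_id, min)
  out <- as.POSIXct(as.numeric(agg), origin = "1970-01-01", tz = "UTC")
  names(out) <- names(agg)
  out[cases]
}

dist_funs <- list(
  exponential = list(name = "exp", q = stats::qexp, p = stats::pexp, r = stats::rexp),
  gamma = list(name = "gamma", q = stats::qgamma, p = stats::pgamma, r = stats::rgamma),
  lognormal = list(name = "lnorm", q = stats::qlnorm, p = stats::plnorm, r = stats::rlnorm),
  weibull = list(name = "weibull", q = stats::qweibull, p = stats::pweibull, r = stats::rweibull)
)

#' Fit a parametric duration distribution by minimum chi-square selection
#'
#' Each candidate family is fitted by maximum likelihood
#' ([fitdistrplus::fitdist()]). All candidates are scored on the same
#' `n_bins` equal-probability bins (empirical quantile edges): the Pearson
#' chi-square compares the observed per-bin counts with the counts each
#' fitted distribution implies. Because a family with more free parameters
#' can only improve the raw score, selection minimizes the chi-square
#' penalized by `qchisq(0.95, 1)` per estimated parameter - an extra
#' parameter must buy a significant chi-square improvement, otherwise the
#' more parsimonious family wins (remaining ties break by candidate order).
#' With fewer than 20 usable durations, degenerate (constant) durations, or
#' when every candidate fails, the model falls back to the empirical
#' distribution (bootstrap resampling), flagged via `fallback = TRUE`.
#'
#' @param durations positive durations in hours.
#' @param candidates subset of
#'   `c("exponential", "gamma", "lognormal", "weibull")`.
#' @param n_bins number of equal-probability bins for the chi-square score.
#' @return a `duration_model`: list with `family`, `params`, `chi_square`
#'   (raw, unpenalized), `bin_edges`, `fallback`, and a `sample(n)` closure.
#' @export
fit_duration_distribution <- function(durations,
                                      candidates = c("exponential", "gamma",
                                                     "lognormal", "weibull"),
                                      n_bins = 20) {
  durations <- durations[is.finite(durations) & durations > 0]
  empirical <- function() {
    structure(list(family = "empirical", params = NULL, chi_square = NA_real_,
                   bin_edges = NULL, fallback = TRUE,
                   sample = function(n) sample(durations, n, replace = TRUE)),
              class = "duration_model")
  }
  if (length(durations) < 20 || stats::sd(durations) == 0) return(empirical())

  n <- length(durations)
  edges <- stats::quantile(durations, seq(0, 1, length.out = n_bins + 1),
                           names = FALSE)
  cut_edges <- unique(c(-Inf, edges[-c(1, n_bins + 1)], Inf))
  obs <- as.numeric(table(cut(durations, breaks = cut_edges)))
  penalty <- stats::qchisq(0.95, df = 1)

  best <- NULL
  for (fam in candidates) {
    fu <- dist_funs[[fam]]
    if (is.null(fu)) stop(sprintf("unknown candidate family '%s'", fam), call. = FALSE)
    fit <- tryCatch(suppressWarnings(fitdistrplus::fitdist(durations, fu$name)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    pars <- as.list(fit$estimate)
    cdf <- do.call(fu$p, c(list(q = cut_edges), pars))
    cdf[1] <- 0; cdf[length(cdf)] <- 1
    expct <- n * diff(cdf)
    if (any(expct <= 0)) next
    chi2 <- sum((obs - expct)^2 / expct)
    score <- chi2 + penalty * length(pars)
    if (!is.finite(score)) next
    if (is.null(best) || score < best$score) {
      best <- list(family = fam, params = unlist(pars), chi_square = chi2,
                   score = score, bin_edges = edges, fallback = FALSE,
                   sample = local({
                     fu0 <- fu; pars0 <- pars
                     function(n) do.call(fu0$r, c(list(n = n), pars0))
                   }))
    }
  }
  if (is.null(best)) return(empirical())
  structure(best, class = "duration_model")
}

#' @export
print.duration_model <- function(x, ...) {
  cat("<duration_model>", x$family,
      if (x$fallback) "(empirical fallback)" else
        sprintf("chi2=%.2f params=[%s]", x$chi_square,
                paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", ")),
      "\n")
  invisible(x)
}

#' Rank-paired event timestamps for control stays
#'
#' One duration is sampled per control from the fitted case duration model.
#' Sampled and true durations are sorted and paired by rank (k-th smallest
#' with k-th smallest); each control's offset is the minimum of its paired
#' sampled duration and its true duration, and its event timestamp is the
#' earliest-note time plus that offset, capped at the discharge time.
#'
#' @param controls data frame with `stay_id`, `first_note_ts` (`POSIXct`),
#'   `true_duration_hours`, `discharge_ts`.
#' @param model a `duration_model`.
#' @param seed RNG seed for the sampled durations.
#' @return data frame `stay_id`, `offset_hours`, `event_ts`.
#' @export
assign_control_timestamps <- function(controls, model, seed = 1L) {
  if (nrow(controls) == 0)
    return(data.frame(stay_id = character(), offset_hours = numeric(),
                      event_ts = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  n <- nrow(controls)
  sampled <- sort(with_seed(seed, model$sample(n)))
  ord <- order(controls$true_duration_hours, controls$stay_id)
  out <- controls[ord, , drop = FALSE]
  out$offset_hours <- pmin(sampled, out$true_duration_hours)
  out$event_ts <- out$first_note_ts + out$offset_hours * 3600
  over <- !is.na(out$discharge_ts) & out$event_ts > out$discharge_ts
  out$event_ts[over] <- out$discharge_ts[over]
  out$offset_hours[over] <- hours_since(out$discharge_ts[over], out$first_note_ts[over])
  rownames(out) <- NULL
  out[c("stay_id", "offset_hours", "event_ts")]
}
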