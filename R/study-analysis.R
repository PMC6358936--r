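#' Traffic offences per second of driving
#'
#' Route completion times differ between drivers, so offence counts are
#' normalised by session duration before any comparison.
#'
#' @param session A [driving_session()].
#' @param kinds Optional subset of [offence_kinds()] to count (default all).
#' @return Offences per second (numeric scalar).
#' @export
#' @examples
#' s <- simulate_session(driver_profile(seed = 1), duration = 120)
#' offences_per_second(s)
offences_per_second <- function(session, kinds = NULL) {
  stopifnot(inherits(session, "driving_session"))
  if (session$duration <= 0) stop("session duration must be positive", call. = FALSE)
  k <- session$offences$kind
  if (!is.null(kinds)) {
    stopifnot(all(kinds %in% offence_kinds()))
    k <- k[k %in% kinds]
  }
  length(k) / session$duration
}

#' Shapiro-Wilk normality screen
#'
#' Computes the Shapiro-Wilk W statistic and p-value and applies the
#' screening convention used throughout the study pipeline: normality is
#' declared (the null of normality is not rejected) when `p > alpha`.
#'
#' @param values Numeric sample, 3 to 5000 non-missing values, not constant.
#' @param alpha Significance level (default 0.05).
#' @return List with `W`, `p`, `normal`.
#' @export
shapiro_normality <- function(values, alpha = 0.05) {
  values <- as.numeric(values[!is.na(values)])
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires between 3 and 5000 values", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("sample is constant; normality is undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value > alpha)
}

#' Pearson correlation with a two-sided t-test
#'
#' The correlation coefficient is the covariance of the two variables
#' divided by the product of their standard deviations; its significance
#' is assessed with the two-sided t-transform on n - 2 degrees of freedom.
#' Computed directly from the defining formula (the package's own
#' implementation; `stats::cor.test` serves as an independent cross-check
#' in the test suite).
#'
#' @param x,y Numeric vectors of equal length n >= 3, neither constant.
#' @param alpha Significance level for the `significant` flag.
#' @param var_x,var_y Optional variable labels carried into the result.
#' @return An object of class `correlation_result`: `var_x`, `var_y`, `r`,
#'   `p`, `n`, `significant`, `alpha`.
#' @export
#' @examples
#' pearson_correlation(1:10, 2 * (1:10) + 1)$r  # exactly 1
pearson_correlation <- function(x, y, alpha = 0.05,
                                var_x = "x", var_y = "y") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  if (sx == 0 || sy == 0) stop("constant input: correlation undefined", call. = FALSE)
  r <- sxy / (sx * sy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  structure(
    list(var_x = var_x, var_y = var_y, r = r, p = p, n = n,
         significant = p < alpha, alpha = alpha),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s ~ %s: r = %.4f, p = %.4g, n = %d%s\n",
              x$var_x, x$var_y, x$r, x$p, x$n,
              if (x$significant) " *" else ""))
  invisible(x)
}

session_features <- function(session, period_s = 5) {
  gyro <- session$traces$gyro
  has_gyro <- !is.null(gyro) && length(gyro$values) > 1L
  v <- session$vehicle
  kinds <- offence_kinds()
  counts <- table(factor(session$offences$kind, levels = kinds))
  out <- data.frame(
    driver_id = session$driver_id,
    scenario_class = session$scenario_class,
    gear = session$gear,
    duration = session$duration,
    n_samples = if (has_gyro) length(gyro$values) else 0L,
    mean_w = if (has_gyro) mean(gyro$values) else NA_real_,
    sd_w = if (has_gyro) sd0(gyro$values) else NA_real_,
    zero_crossings_per_s = if (has_gyro)
      count_zero_crossings(gyro)$count / session$duration else NA_real_,
    n_low_attention = if (has_gyro)
      sum(classify_low_attention(gyro, period_s = period_s)$low_attention) else NA_integer_,
    mean_speed = if (nrow(v)) mean(v$speed) else NA_real_,
    mean_rpm = if (nrow(v)) mean(v$rpm) else NA_real_,
    mean_fuel = if (nrow(v)) mean(v$fuel) else NA_real_,
    offences_per_s = nrow(session$offences) / session$duration,
    n_offences = nrow(session$offences),
    stringsAsFactors = FALSE
  )
  for (k in kinds) out[[paste0("rate_", k)]] <- counts[[k]] / session$duration
  out
}

# exact pooled sd from per-group (n, mean, sd)
pooled_sd <- function(n, m, s) {
  tot <- sum(n)
  if (tot <= 1L) return(0)
  gm <- sum(n * m) / tot
  ss <- sum((n - 1) * s^2 + n * (m - gm)^2)
  sqrt(ss / (tot - 1))
}

#' Build the per-driver study table
#'
#' Computes, for every session, the analysis variables of the correlation
#' study — offences per second (total and per kind), mean and standard
#' deviation of the steering angular speed, zero crossings per second,
#' low-attention period count, and mean speed / rpm / fuel — then
#' aggregates them per driver and scenario class (both gear shifts pooled,
#' the study's pooling rule) unless `by = "session"`. Counts are summed
#' and divided by total duration; means are duration-weighted; the pooled
#' angular-speed standard deviation is combined exactly from the
#' per-session moments.
#'
#' @param sessions List of [driving_session()] objects (or a
#'   `driving_cohort`).
#' @param questionnaires Optional questionnaire data frame merged in by
#'   `driver_id`.
#' @param by `"driver_scenario"` (default), `"driver_scenario_gear"`, or
#'   `"session"` (no aggregation).
#' @param period_s Low-attention period length in seconds.
#' @return Data frame of class `study_table`, one row per aggregation unit.
#' @export
build_study_table <- function(sessions, questionnaires = NULL,
                              by = c("driver_scenario", "driver_scenario_gear",
                                     "session"),
                              period_s = 5) {
  by <- match.arg(by)
  if (inherits(sessions, "driving_cohort")) {
    if (is.null(questionnaires)) questionnaires <- sessions$questionnaires
    sessions <- sessions$sessions
  }
  stopifnot(length(sessions) >= 1L)
  per <- do.call(rbind, lapply(sessions, session_features, period_s = period_s))

  if (by != "session") {
    keys <- if (by == "driver_scenario") c("driver_id", "scenario_class") else
      c("driver_id", "scenario_class", "gear")
    grp <- interaction(per[keys], drop = TRUE, lex.order = TRUE)
    rate_cols <- grep("^rate_", names(per), value = TRUE)
    rows <- lapply(split(seq_len(nrow(per)), grp), function(ix) {
      p <- per[ix, , drop = FALSE]
      dtot <- sum(p$duration)
      wm <- function(x) if (all(is.na(x))) NA_real_ else
        sum(x * p$duration, na.rm = TRUE) / sum(p$duration[!is.na(x)])
      out <- p[1L, keys, drop = FALSE]
      out$duration <- dtot
      out$n_sessions <- nrow(p)
      out$mean_w <- wm(p$mean_w)
      out$sd_w <- if (all(is.na(p$sd_w))) NA_real_ else
        pooled_sd(p$n_samples, p$mean_w, p$sd_w)
      out$zero_crossings_per_s <- wm(p$zero_crossings_per_s)
      out$n_low_attention <- if (all(is.na(p$n_low_attention))) NA_integer_ else
        sum(p$n_low_attention, na.rm = TRUE)
      out$mean_speed <- wm(p$mean_speed)
      out$mean_rpm <- wm(p$mean_rpm)
      out$mean_fuel <- wm(p$mean_fuel)
      out$offences_per_s <- sum(p$n_offences) / dtot
      out$n_offences <- sum(p$n_offences)
      for (rc in rate_cols) out[[rc]] <- sum(p[[rc]] * p$duration) / dtot
      out
    })
    per <- do.call(rbind, rows)
    rownames(per) <- NULL
  }

  if (!is.null(questionnaires)) {
    per <- merge(per, questionnaires, by = "driver_id", all.x = TRUE, sort = FALSE)
  }
  per <- per[order(per$driver_id, per$scenario_class), , drop = FALSE]
  rownames(per) <- NULL
  class(per) <- c("study_table", "data.frame")
  per
}

#' Correlation study between analysis variables and offence kinds
#'
#' For one scenario class (both gear shifts pooled), tests every pair of
#' analysis variable and per-kind offence rate with the Pearson
#' correlation. Before testing, each variable is screened with the
#' Shapiro-Wilk test; a pair is tested when at least one of its two
#' variables is declared normal (the pipeline's stated, deliberately
#' lenient gate). Pairs involving a constant vector are skipped. No
#' multiple-testing correction is applied by default, matching the
#' uncorrected many-offence-type screen; `adjust = "holm"` is available.
#'
#' @param table A `study_table` from [build_study_table()].
#' @param scenario_class Optional filter, `"urban"` or `"interurban"`.
#' @param alpha Significance level for the correlation flags (default 0.05).
#' @param normal_alpha Significance level of the Shapiro-Wilk screen
#'   (default 0.05, kept separate so changing `alpha` only moves the
#'   significance flags, never which pairs get tested or their r values).
#' @param variables Analysis variables to test (default: the five study
#'   variables — mean/sd of angular speed, mean speed, rpm, fuel).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame with one row per tested pair: `variable`, `offence`,
#'   `r`, `p`, `n`, `normal_x`, `normal_y`, `tested`, `significant`.
#' @export
correlation_study <- function(table, scenario_class = NULL, alpha = 0.05,
                              normal_alpha = 0.05,
                              variables = c("mean_w", "sd_w", "mean_speed",
                                            "mean_rpm", "mean_fuel"),
                              adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  df <- as.data.frame(table)
  if (!is.null(scenario_class)) {
    df <- df[df$scenario_class == scenario_class, , drop = FALSE]
  }
  if (nrow(df) < 3L) stop("need at least 3 rows to correlate", call. = FALSE)
  rate_cols <- grep("^rate_", names(df), value = TRUE)
  stopifnot(all(variables %in% names(df)), length(rate_cols) > 0L)

  normal_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || diff(range(x)) == 0) return(NA)
    shapiro_normality(x, alpha = normal_alpha)$normal
  }
  norm_var <- vapply(variables, function(v) normal_of(df[[v]]), NA)
  norm_rate <- vapply(rate_cols, function(v) normal_of(df[[v]]), NA)

  rows <- list()
  for (v in variables) {
    for (rc in rate_cols) {
      x <- df[[v]]; y <- df[[rc]]
      constant <- diff(range(x, na.rm = TRUE)) == 0 ||
        diff(range(y, na.rm = TRUE)) == 0
      tested <- !constant && (isTRUE(norm_var[[v]]) || isTRUE(norm_rate[[rc]]))
      r <- p <- NA_real_; n <- sum(!is.na(x) & !is.na(y))
      if (tested) {
        res <- pearson_correlation(x, y, alpha = alpha, var_x = v, var_y = rc)
        r <- res$r; p <- res$p; n <- res$n
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, offence = sub("^rate_", "", rc), r = r, p = p, n = n,
        normal_x = norm_var[[v]], normal_y = norm_rate[[rc]],
        tested = tested, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$p[out$tested] <- stats::p.adjust(out$p[out$tested], method = "holm")
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  out[order(out$p, na.last = TRUE), , drop = FALSE]
}

#' Low-attention correlation study
#'
#' Aggregates per driver the number of 5-s low-attention periods (from
#' [classify_low_attention()] over every steering trace) and the total
#' offence count, then correlates each against the sleepiness scores (KSS,
#' SSS, ESS) and driver covariates (age, licence years, racing-game
#' experience). Drivers whose low-attention count cannot be computed are
#' dropped; a constant outcome (e.g. an all-alert cohort with no
#' low-attention periods at all) is reported with `tested = FALSE` rather
#' than an error.
#'
#' @param sessions List of [driving_session()] objects or a `driving_cohort`.
#' @param questionnaires Questionnaire data frame (defaults to the
#'   cohort's); every session driver must have a row.
#' @param alpha Significance level.
#' @param period_s Low-attention period length (s).
#' @return Data frame with one row per (outcome, covariate) pair.
#' @export
low_attention_study <- function(sessions, questionnaires = NULL, alpha = 0.05,
                                period_s = 5) {
  if (inherits(sessions, "driving_cohort")) {
    if (is.null(questionnaires)) questionnaires <- sessions$questionnaires
    sessions <- sessions$sessions
  }
  tab <- build_study_table(sessions, by = "session", period_s = period_s)
  agg <- lapply(split(tab, tab$driver_id), function(p) data.frame(
    driver_id = p$driver_id[1L],
    n_low_attention = sum(p$n_low_attention),
    n_offences = sum(p$n_offences)))
  agg <- do.call(rbind, agg)
  miss <- setdiff(agg$driver_id, questionnaires$driver_id)
  if (length(miss)) {
    stop("no questionnaire for driver(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- merge(agg, questionnaires, by = "driver_id", sort = TRUE)
  covars <- c("kss", "sss", "ess", "age", "license_years", "racing_exp")
  rows <- list()
  for (outc in c("n_low_attention", "n_offences")) {
    for (cv in covars) {
      x <- m[[cv]]; y <- m[[outc]]
      constant <- length(y) < 3L || diff(range(y, na.rm = TRUE)) == 0 ||
        diff(range(x, na.rm = TRUE)) == 0
      if (constant) {
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = outc, covariate = cv, r = NA_real_, p = NA_real_,
          n = length(y), tested = FALSE, significant = FALSE,
          stringsAsFactors = FALSE)
      } else {
        res <- pearson_correlation(x, y, alpha = alpha, var_x = cv, var_y = outc)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = outc, covariate = cv, r = res$r, p = res$p, n = res$n,
          tested = TRUE, significant = res$significant,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired gear-shift comparison
#'
#' Descriptive per-driver paired differences (automatic minus manual) of
#' mean speed, mean angular speed and its standard deviation, split by
#' scenario class. No hypothesis test is attached.
#'
#' @param table A `study_table` built with `by = "driver_scenario_gear"`.
#' @return Data frame with one row per (driver, scenario class) and
#'   columns `d_mean_speed`, `d_mean_w`, `d_sd_w`.
#' @export
gearshift_comparison <- function(table) {
  df <- as.data.frame(table)
  need <- c("driver_id", "scenario_class", "gear", "mean_speed", "mean_w", "sd_w")
  stopifnot(all(need %in% names(df)))
  grp <- split(df, interaction(df$driver_id, df$scenario_class, drop = TRUE))
  rows <- lapply(grp, function(p) {
    au <- p[p$gear == "automatic", , drop = FALSE]
    mn <- p[p$gear == "manual", , drop = FALSE]
    if (nrow(au) != 1L || nrow(mn) != 1L) {
      stop(sprintf("driver %s (%s): need exactly one automatic and one manual row",
                   p$driver_id[1L], p$scenario_class[1L]), call. = FALSE)
    }
    data.frame(driver_id = au$driver_id, scenario_class = au$scenario_class,
               d_mean_speed = au$mean_speed - mn$mean_speed,
               d_mean_w = au$mean_w - mn$mean_w,
               d_sd_w = au$sd_w - mn$sd_w,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$driver_id, out$scenario_class), , drop = FALSE]
}
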