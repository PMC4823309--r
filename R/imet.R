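#' Stepped protocol of the incremental maximal exercise test
#'
#' Default protocol: 5-min rest at 50 W, then power increases by 50 W every
#' 3 min until exhaustion.
#'
#' @param start_power_w Starting power (W).
#' @param increment_w Power increment per stage (W).
#' @param stage_s Stage duration (s).
#' @param rest_s Resting-period duration (s).
#' @return An object of class \code{stage_protocol}.
#' @export
stage_protocol <- function(start_power_w = 50, increment_w = 50,
                           stage_s = 180, rest_s = 300) {
  if (any(c(start_power_w, increment_w, stage_s, rest_s) <= 0)) {
    stop("all stage_protocol fields must be positive", call. = FALSE)
  }
  structure(list(start_power_w = start_power_w, increment_w = increment_w,
                 stage_s = stage_s, rest_s = rest_s),
            class = "stage_protocol")
}

#' Maximal oxygen uptake from breath-by-breath gas exchange
#'
#' Bins breath-by-breath VO2 into consecutive 10-s intervals aligned to the
#' recording start, then returns the highest mean over three consecutive
#' bins (the plateau-robust convention). With
#' \code{consecutive = FALSE} the mean of the three highest bins anywhere is
#' used instead.
#'
#' @param time_s Breath times (s), strictly increasing.
#' @param vo2_ml_kg_min Breath-by-breath VO2 (ml/kg/min, >= 0).
#' @param bin_s Bin width in seconds (default 10).
#' @param consecutive Require the three bins to be consecutive (default TRUE).
#' @return VO2max in ml/kg/min.
#' @export
vo2max <- function(time_s, vo2_ml_kg_min, bin_s = 10, consecutive = TRUE) {
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (any(vo2_ml_kg_min < 0)) stop("vo2 values must be >= 0", call. = FALSE)
  rel <- time_s - time_s[1]
  n_complete <- floor((rel[length(rel)] + 1e-9) / bin_s)
  if (n_complete < 3L) {
    stop("need at least 3 complete bins (30 s of recording)", call. = FALSE)
  }
  bin <- floor(rel / bin_s)
  keep <- bin < n_complete
  means <- tapply(vo2_ml_kg_min[keep], factor(bin[keep], levels = 0:(n_complete - 1L)),
                  mean)
  if (anyNA(means)) stop("empty 10-s bin in the gas-exchange recording", call. = FALSE)
  means <- as.numeric(means)
  if (consecutive) {
    runs <- (means[1:(n_complete - 2L)] + means[2:(n_complete - 1L)] +
               means[3:n_complete]) / 3
    max(runs)
  } else {
    mean(sort(means, decreasing = TRUE)[1:3])
  }
}

#' Maximal power output with partial-stage interpolation
#'
#' Pmax is the maximal power sustained for a full stage; when the final stage
#' is abandoned early it is linearly interpolated:
#' \code{last_completed + increment * seconds_into_final_stage / stage_s}.
#'
#' @param last_completed_power_w Power of the last fully completed stage (W).
#' @param seconds_into_final_stage Time sustained in the abandoned stage
#'   (s, in \code{[0, stage_s]}).
#' @param protocol A [stage_protocol()].
#' @return Pmax in watts.
#' @examples
#' pmax_interpolated(250, 90)  # 275 W
#' @export
pmax_interpolated <- function(last_completed_power_w, seconds_into_final_stage,
                              protocol = stage_protocol()) {
  s <- seconds_into_final_stage
  if (s < 0 || s > protocol$stage_s) {
    stop(sprintf("seconds_into_final_stage must lie in [0, %g]", protocol$stage_s),
         call. = FALSE)
  }
  last_completed_power_w + protocol$increment_w * s / protocol$stage_s
}

#' Aerobic threshold from the lactate-power plot
#'
#' Returns the power of the first exercise sample whose lactate exceeds the
#' resting value by more than \code{delta_mmol_l} (the numeric criterion for
#' "first rise above resting"; the default 0.5 mmol/l is typical assay
#' noise). With \code{delta_mmol_l = 0} the rule is noise-sensitive: any
#' measurement above rest triggers.
#'
#' @param power_w Exercise powers (W), non-decreasing.
#' @param lactate_mmol_l Lactate at each power (mmol/l, >= 0).
#' @param rest_lactate_mmol_l Resting lactate; if \code{NULL}, the first
#'   sample is treated as the rest-stage measurement and excluded from the
#'   scan.
#' @param delta_mmol_l Required rise above rest (default 0.5).
#' @return Power at the aerobic threshold (W).
#' @examples
#' aerobic_threshold(c(50, 100, 150, 200), c(1.0, 1.1, 1.8, 2.9),
#'                   rest_lactate_mmol_l = 1.0)  # 150
#' @export
aerobic_threshold <- function(power_w, lactate_mmol_l,
                              rest_lactate_mmol_l = NULL,
                              delta_mmol_l = 0.5) {
  if (length(power_w) != length(lactate_mmol_l)) {
    stop("power_w and lactate_mmol_l must have equal length", call. = FALSE)
  }
  if (is.unsorted(power_w)) stop("power_w must be non-decreasing", call. = FALSE)
  if (any(lactate_mmol_l < 0)) stop("lactate values must be >= 0", call. = FALSE)
  if (is.null(rest_lactate_mmol_l)) {
    rest_lactate_mmol_l <- lactate_mmol_l[1]
    power_w <- power_w[-1]
    lactate_mmol_l <- lactate_mmol_l[-1]
  }
  if (length(power_w) < 3L) stop("need at least 3 exercise points", call. = FALSE)
  hit <- which(lactate_mmol_l > rest_lactate_mmol_l + delta_mmol_l)
  if (length(hit) == 0L) {
    stop("lactate never rose above resting value + delta; threshold not found",
         call. = FALSE)
  }
  power_w[hit[1]]
}

#' Group-by-Time interaction on a scalar cohort measure
#'
#' Two-way mixed-design (Group x Time) interaction computed on per-subject
#' T1 - T0 difference scores: the pooled two-sample t between groups, with
#' \code{F = t^2} - mathematically identical to the 2x2 mixed ANOVA
#' interaction. Also reports per-group percent change both as the mean of
#' individual percent changes and as the percent change of group means (the
#' two differ by construction).
#'
#' @param data Long data frame with columns \code{subject}, \code{group},
#'   \code{session} (values \code{"T0"}, \code{"T1"}) and the value column.
#' @param value Name of the value column (default \code{"value"}).
#' @return List with \code{t}, \code{F}, \code{df}, \code{p} (two-sided),
#'   \code{diff_means} (named per-group mean difference), and per group
#'   \code{pct_change_individual}, \code{pct_change_of_means}.
#' @export
scalar_group_time <- function(data, value = "value") {
  need <- c("subject", "group", "session", value)
  if (!all(need %in% names(data))) {
    stop("data must have columns subject, group, session and the value column",
         call. = FALSE)
  }
  wide <- reshape_sessions(data, value)
  g <- wide$group
  if (length(unique(g)) != 2L) stop("need exactly 2 groups", call. = FALSE)
  d <- wide$T1 - wide$T0
  gl <- sort(unique(as.character(g)))
  d1 <- d[g == gl[1]]; d2 <- d[g == gl[2]]
  tt <- pooled_t(d1, d2)
  pct_ind <- c(tapply(100 * (wide$T1 - wide$T0) / wide$T0, g, mean))
  m0 <- c(tapply(wide$T0, g, mean)); m1 <- c(tapply(wide$T1, g, mean))
  list(t = tt$t, F = tt$t^2, df = tt$df, p = tt$p,
       diff_means = stats::setNames(c(mean(d1), mean(d2)), gl),
       pct_change_individual = pct_ind,
       pct_change_of_means = 100 * (m1 - m0) / m0)
}

# long (subject, group, session, value) -> wide with T0/T1 columns;
# errors listing subjects with missing/duplicated sessions
reshape_sessions <- function(data, value) {
  data$session <- as.character(data$session)
  if (!all(data$session %in% c("T0", "T1"))) {
    stop('session labels must be "T0" and "T1"', call. = FALSE)
  }
  subs <- unique(as.character(data$subject))
  bad <- subs[vapply(subs, function(s) {
    ses <- data$session[data$subject == s]
    !(sum(ses == "T0") == 1L && sum(ses == "T1") == 1L)
  }, logical(1))]
  if (length(bad)) {
    stop("subjects without exactly one T0 and one T1 row: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  t0 <- data[data$session == "T0", ]
  t1 <- data[data$session == "T1", ]
  t1 <- t1[match(t0$subject, t1$subject), ]
  grp <- as.character(t0$group)
  if (any(grp != as.character(t1$group))) {
    stop("group label differs between sessions for some subject", call. = FALSE)
  }
  data.frame(subject = t0$subject, group = grp,
             T0 = t0[[value]], T1 = t1[[value]])
}

# pooled-variance two-sample t (group1 - group2), two-sided p;
# zero pooled variance yields +-Inf (or NaN) with degenerate flag
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group", call. = FALSE)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df,
       p = if (is.finite(t)) 2 * stats::pt(-abs(t), df) else if (is.nan(t)) NaN else 0,
       degenerate = !is.finite(t))
}
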