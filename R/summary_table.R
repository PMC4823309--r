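#' Cohort fitness summary table
#'
#' Builds the usual per-parameter summary of a 2x2 design: per group the T0
#' and T1 mean and SD, the mean of individual percent changes, and the
#' Group x Time interaction p-value from [scalar_group_time()].
#'
#' @param data Long data frame with columns \code{subject}, \code{group},
#'   \code{session} and one column per parameter.
#' @param parameters Character vector of parameter column names.
#' @return Data frame with one row per parameter x group.
#' @export
fitness_summary <- function(data, parameters) {
  rows <- list()
  for (p in parameters) {
    d <- data.frame(subject = data$subject, group = data$group,
                    session = data$session, value = data[[p]])
    res <- scalar_group_time(d)
    w <- reshape_sessions(d, "value")
    for (g in sort(unique(as.character(w$group)))) {
      sel <- w$group == g
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, group = g,
        t0_mean = mean(w$T0[sel]), t0_sd = stats::sd(w$T0[sel]),
        t1_mean = mean(w$T1[sel]), t1_sd = stats::sd(w$T1[sel]),
        pct_change = unname(res$pct_change_individual[g]),
        interaction_p = res$p)
    }
  }
  do.call(rbind, rows)
}
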