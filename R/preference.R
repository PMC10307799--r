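#' Virtual side assignment for the blank-monitor control
#'
#' Sessions of the Absent-vs-Absent condition come as ordered two-session
#' sets; position bias is controlled by treating the (absent) stimulus A as
#' associated with the left compartment in the first session of each set and
#' with the right compartment in the second.
#'
#' @param n_sets number of two-session sets.
#' @return character vector of sides, one per session in order.
#' @export
absent_virtual_assignment <- function(n_sets) {
  stopifnot(n_sets >= 1)
  rep(c("left", "right"), n_sets)
}

.zero_guard <- function(x, dt = 1 / 30) {
  if (x > 0) return(x)
  warning("a pooled side time of 0 s was replaced by half a frame")
  dt / 2
}

#' Pooled log time ratio of one condition
#'
#' The preference index: for each period, the time spent in the compartment
#' associated with stimulus A is summed across the condition's eight sessions
#' (left or right compartment per that session's side assignment), likewise
#' for B, and the index is `log10(T_A / T_B)`. Pooling happens *before* the
#' ratio; this is not the mean of per-session log ratios.
#'
#' @param times data frame of session x period compartment times with columns
#'   `session`, `period`, `left_s`, `right_s`, `center_s` (one row per
#'   session x period, as produced by [run_experiment()]).
#' @param a_side character vector, one entry per session in `times` order:
#'   which compartment ("left"/"right") stimulus A occupied in that session.
#' @param require_balance check the 8-session 4/4 side counterbalance
#'   (disable only for toy inputs).
#' @return data frame with one row per period: `time_A`, `time_B`,
#'   `time_center` (s) and `log_ratio`.
#' @export
condition_log_ratio <- function(times, a_side, require_balance = TRUE) {
  sessions <- unique(times$session)
  if (length(a_side) != length(sessions)) {
    stop("need one a_side entry per session")
  }
  if (!all(a_side %in% c("left", "right"))) stop("a_side must be left/right")
  if (require_balance) {
    if (length(sessions) != 8) {
      stop("a condition pools exactly eight sessions (design error)")
    }
    if (sum(a_side == "left") != 4) {
      stop("side assignment must be balanced 4/4 across sessions (design error)")
    }
  }
  side_of <- setNames(a_side, sessions)
  out <- lapply(sort(unique(times$period)), function(p) {
    tp <- times[times$period == p, ]
    a <- side_of[as.character(tp$session)]
    t_a <- sum(ifelse(a == "left", tp$left_s, tp$right_s))
    t_b <- sum(ifelse(a == "left", tp$right_s, tp$left_s))
    data.frame(period = p, time_A = t_a, time_B = t_b,
               time_center = sum(tp$center_s),
               log_ratio = log10(.zero_guard(t_a) / .zero_guard(t_b)))
  })
  do.call(rbind, out)
}

#' Preference records for a whole simulated experiment
#'
#' Applies [condition_log_ratio()] to every fish x condition of an
#' [run_experiment()] result, using each session's planned side assignment
#' (and the virtual left/right alternation for the blank-monitor sets).
#'
#' @param result an `experiment_result`.
#' @return a `preference_table`: data frame with one row per fish x
#'   condition x period and columns `fish`, `condition`, `period`,
#'   `time_A`, `time_B`, `time_center`, `log_ratio`.
#' @export
preference_table <- function(result) {
  tt <- if (inherits(result, "experiment_result")) result$times else result
  out <- list()
  for (fish in unique(tt$fish)) {
    tf <- tt[tt$fish == fish, ]
    for (cond in unique(tf$condition)) {
      tc <- tf[tf$condition == cond, ]
      ord <- order(tc$session, tc$period)
      tc <- tc[ord, ]
      first <- tc[!duplicated(tc$session), ]
      first <- first[order(first$session), ]
      rec <- condition_log_ratio(tc, a_side = first$a_side)
      rec$fish <- fish
      rec$condition <- cond
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  res <- res[, c("fish", "condition", "period", "time_A", "time_B",
                 "time_center", "log_ratio")]
  rownames(res) <- NULL
  class(res) <- c("preference_table", "data.frame")
  res
}

#' @export
print.preference_table <- function(x, ...) {
  cat(sprintf("<preference_table> %d records (%d fish x %d conditions x %d periods)\n",
              nrow(x), length(unique(x$fish)), length(unique(x$condition)),
              length(unique(x$period))))
  print.data.frame(head(as.data.frame(x), 12), row.names = FALSE, digits = 4)
  if (nrow(x) > 12) cat("  ...\n")
  invisible(x)
}

#' Arithmetic mean log ratios per condition and period
#'
#' @param records a `preference_table` (or compatible data frame with
#'   `condition`, `period`, `log_ratio`).
#' @return data frame with `condition`, `period`, `mean_log_ratio`, `se`, `n`.
#' @export
mean_log_ratio <- function(records) {
  agg <- aggregate(log_ratio ~ condition + period, data = records,
                   function(v) c(mean = mean(v),
                                 se = sd(v) / sqrt(length(v)),
                                 n = length(v)))
  out <- data.frame(condition = agg$condition, period = agg$period,
                    mean_log_ratio = agg$log_ratio[, "mean"],
                    se = agg$log_ratio[, "se"], n = agg$log_ratio[, "n"])
  out[order(out$condition, out$period), ]
}

#' Fold-preference scale (antilog of mean log ratios)
#'
#' Back-transforms an arithmetic mean log10 ratio to the original ratio
#' scale; because the mean is taken on logs this is the geometric mean of the
#' per-fish time ratios, the study's fold-preference scale (e.g. a mean log
#' ratio of 0.70 is a 5.02-fold preference).
#'
#' @param mean_log_ratio numeric mean log10 ratio(s).
#' @return the fold preference(s), `10^x`.
#' @export
antilog_scale <- function(mean_log_ratio) {
  if (any(!is.finite(mean_log_ratio))) stop("mean log ratio must be finite")
  10^mean_log_ratio
}

#' Preference scales of every condition in Period 2
#'
#' @param records a `preference_table`.
#' @param period which period to scale (default the stimulus period, 2).
#' @return data frame with `condition`, `mean_log_ratio`, `fold_preference`.
#' @export
preference_scale <- function(records, period = 2) {
  m <- mean_log_ratio(records)
  m <- m[m$period == period, ]
  data.frame(condition = m$condition, mean_log_ratio = m$mean_log_ratio,
             fold_preference = antilog_scale(m$mean_log_ratio))
}
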