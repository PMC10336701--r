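#' Digitized Kaplan-Meier dataset for one arm
#'
#' Container for the digitized step coordinates of a published
#' Kaplan-Meier curve together with its numbers-at-risk table (or, when
#' no risk table was published, the arm size and total event count).
#' Coordinates are monotonicity-repaired on construction: survival is
#' clamped to \[0, 1\] and made non-increasing by a cumulative minimum.
#' The largest repair applied is stored in attribute `"repair"`; repairs
#' above 0.02 (digitization noise beyond the usual read-off error)
#' trigger a warning.
#'
#' @param coords data frame with columns `time` and `surv`; a (0, 1)
#'   point is prepended when absent. Times must be strictly increasing.
#' @param risk_table optional data frame with columns `time` and
#'   `n_risk`, non-increasing in time; its first entry defines the arm
#'   size.
#' @param n_start arm size at time 0 (required when `risk_table` is
#'   `NULL`).
#' @param total_events optional total number of events in the arm, used
#'   as the constraint when no risk table is available.
#' @param arm_id arm label.
#' @return an object of class `km_dataset`.
#' @export
km_dataset <- function(coords, risk_table = NULL, n_start = NULL,
                       total_events = NULL, arm_id = "arm") {
  stopifnot(is.data.frame(coords), all(c("time", "surv") %in% names(coords)))
  coords <- coords[order(coords$time), c("time", "surv")]
  if (nrow(coords) == 0L || coords$time[1] > 0) {
    coords <- rbind(data.frame(time = 0, surv = 1), coords)
  }
  if (any(diff(coords$time) <= 0)) {
    stop("coordinate times must be strictly increasing", call. = FALSE)
  }
  repaired <- pmin(pmax(coords$surv, 0), 1)
  repaired <- cummin(repaired)
  repair <- max(abs(repaired - coords$surv))
  if (repair > 0.02) {
    warning("monotonicity repair of digitized coordinates changed ",
            "survival by up to ", signif(repair, 3), call. = FALSE)
  }
  coords$surv <- repaired
  if (!is.null(risk_table)) {
    stopifnot(is.data.frame(risk_table),
              all(c("time", "n_risk") %in% names(risk_table)))
    risk_table <- risk_table[order(risk_table$time),
                             c("time", "n_risk")]
    if (any(diff(risk_table$n_risk) > 0)) {
      stop("numbers at risk must be non-increasing over time",
           call. = FALSE)
    }
    if (risk_table$time[1] > 0) {
      stop("risk table must start at time 0", call. = FALSE)
    }
    n_start <- risk_table$n_risk[1]
  }
  if (is.null(n_start)) {
    stop("either a risk table or n_start must be supplied", call. = FALSE)
  }
  structure(list(coords = coords, risk_table = risk_table,
                 n_start = as.integer(n_start),
                 total_events = if (is.null(total_events)) NULL
                                else as.integer(total_events),
                 arm_id = arm_id),
            class = "km_dataset", repair = repair)
}

#' @export
print.km_dataset <- function(x, ...) {
  cat("Kaplan-Meier dataset for arm '", x$arm_id, "': ",
      nrow(x$coords), " coordinates, n at start = ", x$n_start,
      if (is.null(x$risk_table)) " (totals only)" else
        paste0(", risk table at ", nrow(x$risk_table), " times"),
      "\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier estimate from patient-level records
#'
#' Product-limit estimate (via [survival::survfit()]) with step
#' coordinates at event times and a numbers-at-risk table on a regular
#' grid, i.e., the same shape as a digitized published curve.
#'
#' @param ipd data frame with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @param risk_interval spacing of the risk table grid (from 0 to the
#'   last observed time).
#' @param risk_times optional explicit risk-table times (overrides
#'   `risk_interval`).
#' @param arm_id arm label.
#' @return a [km_dataset()].
#' @export
km_estimate <- function(ipd, risk_interval = 1, risk_times = NULL,
                        arm_id = "arm") {
  stopifnot(nrow(ipd) >= 1, all(c("time", "event") %in% names(ipd)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  sm <- summary(fit, censored = FALSE)
  keep <- sm$n.event > 0
  coords <- if (length(keep) > 0 && any(keep)) {
    data.frame(time = sm$time[keep], surv = sm$surv[keep])
  } else {
    data.frame(time = numeric(0), surv = numeric(0))
  }
  if (is.null(risk_times)) {
    risk_times <- seq(0, max(ipd$time), by = risk_interval)
  }
  at <- summary(fit, times = risk_times, extend = TRUE)
  risk_table <- data.frame(time = at$time, n_risk = at$n.risk)
  km_dataset(coords, risk_table = risk_table,
             total_events = sum(ipd$event), arm_id = arm_id)
}

# Count censor times falling into the coordinate gaps
# [t[k], t[k+1]) for k in ks, with the interval closed by `end`.
censor_counts <- function(cen_times, t, ks, end) {
  if (length(ks) == 0L) return(integer(0))
  breaks <- c(t[ks], end)
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  counts <- integer(length(ks))
  if (length(cen_times) > 0) {
    idx <- findInterval(cen_times, breaks, rightmost.closed = TRUE)
    idx[idx < 1] <- 1
    idx[idx > length(ks)] <- length(ks)
    tab <- tabulate(idx, nbins = length(ks))
    counts <- tab
  }
  counts
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Re-implements the standard iterative algorithm for recovering
#' approximate patient-level (time, event) records from digitized
#' Kaplan-Meier coordinates and a numbers-at-risk table: within each
#' inter-risk-table interval, the number of censored patients is solved
#' so that the number at risk at the start of the next interval matches
#' the published table, censoring is spread uniformly within the
#' interval, and event counts at each coordinate are derived from the
#' digitized survival drops. When only arm totals are available, the
#' total event count is matched instead, assuming a constant censoring
#' rate over follow-up.
#'
#' @param km a [km_dataset()].
#' @return data frame of class `reconstructed_ipd` with columns `time`,
#'   `event`, `arm`; one row per patient (`nrow` equals the initial
#'   number at risk).
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "km_dataset"))
  t_s <- km$coords$time
  s <- km$coords$surv
  K <- length(t_s)
  if (!is.null(km$risk_table) && nrow(km$risk_table) > 1L) {
    trisk <- km$risk_table$time
    nrisk <- km$risk_table$n_risk
  } else {
    trisk <- 0
    nrisk <- km$n_start
  }
  if (any(nrisk > nrisk[1])) {
    stop("reconstruction infeasible: a published at-risk count exceeds ",
         "the arm size", call. = FALSE)
  }
  n_int <- length(trisk)
  t_end <- max(t_s[K], trisk[n_int])
  # digitized survival as a right-continuous step function
  s_at <- function(tt) s[pmax(findInterval(tt + 1e-9, t_s), 1L)]
  # coordinate indices belonging to risk interval j (possibly none)
  interval_ks <- function(j) {
    end_j <- if (j < n_int) trisk[j + 1] else Inf
    which(t_s >= trisk[j] - 1e-9 & t_s < end_j - 1e-9)
  }

  d <- integer(K)                    # events at each coordinate
  cen_times <- vector("list", n_int) # censoring times per risk interval
  cen_int <- integer(n_int)          # censor counts per risk interval

  # Censor times for a constant censoring *rate*: spread in proportion
  # to the digitized survival curve (at-risk is proportional to S).
  km_weighted_times <- function(n_censor) {
    seg_len <- diff(c(t_s, t_end))
    seg_val <- pmax(s, 1e-6)
    cum <- c(0, cumsum(seg_len * seg_val))
    tot <- cum[length(cum)]
    q <- seq_len(n_censor) / (n_censor + 1) * tot
    idx <- pmin(pmax(findInterval(q, cum, rightmost.closed = TRUE), 1L),
                length(seg_len))
    t_s[idx] + (q - cum[idx]) / seg_val[idx]
  }

  # Walk the coordinates of one interval for a trial censor count;
  # events at each coordinate follow from the digitized drops relative
  # to the running product-limit value.
  process_interval <- function(j, n_censor, n_at_start, km_last) {
    end_j <- if (j < n_int) trisk[j + 1] else t_end
    ks <- interval_ks(j)
    totals_only <- n_int == 1L && !is.null(km$total_events)
    ct <- if (n_censor <= 0) {
      numeric(0)
    } else if (totals_only) {
      km_weighted_times(n_censor)
    } else {
      trisk[j] + seq_len(n_censor) * (end_j - trisk[j]) / (n_censor + 1)
    }
    cc <- censor_counts(ct, t_s, ks, end_j)
    n_cur <- n_at_start
    dd <- integer(length(ks))
    kml <- km_last
    for (ii in seq_along(ks)) {
      k <- ks[ii]
      if (k > 1L) {
        ev <- if (n_cur > 0 && kml > 0) {
          round(n_cur * (1 - s[k] / kml))
        } else 0
        ev <- min(max(ev, 0), n_cur)
        dd[ii] <- as.integer(ev)
        if (ev > 0) kml <- kml * (1 - ev / n_cur)
      }
      n_cur <- max(n_cur - dd[ii] - cc[ii], 0)
    }
    if (length(ks) == 0L) n_cur <- max(n_cur - n_censor, 0)
    list(d = dd, cen_times = ct, n_next = n_cur, km_last = kml)
  }

  n_cur <- nrisk[1]
  km_last <- 1
  for (j in seq_len(n_int)) {
    target <- if (j < n_int) nrisk[j + 1] else NA_integer_
    if (j < n_int) {
      s0 <- s_at(trisk[j])
      guess <- round(n_cur * (if (s0 > 0) s_at(trisk[j + 1]) / s0 else 1) -
                       target)
    } else if (!is.null(km$total_events)) {
      guess <- 0L
    } else {
      # carry forward the censoring rate observed so far
      prev_span <- trisk[n_int] - trisk[1]
      rate <- if (prev_span > 0) sum(cen_int) / prev_span else 0
      guess <- round(rate * (t_end - trisk[n_int]))
    }
    n_censor <- min(max(as.integer(guess), 0L), n_cur)
    res <- process_interval(j, n_censor, n_cur, km_last)
    for (iter in 1:60) {
      if (j < n_int) {
        diff <- res$n_next - target
      } else if (!is.null(km$total_events)) {
        diff <- sum(d[t_s < trisk[j] - 1e-9]) + sum(res$d) -
          km$total_events
      } else break
      if (diff == 0 || (n_censor == 0L && diff < 0) ||
          (n_censor >= n_cur && diff > 0)) break
      n_censor <- min(max(n_censor + as.integer(diff), 0L), n_cur)
      res <- process_interval(j, n_censor, n_cur, km_last)
    }
    # never assign more patients than are at risk in the interval
    guard <- 0L
    while (sum(res$d) + length(res$cen_times) > n_cur && guard < 10L) {
      n_censor <- max(n_cur - sum(res$d), 0L)
      res <- process_interval(j, n_censor, n_cur, km_last)
      guard <- guard + 1L
    }
    d[interval_ks(j)] <- res$d
    cen_times[[j]] <- res$cen_times
    cen_int[j] <- length(res$cen_times)
    n_cur <- res$n_next
    km_last <- res$km_last
  }

  event_times <- rep(t_s, d)
  censor_t <- unlist(cen_times)
  n_assigned <- length(event_times) + length(censor_t)
  n_rest <- nrisk[1] - n_assigned
  if (n_rest < 0) {
    stop("reconstruction produced more patients than the arm size",
         call. = FALSE)
  }
  out <- data.frame(
    time = c(event_times, censor_t, rep(t_end, n_rest)),
    event = c(rep(1L, length(event_times)),
              rep(0L, length(censor_t) + n_rest)),
    arm = km$arm_id,
    stringsAsFactors = FALSE)
  out <- out[order(out$time, -out$event), ]
  rownames(out) <- NULL
  class(out) <- c("reconstructed_ipd", "data.frame")
  out
}

#' Log hazard ratio from two reconstructed arms by Cox regression
#'
#' Fits a Cox proportional-hazards model with a single binary covariate
#' (treatment vs. control) to the pooled patient-level records and
#' returns the log hazard ratio with its standard error from the inverse
#' observed information. Efron's method is the default for the heavy ties
#' produced by interval-based reconstruction.
#'
#' @param treat,ctrl data frames with columns `time` and `event`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `effect_estimate` with elements `loghr`, `se`,
#'   `n` (named per arm), `events` (named per arm), `ties`.
#' @export
cox_loghr <- function(treat, ctrl, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(treat)),
            all(c("time", "event") %in% names(ctrl)))
  if (sum(treat$event) + sum(ctrl$event) < 1) {
    stop("no events in either arm; log hazard ratio is not estimable",
         call. = FALSE)
  }
  df <- rbind(data.frame(time = treat$time, event = treat$event, z = 1L),
              data.frame(time = ctrl$time, event = ctrl$event, z = 0L))
  fit <- survival::coxph(survival::Surv(time, event) ~ z, data = df,
                         ties = ties)
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 1)) {
    stop("Cox partial-likelihood maximisation did not converge",
         call. = FALSE)
  }
  structure(list(loghr = unname(stats::coef(fit)[1]),
                 se = unname(sqrt(fit$var[1, 1])),
                 n = c(treat = nrow(treat), ctrl = nrow(ctrl)),
                 events = c(treat = sum(treat$event),
                            ctrl = sum(ctrl$event)),
                 ties = ties),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("logHR = %.4f (SE %.4f); n = %d/%d, events = %d/%d [%s ties]\n",
              x$loghr, x$se, x$n["treat"], x$n["ctrl"],
              x$events["treat"], x$events["ctrl"], x$ties))
  invisible(x)
}

#' Read a digitized Kaplan-Meier dataset from CSV files
#'
#' @param coords_path CSV with columns `time`, `surv`.
#' @param risk_path optional CSV with columns `time`, `n_risk`.
#' @param n_start,total_events totals used when no risk table exists.
#' @param arm_id arm label.
#' @return a [km_dataset()].
#' @export
read_km_dataset <- function(coords_path, risk_path = NULL, n_start = NULL,
                            total_events = NULL, arm_id = "arm") {
  coords <- utils::read.csv(coords_path)
  risk <- if (!is.null(risk_path)) utils::read.csv(risk_path) else NULL
  km_dataset(coords, risk_table = risk, n_start = n_start,
             total_events = total_events, arm_id = arm_id)
}

#' Write a Kaplan-Meier dataset to CSV files
#'
#' @param km a [km_dataset()].
#' @param coords_path output CSV for the coordinates.
#' @param risk_path optional output CSV for the risk table.
#' @return `coords_path`, invisibly.
#' @export
write_km_dataset <- function(km, coords_path, risk_path = NULL) {
  utils::write.csv(km$coords, coords_path, row.names = FALSE, quote = FALSE)
  if (!is.null(risk_path) && !is.null(km$risk_table)) {
    utils::write.csv(km$risk_table, risk_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(coords_path)
}

#' Write reconstructed patient-level records to CSV
#'
#' Columns are `time`, `event`, `arm`, in that order.
#'
#' @param ipd data frame from [reconstruct_ipd()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(ipd[, c("time", "event", "arm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
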