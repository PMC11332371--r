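#' Artificially censor follow-up at deviation from a treatment strategy
#'
#' Builds the modified validation set \eqn{V_a}: each subject's follow-up is
#' censored at the first visit at which their observed treatment deviates from
#' the strategy of interest, which can be visit 0. With \eqn{C_a} the first
#' deviation visit (\eqn{+\infty} if the subject never deviates during
#' follow-up), the censored observation time is \eqn{\tilde T = \min(T^*,
#' C_a)} and the event indicator \eqn{\tilde D = I(T^* < C_a) D}: an event
#' occurring exactly at the deviation visit is treated as censored (the
#' indicator is strict). Subjects deviating at visit 0 remain in the set with
#' zero follow-up, so that treatment models fitted at visit 0 still see them.
#'
#' @param table a validated `cf_longitudinal` table.
#' @param strat a `cf_strategy`.
#' @return an object of class `cf_censored`: a list with `subjects` (one row
#'   per subject: `id`, `Ca`, `T_tilde`, `D_tilde`, original `event_time` and
#'   `event_indicator`, `n_adherent_visits`), `data` (the input table, with an
#'   `adherent` flag per row), and `strategy`.
#' @export
apply_artificial_censoring <- function(table, strat) {
  stopifnot(inherits(table, "cf_longitudinal"), inherits(strat, "cf_strategy"))
  a_k <- strategy_actions(strat, table$visit)
  dev_row <- table$A != a_k

  ids <- unique(table$id)
  idx <- match(table$id, ids)
  n <- length(ids)

  # first deviation visit per subject (+Inf if none)
  Ca <- rep(Inf, n)
  if (any(dev_row)) {
    dv <- tapply(table$visit[dev_row], idx[dev_row], min)
    Ca[as.integer(names(dv))] <- as.numeric(dv)
  }

  first_row <- which(!duplicated(idx))
  Tstar <- table$event_time[first_row]
  D <- table$event_indicator[first_row]

  T_tilde <- pmin(Tstar, Ca)
  D_tilde <- as.numeric(Tstar < Ca) * D
  # adherent visits = visits strictly before Ca (all recorded visits when Ca = Inf)
  adh_vis <- table$visit < Ca[idx]
  n_adherent <- as.integer(tapply(adh_vis, idx, sum))

  data <- table
  data$adherent <- table$visit < Ca[idx]

  subjects <- data.frame(id = ids, Ca = Ca, T_tilde = T_tilde,
                         D_tilde = D_tilde, event_time = Tstar,
                         event_indicator = D,
                         n_adherent_visits = n_adherent,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, data = data, strategy = strat),
            class = "cf_censored")
}

#' @export
print.cf_censored <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<cf_censored> strategy '%s': %d subjects, %d artificially censored (%d at visit 0), %d events retained\n",
              x$strategy$label, nrow(s), sum(is.finite(s$Ca)),
              sum(s$Ca == 0), sum(s$D_tilde == 1)))
  invisible(x)
}

#' Per-visit adherence summary of an artificially censored set
#'
#' Supports the positivity diagnostic: for each visit k it reports the number
#' of subjects contributing adherent person-time at k, the number artificially
#' censored at k, and the proportion adherent among subjects eligible at k.
#' A warning is raised if no adherent person-time remains from some visit
#' onwards while subjects were still eligible.
#'
#' @param censored a `cf_censored` set.
#' @return a data.frame with columns `visit`, `n_at_risk`,
#'   `n_artificially_censored`, `n_eligible`, `prop_adherent`.
#' @export
adherence_summary <- function(censored) {
  stopifnot(inherits(censored, "cf_censored"))
  s <- censored$subjects
  kmax <- max(censored$data$visit)
  out <- do.call(rbind, lapply(0:kmax, function(k) {
    eligible <- s$Ca >= k & floor(s$event_time) >= k   # has a visit-k record in V_a
    cens_k <- sum(s$Ca == k)
    at_risk <- sum(s$Ca > k & s$T_tilde > k)
    data.frame(visit = k, n_at_risk = at_risk,
               n_artificially_censored = cens_k,
               n_eligible = sum(eligible),
               prop_adherent = if (sum(eligible)) 1 - cens_k / sum(eligible) else NA_real_)
  }))
  bad <- out$visit[out$n_at_risk == 0 & out$n_eligible > 0]
  if (length(bad))
    warn_fmt("positivity: no adherent person-time at visit(s) %s under strategy '%s'",
             paste(bad, collapse = ", "), censored$strategy$label)
  out
}
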