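#' Unpaired Welch t-test
#'
#' Two-sample t-test for equal means without assuming equal variances:
#' `t = (mean(a) - mean(b)) / sqrt(va/na + vb/nb)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Significance is flagged at the
#' 0.1 (*) and 0.05 (**) margins used throughout the group comparisons.
#'
#' Degenerate samples (both variances zero) use the conventions p = 1 when
#' the means are equal and p = 0 when they differ.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return A one-row data.frame of class `welch_test` with columns
#'   `t_stat`, `dof`, `p_value`, `sig_010`, `sig_005`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_xlf("each sample needs n >= 2 (got %d and %d)", length(a), length(b))
  if (any(!is.finite(a)) || any(!is.finite(b))) stop_xlf("samples must be finite")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    equal <- mean(a) == mean(b)
    t_stat <- if (equal) 0 else sign(mean(a) - mean(b)) * Inf
    out <- data.frame(t_stat = t_stat, dof = na + nb - 2,
                      p_value = if (equal) 1 else 0)
  } else {
    t_stat <- (mean(a) - mean(b)) / sqrt(se2)
    dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    out <- data.frame(t_stat = t_stat, dof = dof,
                      p_value = 2 * pt(-abs(t_stat), df = dof))
  }
  out$sig_010 <- out$p_value < 0.1
  out$sig_005 <- out$p_value < 0.05
  class(out) <- c("welch_test", "data.frame")
  out
}

as_summary_df <- function(g, name) {
  if (inherits(g, "scan_summary") || is.data.frame(g)) return(as.data.frame(g))
  if (is.list(g)) return(do.call(rbind, lapply(g, as.data.frame)))
  stop_xlf("group '%s' must be a data.frame of scan summaries or a list of them", name)
}

#' Compare groups of scan summaries parameter by parameter
#'
#' Pairwise unpaired Welch t-tests of every requested parameter between every
#' pair of groups (e.g. healthy controls vs allergic-inflammation vs treated
#' animals). No multiple-testing correction is applied by default, mirroring
#' the original analysis; `holm = TRUE` applies a Holm correction across the
#' parameters within each group pair.
#'
#' @param groups named list; each element a data.frame of scan summaries
#'   (rows = animals/scans) or a list of `scan_summary` rows.
#' @param params parameter column names to test
#'   (default `b1, b3, b5, t_in_pct`).
#' @param holm apply Holm correction within each group pair (default FALSE).
#' @return A data.frame of class `group_comparison`: one row per group pair
#'   and parameter, with group means, SDs, sizes and the Welch test columns.
#' @export
compare_groups <- function(groups, params = c("b1", "b3", "b5", "t_in_pct"),
                           holm = FALSE) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_xlf("'groups' must be a named list")
  dfs <- Map(as_summary_df, groups, names(groups))
  for (nm in names(dfs)) {
    if (nrow(dfs[[nm]]) < 2L) stop_xlf("group '%s' too small: need >= 2 scans", nm)
    missing <- setdiff(params, names(dfs[[nm]]))
    if (length(missing))
      stop_xlf("unknown parameter(s) in group '%s': %s", nm, paste(missing, collapse = ", "))
  }
  pairs <- utils::combn(names(dfs), 2L, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    tests <- lapply(params, function(p)
      welch_t_test(dfs[[pr[1L]]][[p]], dfs[[pr[2L]]][[p]]))
    pv <- vapply(tests, function(tt) tt$p_value, 0)
    if (holm) pv <- stats::p.adjust(pv, method = "holm")
    for (i in seq_along(params)) {
      p <- params[i]; tt <- tests[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = pr[1L], group2 = pr[2L], parameter = p,
        n1 = nrow(dfs[[pr[1L]]]), n2 = nrow(dfs[[pr[2L]]]),
        mean1 = mean(dfs[[pr[1L]]][[p]]), mean2 = mean(dfs[[pr[2L]]][[p]]),
        sd1 = sd(dfs[[pr[1L]]][[p]]), sd2 = sd(dfs[[pr[2L]]][[p]]),
        t_stat = tt$t_stat, dof = tt$dof, p_value = pv[i],
        sig_010 = pv[i] < 0.1, sig_005 = pv[i] < 0.05)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Methacholine dose-response analysis
#'
#' Airway responsiveness is quantified as the relative change of each
#' parameter to its baseline value, per animal:
#' `100 * (v - v0) / v0` (%), where `v0` is the animal's measurement at the
#' first (baseline, 0 mg/ml) concentration. Each post-baseline dose is tested
#' against the all-zero baseline changes with an unpaired Welch t-test.
#'
#' @param per_dose_summaries list (ordered by dose) of scan-summary
#'   data.frames; rows are animals, aligned across doses (each animal is its
#'   own baseline).
#' @param doses numeric concentrations (mg/ml); the first must be the
#'   baseline, conventionally 0.
#' @param params parameter columns to analyze.
#' @return A list of class `dose_response` with `changes` (long data.frame:
#'   dose, parameter, animal, rel_change_pct) and `tests` (per dose and
#'   parameter Welch test vs baseline).
#' @export
dose_response <- function(per_dose_summaries, doses,
                          params = c("b1", "b3", "b5", "t_in_pct")) {
  if (length(per_dose_summaries) != length(doses))
    stop_xlf("need one summary set per dose")
  if (length(doses) < 2L) stop_xlf("need a baseline plus at least one dose")
  if (is.unsorted(doses)) stop_xlf("doses must be in increasing order")
  dfs <- lapply(per_dose_summaries, as_summary_df, name = "dose")
  n <- nrow(dfs[[1L]])
  if (any(vapply(dfs, nrow, 0L) != n))
    stop_xlf("equal animal counts required across doses (paired by animal)")
  changes <- list(); tests <- list()
  for (p in params) {
    v0 <- dfs[[1L]][[p]]
    if (any(v0 == 0)) stop_xlf("baseline value is zero for parameter '%s'", p)
    for (d in seq_along(doses)) {
      rel <- 100 * (dfs[[d]][[p]] - v0) / v0
      changes[[length(changes) + 1L]] <- data.frame(
        dose = doses[d], parameter = p, animal = seq_len(n), rel_change_pct = rel)
      if (d > 1L) {
        tt <- welch_t_test(rel, rep(0, n))
        tests[[length(tests) + 1L]] <- cbind(
          data.frame(dose = doses[d], parameter = p,
                     mean_rel_change_pct = mean(rel)), as.data.frame(tt))
      }
    }
  }
  structure(list(changes = do.call(rbind, changes),
                 tests = do.call(rbind, tests),
                 doses = doses),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("dose_response over", paste(x$doses, collapse = "/"), "mg/ml\n")
  print(x$tests, digits = 4)
  invisible(x)
}
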