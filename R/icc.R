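# Test-retest and between-subject reliability of connectopic maps:
# ICC(2,1), the two-way random-effects absolute-agreement single-measure
# intraclass correlation, with bootstrap confidence intervals of means.

#' ICC(2,1): two-way random-effects absolute-agreement single-measure ICC
#'
#' With targets as rows and raters as columns, the two-way ANOVA mean
#' squares (rows `MS_R`, columns `MS_C`, error `MS_E`) give
#' `ICC(2,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)`.
#'
#' @param ratings an n x k numeric matrix (n targets, k raters)
#' @return a scalar in [-1, 1]
#' @export
icc_2_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters", call. = FALSE)
  grand <- mean(ratings)
  if (sum((ratings - grand)^2) == 0)
    stop("zero total variance; ICC undefined", call. = FALSE)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  ms_r <- ss_row / (n - 1)
  ms_c <- ss_col / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
}

# percentile bootstrap CI of the mean of x, resampling its elements
boot_ci_mean <- function(x, n_boot, seed) {
  with_seed(seed, {
    bm <- vapply(seq_len(n_boot), function(b)
      mean(x[sample.int(length(x), replace = TRUE)]), numeric(1))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE, type = 7)
  })
}

icc_result <- function(comparison, mode, per_unit, mean_icc, ci,
                       session = NA) {
  structure(list(comparison = comparison, mode = mode, session = session,
                 per_unit = per_unit, mean = mean_icc,
                 ci_low = ci[1], ci_high = ci[2]),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) %s, mode g%d%s: %.3f [%.3f-%.3f] over %d pair(s)\n",
              x$comparison, x$mode,
              if (!is.na(x$session)) paste0(", session ", x$session) else "",
              x$mean, x$ci_low, x$ci_high, length(x$per_unit)))
  invisible(x)
}

# collect maps into a subject x session table of value matrices
cohort_table <- function(cohort_maps) {
  subj <- vapply(cohort_maps, function(x) as.character(x$subject), character(1))
  sess <- vapply(cohort_maps, function(x) as.character(x$session), character(1))
  list(subjects = sort(unique(subj)), sessions = sort(unique(sess)),
       subj = subj, sess = sess)
}

#' Between-session (test-retest) ICC of a cohort's connectopic maps
#'
#' Per subject, ICC(2,1) over vertices with that subject's two (or more)
#' sessions as raters; reported as the mean over subjects with a
#' percentile bootstrap 95% CI of that mean (resampling subjects).
#'
#' @param cohort_maps list of aligned [connectopic_map()]s with `subject`
#'   and `session` labels; every subject needs every session
#' @param mode gradient mode to analyse
#' @param n_boot bootstrap resamples
#' @param rng_seed integer seed
#' @return an `icc_result` with per-subject ICCs in `per_unit`
#' @export
between_session_icc <- function(cohort_maps, mode = 1L, n_boot = 10000L,
                                rng_seed = 1L) {
  tab <- cohort_table(cohort_maps)
  if (length(tab$sessions) < 2)
    stop("need at least two sessions", call. = FALSE)
  per_subject <- vapply(tab$subjects, function(s) {
    idx <- which(tab$subj == s)
    have <- tab$sess[idx]
    if (!all(tab$sessions %in% have))
      stop("subject ", s, " is missing session(s): ",
           paste(setdiff(tab$sessions, have), collapse = ", "), call. = FALSE)
    ratings <- vapply(tab$sessions, function(ss)
      cohort_maps[[idx[which(have == ss)[1]]]]$values[, mode],
      numeric(nrow(cohort_maps[[idx[1]]]$values)))
    icc_2_1(ratings)
  }, numeric(1))
  ci <- boot_ci_mean(per_subject, n_boot,
                     derive_seed(rng_seed, "icc-between-session", mode))
  icc_result("between_sessions", as.integer(mode), per_subject,
             mean(per_subject), ci)
}

#' Between-subject ICC within one session
#'
#' ICC(2,1) over vertices for every unordered pair of distinct subjects
#' within the session; reported as the mean over pairs with a percentile
#' bootstrap 95% CI of that mean.
#'
#' @inheritParams between_session_icc
#' @param session which session to analyse
#' @param resample bootstrap unit: `"pairs"` (default) or `"subjects"`
#'   (resample subjects, keep the pairs among them)
#' @return an `icc_result` with per-pair ICCs in `per_unit`
#' @export
between_subject_icc <- function(cohort_maps, session, mode = 1L,
                                n_boot = 10000L, rng_seed = 1L,
                                resample = c("pairs", "subjects")) {
  resample <- match.arg(resample)
  tab <- cohort_table(cohort_maps)
  session <- as.character(session)
  idx <- which(tab$sess == session)
  subs <- tab$subj[idx]
  if (length(unique(subs)) < 2)
    stop("need at least two subjects in session ", session, call. = FALSE)
  usub <- sort(unique(subs))
  map_of <- lapply(stats::setNames(nm = usub), function(s)
    cohort_maps[[idx[which(subs == s)[1]]]]$values[, mode])
  pairs <- utils::combn(usub, 2)
  per_pair <- apply(pairs, 2L, function(p)
    icc_2_1(cbind(map_of[[p[1]]], map_of[[p[2]]])))
  seed <- derive_seed(rng_seed, "icc-between-subject", session, mode)
  if (resample == "pairs") {
    ci <- boot_ci_mean(per_pair, n_boot, seed)
  } else {
    ci <- with_seed(seed, {
      bm <- vapply(seq_len(n_boot), function(b) {
        bs <- sample(usub, replace = TRUE)
        keep <- apply(pairs, 2L, function(p) p[1] %in% bs && p[2] %in% bs)
        if (!any(keep)) return(NA_real_)
        mean(per_pair[keep])
      }, numeric(1))
      stats::quantile(bm, c(0.025, 0.975), names = FALSE, type = 7, na.rm = TRUE)
    })
  }
  icc_result("between_subjects", as.integer(mode), per_pair,
             mean(per_pair), ci, session = session)
}
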