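# Clinical score derivations and cohort-level group statistics: HDRS percent
# change, Cohen's d of the change, pooled two-sample t from printed summaries,
# a 50:50 sex-ratio chi-squared test and the paired pre/post t-test.

#' HDRS percent change
#'
#' `(baseline - post) / baseline`, as a fraction; positive values denote
#' improvement, negative values worsening.
#'
#' @param baseline,post HDRS scores (vectors allowed); `baseline` must be
#'   strictly positive.
#' @return Fractional change, same length as the inputs.
#' @export
pct_change <- function(baseline, post) {
  if (any(baseline <= 0)) stop("HDRS baseline must be > 0 to derive % change")
  (baseline - post) / baseline
}

#' Cohen's d of a within-group change
#'
#' `d = mean(changes) / sd(changes)` with the sample (n-1) standard
#' deviation. Either raw change scores or a printed (mean, sd) summary may be
#' supplied.
#'
#' @param changes Numeric vector of change scores; ignored when `mean` and
#'   `sd` are given.
#' @param mean,sd Optional summary statistics in place of raw scores.
#' @return Cohen's d.
#' @export
cohens_d_change <- function(changes = NULL, mean = NULL, sd = NULL) {
  if (!is.null(mean) && !is.null(sd)) {
    if (sd <= 0) stop("zero or negative SD: Cohen's d undefined")
    return(mean / sd)
  }
  if (length(changes) < 2L) stop("need >= 2 change scores")
  s <- stats::sd(changes)
  if (s == 0) stop("zero SD across change scores: Cohen's d undefined")
  base::mean(changes) / s
}

#' Pooled two-sample t-test from group summaries
#'
#' Student's pooled-variance independent-samples t-test computed from
#' printed group means, SDs and sizes; `df = n1 + n2 - 2`.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param var_equal Pooled-variance Student t when `TRUE` (default); Welch
#'   t with Satterthwaite df when `FALSE`. Published demographic tables mix
#'   the two conventions, so both are provided.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
two_sample_t_summary <- function(m1, sd1, n1, m2, sd2, n2, var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    if (sp2 <= 0) stop("zero pooled variance")
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    if (se2 <= 0) stop("zero variance in both groups")
    tval <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Chi-squared test of a sex ratio against 50:50
#'
#' Goodness-of-fit chi-squared with equal expected counts and no continuity
#' correction.
#'
#' @param n_male,n_female Observed counts.
#' @return List with `chi2`, `df` (= 1) and `p`.
#' @export
sex_ratio_chisq <- function(n_male, n_female) {
  n <- n_male + n_female
  if (n < 1) stop("empty sample")
  e <- n / 2
  chi2 <- (n_male - e)^2 / e + (n_female - e)^2 / e
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Paired t-test of pre vs post scores
#'
#' One-sample t-test on the paired differences `pre - post`.
#'
#' @param pre_scores,post_scores Equal-length numeric vectors.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
paired_t <- function(pre_scores, post_scores) {
  stopifnot(length(pre_scores) == length(post_scores),
            length(pre_scores) >= 2)
  d <- pre_scores - post_scores
  s <- stats::sd(d)
  n <- length(d)
  if (s == 0) {
    # identical pre/post is a well-defined no-change result; a constant
    # nonzero difference has an undefined t
    if (all(d == 0)) return(list(t = 0, df = n - 1L, p = 1))
    stop("zero-variance differences")
  }
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1))
}

#' Cohort summary table (demographics and HDRS outcomes by sex)
#'
#' Emits a Table-1-style data.frame: per-variable overall and by-sex means
#' (SD) plus the male-vs-female test p-value (pooled t for continuous rows,
#' 50:50 chi-squared for the subject-count row).
#'
#' @param subjects Subjects data.frame (see [read_subjects()]).
#' @return A data.frame with one row per variable.
#' @export
clinical_table <- function(subjects) {
  if (is.null(subjects$hdrs_pct_change))
    subjects$hdrs_pct_change <- pct_change(subjects$hdrs_baseline,
                                           subjects$hdrs_post)
  male <- subjects$sex == 0
  fem <- subjects$sex == 1
  vars <- list(age = subjects$age,
               hdrs_baseline = subjects$hdrs_baseline,
               hdrs_post = subjects$hdrs_post,
               hdrs_pct_change = subjects$hdrs_pct_change * 100)
  fmt <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  rows <- lapply(names(vars), function(nm) {
    x <- vars[[nm]]
    p <- two_sample_t_summary(mean(x[male]), stats::sd(x[male]), sum(male),
                              mean(x[fem]), stats::sd(x[fem]), sum(fem))$p
    data.frame(variable = nm, all = fmt(x), males = fmt(x[male]),
               females = fmt(x[fem]), p_value = round(p, 3))
  })
  chisq <- sex_ratio_chisq(sum(male), sum(fem))
  header <- data.frame(variable = "n_subjects",
                       all = as.character(nrow(subjects)),
                       males = as.character(sum(male)),
                       females = as.character(sum(fem)),
                       p_value = round(chisq$p, 3))
  rbind(header, do.call(rbind, rows))
}
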