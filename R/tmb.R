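# RNA-based tumor mutational burden and survival stratification.
#
# TMB here is the raw count of non-silent somatic SNVs per sample (no
# per-megabase normalization, which would require a coverage footprint).
# Stratifications: median split into low/high, and a three-group split with
# a very-high tier at the top percentile; significance via the logrank test
# and a multivariate Cox proportional-hazards model on log10(TMB + 1), age
# and ordinal tumor stage.

# Non-silent classifications: variants predicted to alter the protein.
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Translation_Start_Site")
}

#' Tumor mutational burden per sample
#'
#' Counts non-silent somatic SNVs per sample.
#'
#' @param variants data.frame of final somatic variants with
#'   \code{sample_id} and \code{variant_classification}.
#' @param sample_ids optional vector of sample identifiers to report
#'   (samples without variants get TMB 0); defaults to the samples present.
#' @return named integer vector of TMB values.
#' @export
compute_tmb <- function(variants, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- sort(unique(variants$sample_id))
  nonsilent <- variants[variants$variant_classification %in%
                          nonsilent_classes(), , drop = FALSE]
  counts <- table(factor(nonsilent$sample_id, levels = sample_ids))
  setNames(as.integer(counts), sample_ids)
}

#' Median TMB split
#'
#' Samples at or above the cohort median are "high" (tie convention:
#' a sample exactly at the median is high).
#'
#' @param tmb named numeric vector of per-sample TMB.
#' @return factor of \code{low}/\code{high} groups, named by sample.
#' @export
median_split <- function(tmb) {
  if (length(unique(tmb)) == 1) {
    warning("median_split: all TMB values equal; every sample is 'high'")
  }
  cut <- median(tmb)
  factor(setNames(ifelse(tmb >= cut, "high", "low"), names(tmb)),
         levels = c("low", "high"))
}

#' Three-group TMB split with a very-high tier
#'
#' Samples at or above the (1 - top_fraction) quantile form the
#' \code{very_high} group; the remaining samples are median-split into
#' \code{low} and \code{high}.  \code{top_fraction = 0} reduces to the plain
#' median split.
#'
#' @param tmb named numeric vector of per-sample TMB.
#' @param top_fraction fraction in the very-high tier (default 0.10).
#' @return factor with levels \code{low}, \code{high}, \code{very_high}.
#' @export
percentile_split <- function(tmb, top_fraction = 0.10) {
  stopifnot(top_fraction >= 0, top_fraction < 1)
  if (top_fraction == 0) {
    g <- median_split(tmb)
    return(factor(setNames(as.character(g), names(tmb)),
                  levels = c("low", "high", "very_high")))
  }
  q <- quantile(tmb, 1 - top_fraction, names = FALSE)
  very_high <- tmb >= q
  out <- rep(NA_character_, length(tmb))
  out[very_high] <- "very_high"
  rest <- tmb[!very_high]
  cut <- median(rest)
  out[!very_high] <- ifelse(rest >= cut, "high", "low")
  factor(setNames(out, names(tmb)), levels = c("low", "high", "very_high"))
}

#' Logrank test between TMB groups
#'
#' Standard logrank statistic (observed vs. expected events over the pooled
#' risk set, via \code{survival::survdiff}) with a chi-square reference on
#' (groups - 1) degrees of freedom.
#'
#' @param groups factor of group assignments named by sample_id (or aligned
#'   with \code{clinical}).
#' @param clinical data.frame with \code{sample_id}, \code{os_time} (days),
#'   \code{os_event} (0/1).
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
logrank_test <- function(groups, clinical) {
  g <- if (!is.null(names(groups))) {
    groups[match(clinical$sample_id, names(groups))]
  } else {
    groups
  }
  g <- droplevels(factor(g))
  if (nlevels(g) < 2) stop("logrank_test: need >= 2 nonempty groups",
                           call. = FALSE)
  if (any(is.na(g))) stop("logrank_test: samples without a group",
                          call. = FALSE)
  if (sum(clinical$os_event) == 0) {
    stop("logrank_test: no events observed", call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(clinical$os_time, clinical$os_event) ~ g)
  df <- nlevels(g) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier fit per TMB group
#'
#' Product-limit survival curves, for plotting alongside the logrank test.
#'
#' @inheritParams logrank_test
#' @return a \code{survival::survfit} object.
#' @export
km_fit <- function(groups, clinical) {
  g <- if (!is.null(names(groups))) {
    groups[match(clinical$sample_id, names(groups))]
  } else {
    groups
  }
  survival::survfit(
    survival::Surv(clinical$os_time, clinical$os_event) ~ g)
}

#' Multivariate Cox regression on TMB, age and stage
#'
#' Proportional-hazards fit with covariates log10(TMB + 1), age, and
#' ordinal-coded tumor stage (the +1 guards samples with zero TMB).  Samples
#' whose stage is not in the coding map are excluded with a logged count.
#'
#' @param clinical data.frame with \code{sample_id}, \code{os_time},
#'   \code{os_event}, \code{age}, \code{stage}.
#' @param tmb named numeric vector of per-sample TMB.
#' @param stage_map named numeric vector coding stages as ordinals; by
#'   default stages "I".."IV" (and numeric strings "1".."4") map to 1..4.
#' @return list with \code{status} ("ok" or "failed"), and on success
#'   \code{coefficients}: a data.frame (term, hr, ci_lower, ci_upper, p).
#' @export
cox_tmb <- function(clinical, tmb,
                    stage_map = c(I = 1, II = 2, III = 3, IV = 4,
                                  "1" = 1, "2" = 2, "3" = 3, "4" = 4)) {
  df <- clinical
  df$log10_tmb <- log10(tmb[match(df$sample_id, names(tmb))] + 1)
  df$stage_ord <- unname(stage_map[as.character(df$stage)])
  dropped <- sum(is.na(df$stage_ord))
  if (dropped > 0) {
    message("cox_tmb: excluded ", dropped, " sample(s) with unknown stage")
    df <- df[!is.na(df$stage_ord), , drop = FALSE]
  }
  if (sum(df$os_event) < 10) {
    warning("cox_tmb: fewer than 10 events; estimates unstable")
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(os_time, os_event) ~
                      log10_tmb + age + stage_ord, data = df),
    error = function(e) e)
  if (inherits(fit, "condition")) {
    return(list(status = "failed", message = conditionMessage(fit)))
  }
  if (any(is.na(stats::coef(fit)))) {
    return(list(status = "failed",
                message = "separation or singular fit: NA coefficient"))
  }
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  list(status = "ok",
       coefficients = data.frame(
         term = rownames(co),
         hr = unname(co[, "exp(coef)"]),
         ci_lower = unname(ci[, "lower .95"]),
         ci_upper = unname(ci[, "upper .95"]),
         p = unname(co[, "Pr(>|z|)"])),
       n = s$n, n_events = s$nevent)
}
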