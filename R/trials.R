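#' Validate trial reports
#'
#' A trial is valid when the reported number was actually shown on the
#' scroller during that trial and the reported target is consistent with the
#' condition (EC: the single water glass; IDII: one of the two water
#' glasses; ID: any of 1..5).  Missing reports give invalid trials, not
#' errors.
#'
#' @param trials Trial-record tibble from [generate_session()] (or with the
#'   same columns).
#' @return The tibble with its `valid` flags set.
#' @export
validate_trials <- function(trials) {
  trials$valid <- purrr::pmap_lgl(
    list(
      trials$scroller_numbers, trials$expected_targets,
      trials$reported_number, trials$reported_target
    ),
    function(nums, expected, rep_num, rep_tgt) {
      !is.na(rep_num) && !is.na(rep_tgt) &&
        rep_num %in% nums && rep_tgt %in% expected
    }
  )
  trials
}

#' Estimate imagination onsets from reported numbers
#'
#' The imagination onset (IO) of a valid trial is the onset of the scroller
#' event whose payload equals the reported number.  Invalid trials keep an
#' undefined (`NA`) IO and are excluded downstream.
#'
#' @param trials Validated trial-record tibble (see [validate_trials()]).
#' @return The tibble with `io_time` filled in for valid trials.
#' @export
estimate_io <- function(trials) {
  if (!is.logical(trials$valid) || anyNA(trials$valid)) {
    stop("run validate_trials() first", call. = FALSE)
  }
  trials$io_time <- purrr::pmap_dbl(
    list(
      trials$scroller_numbers, trials$scroller_onsets,
      trials$reported_number, trials$valid
    ),
    function(nums, onsets, rep_num, ok) {
      if (!ok) {
        return(NA_real_)
      }
      hit <- which(nums == rep_num)
      if (length(hit) != 1) {
        stop("duplicate scroller payloads within a trial", call. = FALSE)
      }
      onsets[hit]
    }
  )
  trials
}

#' Compare imagination-onset times across conditions
#'
#' Pairwise nonparametric Wilcoxon tests on cue-relative IO times for the
#' three condition pairs, Benjamini-Hochberg adjusted over the three
#' p-values.  The rank-sum (Mann-Whitney) variant is the default; the
#' signed-rank variant on trial-index-paired samples is available via
#' `paired = TRUE`.
#'
#' @param trials Validated trial tibble with `io_time` set.
#' @param paired Use the signed-rank variant (default `FALSE`).
#' @param alpha Significance level carried into the output (default 0.05).
#' @return Tibble with columns `condition_a`, `condition_b`, `n_a`, `n_b`,
#'   `p_value`, `p_adjusted`, `significant`.  Pairs with fewer than 2 valid
#'   trials per condition are reported with `NA` p-values.
#' @export
compare_io_conditions <- function(trials, paired = FALSE, alpha = 0.05) {
  ok <- trials$valid & !is.na(trials$io_time)
  rel <- trials$io_time - trials$cue_time
  pairs <- list(c("ID", "IDII"), c("ID", "EC"), c("IDII", "EC"))
  res <- purrr::map_dfr(pairs, function(pr) {
    xa <- rel[ok & trials$condition == pr[1]]
    xb <- rel[ok & trials$condition == pr[2]]
    p <- NA_real_
    if (length(xa) >= 2 && length(xb) >= 2) {
      if (paired) {
        m <- min(length(xa), length(xb))
        p <- suppressWarnings(stats::wilcox.test(xa[seq_len(m)], xb[seq_len(m)],
          paired = TRUE, exact = FALSE
        ))$p.value
      } else {
        p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))$p.value
      }
    }
    tibble::tibble(
      condition_a = pr[1], condition_b = pr[2],
      n_a = length(xa), n_b = length(xb), p_value = p
    )
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res
}
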