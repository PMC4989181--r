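# Ovulation rate, egg number, and per-transition lipid-delivery rates.

#' Ovulation rate from one assay row
#'
#' `(eggs laid + finally retained - initially retained) / (elapsed hours x
#' gonad arms)`, i.e. newly ovulated oocytes per gonad arm per hour.  A
#' negative value can only arise from inconsistent counts; it is returned
#' as-is with a warning rather than clamped, since it diagnoses a bad assay
#' record.
#'
#' @param eggs_laid,final_retained,initial_retained Nonnegative counts
#'   (vectorised).
#' @param elapsed Assay duration in hours (> 0).
#' @param gonad_arms Number of gonad arms (default 2).
#' @return Ovulation rate(s) in oocytes per gonad arm per hour.
#' @export
ovulation_rate <- function(eggs_laid, final_retained, initial_retained,
                           elapsed, gonad_arms = 2L) {
  if (any(elapsed <= 0)) stop("elapsed must be positive")
  if (any(gonad_arms < 1)) stop("gonad_arms must be >= 1")
  rate <- (eggs_laid + final_retained - initial_retained) /
    (elapsed * gonad_arms)
  if (any(rate < 0))
    warning("negative ovulation rate: inconsistent assay counts")
  rate
}

#' Total egg number of one worm
#'
#' Lifetime egg output: the sum of laid eggs, hatched and non-hatched alike.
#'
#' @param hatched,non_hatched Nonnegative counts per laying interval.
#' @return Total count.
#' @export
egg_number <- function(hatched, non_hatched = 0) {
  if (any(hatched < 0) || any(non_hatched < 0)) stop("counts must be >= 0")
  sum(hatched) + sum(non_hatched)
}

#' Per-transition lipid-delivery rates
#'
#' The mean dwell time at each oocyte position equals the inverse of the
#' ovulation rate, so the delivery rate across the transition from position
#' `-n` to `-(n-1)` is the lipid-content increment multiplied by the
#' ovulation rate (per gonad arm).
#'
#' @param lipid_by_position Named numeric vector of lipid contents with names
#'   `"-5"` .. `"-1"` (consecutive positions, any contiguous run of >= 2).
#' @param ovulation Ovulation rate (per gonad arm per hour, >= 0).
#' @return Data frame with `from`, `to`, `delta_content`, `rate`
#'   (lipid units per hour).
#' @export
delivery_rates <- function(lipid_by_position, ovulation) {
  pos <- as.integer(names(lipid_by_position))
  if (anyNA(pos) || length(pos) < 2 || any(diff(pos) != 1L))
    stop("lipid_by_position needs consecutive integer-named positions")
  if (ovulation < 0) stop("ovulation rate must be >= 0")
  d <- diff(unname(lipid_by_position))
  data.frame(from = pos[-length(pos)], to = pos[-1],
             delta_content = d, rate = d * ovulation)
}

#' Normalise delivery-rate tables against a reference strain
#'
#' Divides each strain's transition rates by the wild-type reference.  By
#' default each transition is normalised by the reference strain's *same*
#' transition; `per_transition = FALSE` instead divides everything by the
#' reference's -2 to -1 rate (the canonical transition into the mature
#' oocyte).
#'
#' @param tables Named list of data frames from [delivery_rates()], one per
#'   strain.
#' @param reference Name of the reference strain (default `"N2"`).
#' @param per_transition Normalise per matching transition (default) or by
#'   the reference's -2 -> -1 rate only.
#' @return One data frame with `strain` and `normalized_rate` added; the
#'   reference strain's own entries equal 1 (per transition) or its -2 -> -1
#'   entry equals 1.
#' @export
normalize_delivery <- function(tables, reference = "N2",
                               per_transition = TRUE) {
  if (!reference %in% names(tables))
    stop("reference strain ", reference, " not in tables")
  ref <- tables[[reference]]
  out <- lapply(names(tables), function(s) {
    t <- tables[[s]]
    t$strain <- s
    if (per_transition) {
      m <- match(paste(t$from, t$to), paste(ref$from, ref$to))
      t$normalized_rate <- t$rate / ref$rate[m]
    } else {
      r0 <- ref$rate[ref$from == -2L & ref$to == -1L]
      if (!length(r0)) stop("reference table lacks the -2 -> -1 transition")
      t$normalized_rate <- t$rate / r0
    }
    t
  })
  do.call(rbind, out)
}

#' Simulate an egg-laying / ovulation assay cohort
#'
#' Each worm starts with a Poisson number of retained oocytes/embryos, newly
#' ovulates a Poisson number with mean `ovulation_rate_true x gonad_arms x
#' elapsed`, and lays a binomial share of everything on the plate, so that
#' `eggs_laid + (final - initial)` recovers the newly ovulated count exactly.
#' Deterministic for a fixed seed.
#'
#' @param profile A `strain_profile`.
#' @param n_worms Cohort size (>= 1).
#' @param elapsed Assay duration in hours (default 6, within the standard
#'   5-8 h window).
#' @param seed Integer seed.
#' @param gonad_arms Gonad arms per worm (default 2).
#' @param initial_mean Mean initially retained count (default 12).
#' @param lay_prob Probability an egg ends up laid on the plate (default
#'   0.7).
#' @return Data frame with one row per worm: `worm_id`, `initial_retained`,
#'   `eggs_laid`, `final_retained`, `elapsed`, `gonad_arms`.
#' @export
simulate_reproduction <- function(profile, n_worms, elapsed = 6, seed,
                                  gonad_arms = 2L, initial_mean = 12,
                                  lay_prob = 0.7) {
  validate_strain_profile(profile)
  stopifnot(n_worms >= 1, elapsed > 0)
  with_seed(seed, {
    initial <- stats::rpois(n_worms, initial_mean)
    newly <- stats::rpois(n_worms,
                          profile$ovulation_rate_true * gonad_arms * elapsed)
    laid <- stats::rbinom(n_worms, initial + newly, lay_prob)
    data.frame(worm_id = sprintf("%s_w%03d", profile$strain_name,
                                 seq_len(n_worms)),
               initial_retained = initial, eggs_laid = laid,
               final_retained = initial + newly - laid,
               elapsed = elapsed, gonad_arms = as.integer(gonad_arms))
  })
}
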