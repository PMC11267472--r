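#' Simulate a no-choice mating assay
#'
#' Males are distributed into vials (10 males with 5 tester females by
#' default) and observed for `window` minutes.  Mating is a competing-risk
#' process: while unmated females remain, each free male courts each free
#' female at his per-minute hazard, so the next copulation occurs after an
#' exponential waiting time with total rate
#' `(free females) * sum(free male hazards)`, the mating male is drawn
#' proportionally to his hazard, and the pair is removed.  Latencies are
#' recorded in minutes; unmated males carry `NA`.
#'
#' @param hazard Per-minute per-pair hazard per male, e.g. from
#'   [liability_hazard()].
#' @param n_females Tester females per vial.
#' @param males_per_vial Males per vial; males fill vials in order.
#' @param window Observation window in minutes (> 0).
#' @param male_id Optional male identifiers (default `seq_along(hazard)`).
#' @param observe_beyond_window Keep watching each vial after the scored
#'   window until its females are exhausted.  Matings beyond the window
#'   get a latency but `mated = FALSE` (they do not count towards the
#'   vial's scored proportion); used by the selection designs, where the
#'   breeding quota is the first k copulations regardless of the scored
#'   window.
#' @param seed Optional RNG seed.
#' @return A `mating_trials` data.frame: vial, male_id, hazard, mated,
#'   latency, window_min, n_females.
#' @export
#' @examples
#' a <- simulate_mating_assay(rep(0.001, 30), window = 60, seed = 1)
#' mean(assay_summary(a)$proportion)
simulate_mating_assay <- function(hazard, n_females = 5, males_per_vial = 10,
                                  window = 60, male_id = NULL,
                                  observe_beyond_window = FALSE,
                                  seed = NULL) {
  if (window <= 0) stop("observation window must be positive")
  if (any(hazard < 0)) stop("hazards must be non-negative")
  n <- length(hazard)
  if (is.null(male_id)) male_id <- seq_len(n)
  vial <- rep(seq_len(ceiling(n / males_per_vial)), each = males_per_vial)[seq_len(n)]
  with_seed(seed, {
    latency <- rep(NA_real_, n)
    for (v in unique(vial)) {
      in_v <- which(vial == v)
      free <- in_v
      fem <- n_females
      t <- 0
      while (fem > 0 && length(free) > 0) {
        rate <- fem * sum(hazard[free])
        if (rate <= 0) break
        t <- t + stats::rexp(1, rate)
        if (t > window && !observe_beyond_window) break
        j <- if (length(free) == 1L) free else
          sample(free, 1L, prob = hazard[free])
        latency[j] <- t
        free <- setdiff(free, j)
        fem <- fem - 1L
      }
    }
    structure(data.frame(vial = vial, male_id = male_id, hazard = hazard,
                         mated = !is.na(latency) & latency <= window,
                         latency = latency,
                         window_min = window, n_females = n_females),
              class = c("mating_trials", "data.frame"))
  })
}

#' Per-vial summary of a mating assay
#'
#' @param trials A `mating_trials` table.
#' @return data.frame: vial, n_females, n_mated, proportion.  Every vial
#'   conserves females: `n_mated + unmated = n_females`.
#' @export
assay_summary <- function(trials) {
  agg <- aggregate(mated ~ vial, data = trials, FUN = sum)
  nf <- trials$n_females[match(agg$vial, trials$vial)]
  data.frame(vial = agg$vial, n_females = nf, n_mated = agg$mated,
             proportion = agg$mated / nf)
}

#' Select males from an assay by a truncation rule
#'
#' `first_k` takes the first k males to copulate (the k smallest latencies
#' across all vials observed in parallel; `k_fastest` is the same statistic
#' phrased over completed assays).  `k_random` draws k males uniformly from
#' all assayed males.  Latency ties are broken by a seeded uniform draw.
#'
#' @param trials A `mating_trials` table.
#' @param rule One of "first_k", "k_fastest", "k_random".
#' @param k Number of males to keep.
#' @param seed Optional RNG seed (tie-breaking / random rule).
#' @return The selected `male_id`s.
#' @export
truncation_select <- function(trials, rule = c("first_k", "k_fastest",
                                               "k_random"), k, seed = NULL) {
  rule <- match.arg(rule)
  with_seed(seed, {
    if (rule == "k_random") {
      if (k > nrow(trials))
        stop(sprintf("cannot select k=%d from %d assayed males", k,
                     nrow(trials)))
      return(sample(trials$male_id, k))
    }
    maters <- trials[!is.na(trials$latency), ]
    if (nrow(maters) < k)
      stop(sprintf("only %d males mated; cannot select k=%d under rule '%s'",
                   nrow(maters), k, rule))
    o <- order(maters$latency, runif(nrow(maters)))
    maters$male_id[o[seq_len(k)]]
  })
}
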